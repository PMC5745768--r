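# Pose application (sagittal rotation about the talocrural axis, then
# frontal rotation about the carried-along subtalar axis), the percent
# strain formula, the pose-grid sweep and cohort aggregation.
#
# Sign conventions (right foot, canonical frame): the talocrural axis is
# oriented medial->lateral and the subtalar axis posterior->anterior;
# positive right-hand rotations about them are dorsiflexion and inversion.
# For a left foot the frontal mapping mirrors, handled by `side = "left"`.

#' The pose grid
#'
#' Sagittal angles -30, -20, -10, 0, +10, +20 degrees (negative =
#' plantarflexion, positive = dorsiflexion) crossed with frontal angles
#' -20, 0, +20 degrees (negative = eversion, positive = inversion):
#' plantarflexion to 30 degrees, dorsiflexion to 20, inversion and eversion
#' to 20.
#'
#' @return data.frame with columns `sagittal_deg`, `frontal_deg` (18 rows).
#' @export
pose_grid <- function() {
  expand.grid(sagittal_deg = c(-30, -20, -10, 0, 10, 20),
              frontal_deg = c(-20, 0, 20), KEEP.OUT.ATTRS = FALSE)
}

#' Apply a pose to the foot-side landmarks
#'
#' Rotates talus- and calcaneus-fixed landmarks about the talocrural axis
#' by the sagittal angle, then rotates the calcaneus-fixed landmarks about
#' the sagittally-carried subtalar axis (rebuilt from the rotated talar and
#' calcaneal landmarks, which both sit distal to the ankle hinge) by the
#' frontal angle.  Fibula-fixed points, including the CFL origin(s), do not
#' move.
#'
#' @param model an [ankle_model()].
#' @param sagittal_deg sagittal angle in degrees (+ = dorsiflexion).
#' @param frontal_deg frontal angle in degrees (+ = inversion).
#' @param side `"right"` (default) or `"left"`; for a left foot the frontal
#'   rotation sign is mirrored so that positive still means inversion.
#' @return The posed [ankle_landmarks()] set.
#' @export
apply_pose <- function(model, sagittal_deg, frontal_deg, side = c("right", "left")) {
  stopifnot(inherits(model, "ankle_model"))
  side <- match.arg(side)
  if (!is.finite(sagittal_deg) || !is.finite(frontal_deg)) {
    stop("pose angles must be finite", call. = FALSE)
  }
  fro <- if (side == "left") -frontal_deg else frontal_deg
  lm <- model$landmarks
  xyz <- as.matrix(lm[, c("x", "y", "z")])

  foot <- lm$segment %in% c("talus", "calcaneus")
  if (sagittal_deg != 0) {
    xyz[foot, ] <- rotate_points_about_axis(xyz[foot, , drop = FALSE],
                                            model$talocrural, sagittal_deg)
  }
  if (fro != 0) {
    tub <- xyz[match("calcaneal_tuberosity_lateral", lm$name), ]
    tal <- xyz[match("talar_head_midpoint", lm$name), ]
    if (segment_length(tub, tal) < 1e-9) {
      stop("degenerate axis: subtalar landmarks coincide", call. = FALSE)
    }
    st <- axis_line(tub, tal - tub)
    calc <- lm$segment == "calcaneus"
    xyz[calc, ] <- rotate_points_about_axis(xyz[calc, , drop = FALSE], st, fro)
  }
  lm$x <- xyz[, 1]; lm$y <- xyz[, 2]; lm$z <- xyz[, 3]
  lm
}

#' Percent strain from a reference length
#'
#' `100 * (L_T - L_S) / L_S`: positive = stretched, negative = contracted.
#'
#' @param length_mm ligament length in the pose (mm).
#' @param neutral_mm reference (neutral-pose) length (mm), must be > 0.
#' @return Strain in percent.
#' @export
strain_percent <- function(length_mm, neutral_mm) {
  if (any(!is.finite(neutral_mm)) || any(neutral_mm <= 0)) {
    stop("invalid reference length: must be positive", call. = FALSE)
  }
  (length_mm - neutral_mm) / neutral_mm * 100
}

# Per-bundle posed lengths, internal.
bundle_lengths <- function(model, posed) {
  vapply(model$bundles, function(b) {
    segment_length(landmark_point(posed, b$origin_name),
                   landmark_point(posed, b$insertion_name))
  }, numeric(1))
}

#' Specimen strain at one pose
#'
#' Single-bundle specimens: percent strain of the bundle.  Two-bundle
#' (CFL2) specimens: unweighted mean of the two bundle strains.
#'
#' @inheritParams apply_pose
#' @return Strain in percent (exactly 0 at the neutral pose).
#' @export
specimen_strain <- function(model, sagittal_deg, frontal_deg,
                            side = c("right", "left")) {
  side <- match.arg(side)
  posed <- apply_pose(model, sagittal_deg, frontal_deg, side)
  lens <- bundle_lengths(model, posed)
  neutral <- vapply(model$bundles, `[[`, numeric(1), "neutral_length")
  mean(strain_percent(lens, neutral))
}

#' Sweep the full pose grid for one specimen
#'
#' @inheritParams apply_pose
#' @param category optional category label attached to the result.
#' @return A `strain_table`: data.frame over the 18-pose grid with columns
#'   `sagittal_deg`, `frontal_deg`, `strain_pct` (full precision; rounding
#'   happens only when written out), with per-bundle posed lengths in the
#'   `"lengths_mm"` attribute and neutral lengths in `"neutral_mm"`.
#' @export
sweep_grid <- function(model, side = c("right", "left"), category = NULL) {
  side <- match.arg(side)
  grid <- pose_grid()
  neutral <- vapply(model$bundles, `[[`, numeric(1), "neutral_length")
  lens <- matrix(NA_real_, nrow(grid), length(model$bundles))
  for (i in seq_len(nrow(grid))) {
    posed <- apply_pose(model, grid$sagittal_deg[i], grid$frontal_deg[i], side)
    lens[i, ] <- bundle_lengths(model, posed)
  }
  grid$strain_pct <- rowMeans(sweep(sweep(lens, 2, neutral), 2, neutral, "/")) * 100
  structure(grid, lengths_mm = lens, neutral_mm = neutral,
            category = category, class = c("strain_table", "data.frame"))
}

# Strain at a given pose from a strain_table, internal.
strain_at <- function(table, sagittal_deg, frontal_deg) {
  i <- which(table$sagittal_deg == sagittal_deg & table$frontal_deg == frontal_deg)
  if (length(i) != 1L) {
    stop("incomplete pose grid: no unique record at (", sagittal_deg, ", ",
         frontal_deg, ")", call. = FALSE)
  }
  table$strain_pct[i]
}

validate_strain_table <- function(table) {
  need <- c("sagittal_deg", "frontal_deg", "strain_pct")
  if (!all(need %in% names(table))) {
    stop("strain table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  grid <- pose_grid()
  key <- function(d) paste(d$sagittal_deg, d$frontal_deg)
  if (nrow(table) != 18L || !setequal(key(table), key(grid)) ||
      anyDuplicated(key(table))) {
    stop("incomplete pose grid: expected exactly the 18 grid poses",
         call. = FALSE)
  }
  invisible(table)
}

#' Qualitative strain pattern of a specimen
#'
#' Labels the sagittal behaviour from the strain signs at the sagittal grid
#' extremes (plantarflexion 30 and dorsiflexion 20, neutral frontal) and the
#' frontal behaviour from the signs at inversion/eversion 20 (neutral
#' sagittal).
#'
#' @param table a `strain_table` from [sweep_grid()] (full 18-pose grid).
#' @param tol strains with magnitude below `tol` count as zero.
#' @return List with elements `sagittal` and `frontal`; sagittal is one of
#'   `"contracts-in-PF/stretches-in-DF"`, `"stretches-in-PF/contracts-in-DF"`,
#'   `"isometric"`, `"mixed"`; frontal analogously with
#'   `"stretches-in-INV/contracts-in-EV"` and
#'   `"contracts-in-INV/stretches-in-EV"`.
#' @export
sign_pattern <- function(table, tol = 1e-9) {
  validate_strain_table(table)
  s_pf <- strain_at(table, -30, 0)
  s_df <- strain_at(table, 20, 0)
  s_inv <- strain_at(table, 0, 20)
  s_ev <- strain_at(table, 0, -20)
  lab <- function(a, b, neg_pos, pos_neg) {
    if (abs(a) < tol && abs(b) < tol) "isometric"
    else if (a < -tol && b > tol) neg_pos
    else if (a > tol && b < -tol) pos_neg
    else "mixed"
  }
  list(
    sagittal = lab(s_pf, s_df, "contracts-in-PF/stretches-in-DF",
                   "stretches-in-PF/contracts-in-DF"),
    frontal = lab(s_ev, s_inv, "stretches-in-INV/contracts-in-EV",
                  "contracts-in-INV/stretches-in-EV")
  )
}

#' Aggregate per-category strain values
#'
#' Given per-category strain values at a common set of poses, returns the
#' cross-category mean and sample standard deviation (n-1 denominator) per
#' pose, at full precision (round only for display, e.g. with
#' [round_half_up()] or [write_strain_table()]).
#'
#' @param x either a numeric matrix / data.frame (rows = categories,
#'   columns = poses) or a list of `strain_table`s from [sweep_grid()].
#' @param sd compute the sample SD row?  Requires at least two categories.
#' @return For matrix input: data.frame with `pose` (column names of `x`),
#'   `mean` and (if requested) `sd`.  For a list of strain tables:
#'   data.frame with `sagittal_deg`, `frontal_deg`, `mean`, `sd`.
#' @export
summarize_cohort <- function(x, sd = TRUE) {
  if (is.list(x) && !is.data.frame(x) && all(vapply(x, inherits, TRUE, "strain_table"))) {
    if (length(x) == 0) stop("empty input", call. = FALSE)
    for (t in x) validate_strain_table(t)
    grid <- pose_grid()
    vals <- vapply(x, function(t) {
      mapply(function(s, f) strain_at(t, s, f), grid$sagittal_deg, grid$frontal_deg)
    }, numeric(nrow(grid)))
    vals <- t(vals)  # categories x poses
    out <- grid
  } else {
    vals <- as.matrix(x)
    if (!is.numeric(vals) || length(vals) == 0) {
      stop("expected numeric per-category values or a list of strain tables",
           call. = FALSE)
    }
    out <- data.frame(pose = colnames(vals) %||% as.character(seq_len(ncol(vals))),
                      stringsAsFactors = FALSE)
  }
  if (sd && nrow(vals) < 2) {
    stop("undefined SD: need at least two category values per pose",
         call. = FALSE)
  }
  out$mean <- colMeans(vals)
  if (sd) out$sd <- apply(vals, 2, stats::sd)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
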