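# From named landmarks to joint axes, the fibular long axis, the CFL
# running angle, the five morphology categories and the cohort-level
# census statistics.

build_axis_between <- function(landmarks, from, to, what) {
  p <- landmark_point(landmarks, from)
  q <- landmark_point(landmarks, to)
  if (segment_length(p, q) < 1e-9) {
    stop("degenerate axis: ", what, " landmarks coincide (", from, ", ", to, ")",
         call. = FALSE)
  }
  axis_line(p, q - p)
}

#' Talocrural (ankle hinge) axis
#'
#' The line connecting the inferior borders of the medial and lateral
#' malleoli, oriented medial to lateral.
#'
#' @param landmarks an [ankle_landmarks()] set.
#' @return An [axis_line()] anchored at the medial malleolus landmark.
#' @export
build_talocrural_axis <- function(landmarks) {
  build_axis_between(landmarks, "medial_malleolus_inferior",
                     "lateral_malleolus_inferior", "talocrural")
}

#' Subtalar joint axis
#'
#' The line connecting the lateral border of the calcaneal tuberosity and
#' the midpoint of the talar head, oriented posterior to anterior.
#'
#' @inheritParams build_talocrural_axis
#' @return An [axis_line()] anchored at the calcaneal tuberosity landmark.
#' @export
build_subtalar_axis <- function(landmarks) {
  build_axis_between(landmarks, "calcaneal_tuberosity_lateral",
                     "talar_head_midpoint", "subtalar")
}

#' Fibular long axis
#'
#' The line through the proximal fibular shaft landmark and the inferior
#' border of the lateral malleolus, oriented proximal to distal.
#'
#' @inheritParams build_talocrural_axis
#' @return An [axis_line()] anchored at the proximal shaft landmark.
#' @export
build_fibula_long_axis <- function(landmarks) {
  build_axis_between(landmarks, "fibula_shaft_proximal",
                     "lateral_malleolus_inferior", "fibula long")
}

#' Assemble an ankle model from landmarks
#'
#' Builds the three axes and the 1-2 CFL bundles (origin, insertion and
#' neutral length at the supplied reference position).
#'
#' @inheritParams build_talocrural_axis
#' @return An object of class `ankle_model`: list with `landmarks`,
#'   `talocrural`, `subtalar`, `fibula` axes and `bundles` (each bundle a
#'   list with `origin`, `insertion`, `neutral_length` in mm).
#' @export
ankle_model <- function(landmarks) {
  landmarks <- validate_ankle_landmarks(landmarks)
  bundles <- list(make_bundle(landmarks, "cfl_origin", "cfl_insertion"))
  if (has_second_bundle(landmarks)) {
    bundles <- c(bundles,
                 list(make_bundle(landmarks, "cfl_origin_2", "cfl_insertion_2")))
  }
  structure(list(
    landmarks  = landmarks,
    talocrural = build_talocrural_axis(landmarks),
    subtalar   = build_subtalar_axis(landmarks),
    fibula     = build_fibula_long_axis(landmarks),
    bundles    = bundles
  ), class = "ankle_model")
}

make_bundle <- function(landmarks, origin_name, insertion_name) {
  origin <- landmark_point(landmarks, origin_name)
  insertion <- landmark_point(landmarks, insertion_name)
  len <- segment_length(origin, insertion)
  if (len < 1e-9) {
    stop("degenerate ligament: ", origin_name, " and ", insertion_name,
         " coincide", call. = FALSE)
  }
  list(origin = origin, insertion = insertion, neutral_length = len,
       origin_name = origin_name, insertion_name = insertion_name)
}

#' @export
print.ankle_model <- function(x, ...) {
  cat(sprintf("ankle model: %d CFL bundle(s), neutral length(s) %s mm\n",
              length(x$bundles),
              paste(sprintf("%.2f", vapply(x$bundles, `[[`, 0,
                                           "neutral_length")), collapse = ", ")))
  invisible(x)
}

#' CFL running angle
#'
#' The angle between the proximal-to-distal fibular long-axis direction and
#' the origin-to-insertion direction of the first CFL bundle, in degrees.
#' With `projected = TRUE` both directions are first projected onto the
#' plane perpendicular to the talocrural axis (the "lateral view" plane),
#' emulating a goniometer reading taken on the lateral aspect; the default
#' is the true 3D angle.
#'
#' @param model an [ankle_model()].
#' @param projected project onto the lateral-view plane first?
#' @return Angle in degrees, in \[0, 180\].
#' @export
cfl_running_angle <- function(model, projected = FALSE) {
  stopifnot(inherits(model, "ankle_model"))
  d <- model$fibula$direction
  b <- model$bundles[[1]]
  v <- b$insertion - b$origin
  if (sqrt(sum(v^2)) < 1e-9) {
    stop("degenerate ligament: zero length", call. = FALSE)
  }
  if (projected) {
    n <- model$talocrural$direction
    d <- d - sum(d * n) * n
    v <- v - sum(v * n) * n
    if (sqrt(sum(d^2)) < 1e-9 || sqrt(sum(v^2)) < 1e-9) {
      stop("degenerate projection: direction parallel to the talocrural axis",
           call. = FALSE)
    }
  }
  angle_between_directions(d, v)
}

#' The five CFL morphology categories
#'
#' @return Character vector of category labels in canonical order.
#' @export
cfl_categories <- function() c("CFL20", "CFL30", "CFL40", "CFL50", "CFL2")

#' Classify a CFL by running angle and bundle count
#'
#' Two crossing bundles are category `CFL2` regardless of angle.  Single
#' bundles are classified by half-open running-angle intervals
#' \[20, 30), \[30, 40), \[40, 50), \[50, 60); single-bundle angles outside
#' \[20, 60) are not covered by the scheme and raise an error.
#'
#' @param angle_deg running angle in degrees, in \[0, 180\].
#' @param n_bundles 1 or 2.
#' @return One of `cfl_categories()`.
#' @export
classify_cfl <- function(angle_deg, n_bundles = 1L) {
  if (!is.finite(angle_deg) || angle_deg < 0 || angle_deg > 180) {
    stop("running angle must be in [0, 180] degrees", call. = FALSE)
  }
  if (!n_bundles %in% c(1L, 2L)) {
    stop("n_bundles must be 1 or 2", call. = FALSE)
  }
  if (n_bundles == 2L) return("CFL2")
  if (angle_deg < 20 || angle_deg >= 60) {
    stop(sprintf("unclassifiable: single-bundle running angle %.2f degrees is outside [20, 60)",
                 angle_deg), call. = FALSE)
  }
  c("CFL20", "CFL30", "CFL40", "CFL50")[findInterval(angle_deg, c(20, 30, 40, 50))]
}

#' Per-category census of a classified cohort
#'
#' @param categories character vector of category labels (values of
#'   [classify_cfl()]).
#' @return data.frame with columns `category`, `n` and `pct` (percentage of
#'   the cohort, half-up rounded to 1 decimal), one row per category in
#'   canonical order, including zero-count categories.
#' @export
category_proportions <- function(categories) {
  if (length(categories) == 0) {
    stop("empty input: no categories to tabulate", call. = FALSE)
  }
  bad <- setdiff(unique(categories), cfl_categories())
  if (length(bad)) {
    stop("unknown category label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- as.integer(table(factor(categories, levels = cfl_categories())))
  data.frame(category = cfl_categories(), n = n,
             pct = round_half_up(100 * n / length(categories), 1),
             stringsAsFactors = FALSE)
}

#' Pearson chi-squared test of homogeneity
#'
#' Pearson statistic on a contingency table of counts with expected counts
#' from the row/column margins, df = (r-1)(c-1), p-value from the
#' asymptotic chi-squared upper tail; no continuity correction.  Cells with
#' small expected counts are allowed but trigger a warning.
#'
#' @param counts integer matrix of counts (at least 2 x 2).
#' @return List with `statistic`, `df`, `p_value` and the `expected` matrix.
#' @export
chi_squared_homogeneity <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and finite", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("invalid table: zero row or column margin", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ht$expected < 5)) {
    warning("some expected counts are below 5; the asymptotic chi-squared ",
            "p-value may be inaccurate", call. = FALSE)
  }
  list(statistic = unname(ht$statistic), df = as.integer(unname(ht$parameter)),
       p_value = unname(ht$p.value), expected = ht$expected)
}
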