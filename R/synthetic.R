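# Synthetic anatomy generator: a deterministic template ankle, CFL
# placement at any prescribed running angle, a two-crossing-bundle variant,
# Gaussian digitizer noise and cohort sampling at the reference category
# proportions.  No cadaver coordinates were ever published for this
# problem, so every template coordinate is an invented, documented default;
# they are configuration, not constants.

#' Template-ankle configuration
#'
#' Defaults define a right-foot canonical frame (+x anterior, +y proximal,
#' +z lateral; mm).  The malleolar, shaft and CFL-origin offsets were fixed
#' once, by constrained optimisation over anatomically plausible ranges, so
#' that the default template reproduces the documented qualitative strain
#' behaviour of low- versus high-running-angle ligaments (see the package
#' vignette for the geometric analysis); they are not fitted to any data.
#'
#' @param fibula_shaft_length distance from the lateral malleolus up to the
#'   proximal fibular shaft landmark (mm).
#' @param intermalleolar_width medial-to-lateral malleolus separation (mm).
#' @param cfl_length neutral CFL length (mm).
#' @param cfl_plane_tilt_deg out-of-plane tilt of the CFL plane, degrees
#'   medial from the parasagittal plane of the fibular axis.
#' @param cfl_origin_offset (x, y) offset of the CFL origin from the
#'   lateral malleolus landmark (mm; negative x = posterior, negative y =
#'   distal).
#' @param medial_malleolus_offset (x, y) offset of the medial malleolus
#'   landmark relative to the lateral one (mm; anterior, proximal) - the
#'   talocrural axis obliquity.
#' @param fibula_shaft_anterior_offset x offset of the proximal shaft
#'   landmark (mm) - the sagittal inclination of the fibular long axis.
#' @param calcaneal_tuberosity position of the lateral border of the
#'   calcaneal tuberosity (mm).
#' @param talar_head position of the talar head midpoint (mm).
#' @param default_angle_deg running angle of the template's CFL.
#' @return A list of class `template_config`.
#' @export
template_config <- function(fibula_shaft_length = 80,
                            intermalleolar_width = 70,
                            cfl_length = 20,
                            cfl_plane_tilt_deg = 15,
                            cfl_origin_offset = c(-1, -1),
                            medial_malleolus_offset = c(8, 5),
                            fibula_shaft_anterior_offset = 4.5,
                            calcaneal_tuberosity = c(-30, -30, 30),
                            talar_head = c(45, 0, 10),
                            default_angle_deg = 35) {
  cfg <- list(fibula_shaft_length = fibula_shaft_length,
              intermalleolar_width = intermalleolar_width,
              cfl_length = cfl_length,
              cfl_plane_tilt_deg = cfl_plane_tilt_deg,
              cfl_origin_offset = as.numeric(cfl_origin_offset),
              medial_malleolus_offset = as.numeric(medial_malleolus_offset),
              fibula_shaft_anterior_offset = fibula_shaft_anterior_offset,
              calcaneal_tuberosity = as.numeric(calcaneal_tuberosity),
              talar_head = as.numeric(talar_head),
              default_angle_deg = default_angle_deg)
  if (!all(vapply(cfg, function(v) all(is.finite(v)), TRUE))) {
    stop("invalid config: all values must be finite", call. = FALSE)
  }
  if (cfg$fibula_shaft_length <= 0 || cfg$intermalleolar_width <= 0 ||
      cfg$cfl_length <= 0) {
    stop("invalid config: lengths must be positive", call. = FALSE)
  }
  if (cfg$default_angle_deg <= 0 || cfg$default_angle_deg >= 90) {
    stop("invalid config: default running angle must be in (0, 90) degrees",
         call. = FALSE)
  }
  structure(cfg, class = "template_config")
}

#' Deterministic template ankle
#'
#' Builds a complete landmark set in the canonical right-foot frame from a
#' [template_config()].  The same configuration always yields identical
#' coordinates; all three axis builders succeed on the result.
#'
#' @param config a [template_config()].
#' @return An [ankle_landmarks()] set carrying the configuration in its
#'   `"template_config"` attribute (used by [make_cfl_at_angle()]).
#' @export
make_template_ankle <- function(config = template_config()) {
  if (!inherits(config, "template_config")) {
    stop("invalid config: expected a 'template_config'", call. = FALSE)
  }
  zlat <- config$intermalleolar_width / 2
  lat <- c(0, 0, zlat)
  med <- c(config$medial_malleolus_offset[1], config$medial_malleolus_offset[2], -zlat)
  prox <- c(config$fibula_shaft_anterior_offset, config$fibula_shaft_length, zlat)
  origin <- lat + c(config$cfl_origin_offset[1], config$cfl_origin_offset[2], 0)
  lm <- ankle_landmarks(
    name = c("fibula_shaft_proximal", "lateral_malleolus_inferior",
             "medial_malleolus_inferior", "calcaneal_tuberosity_lateral",
             "talar_head_midpoint", "cfl_origin", "cfl_insertion"),
    segment = c("fibula", "fibula", "fibula", "calcaneus", "talus",
                "fibula", "calcaneus"),
    x = c(prox[1], lat[1], med[1], config$calcaneal_tuberosity[1],
          config$talar_head[1], origin[1], 0),
    y = c(prox[2], lat[2], med[2], config$calcaneal_tuberosity[2],
          config$talar_head[2], origin[2], 0),
    z = c(prox[3], lat[3], med[3], config$calcaneal_tuberosity[3],
          config$talar_head[3], origin[3], 0)
  )
  attr(lm, "template_config") <- config
  make_cfl_at_angle(lm, config$default_angle_deg, config$cfl_length)
}

# In-plane frame for CFL placement, internal: d = proximal->distal fibular
# direction; e = unit vector perpendicular to d, posterior, tilted medially
# by the configured out-of-plane angle.
cfl_placement_frame <- function(template, tilt_deg) {
  d_axis <- build_fibula_long_axis(template)
  d <- d_axis$direction
  e0 <- c(-1, 0, 0)
  e0 <- e0 - sum(e0 * d) * d
  n0 <- sqrt(sum(e0^2))
  if (n0 < 1e-9) {
    stop("degenerate template: fibular axis parallel to the posterior direction",
         call. = FALSE)
  }
  e0 <- e0 / n0
  f0 <- cross3(d, e0)  # medial in the canonical frame
  til <- deg2rad(tilt_deg)
  list(d = d, e = cos(til) * e0 + sin(til) * f0)
}

#' Place the CFL at a prescribed running angle
#'
#' Sets the CFL insertion at `cfl_origin + length * u`, where `u` makes
#' exactly the angle `theta_deg` with the distal fibular direction and lies
#' in the template's posteroinferior CFL plane (tilted medially by the
#' configured out-of-plane angle).  The measured running angle of the
#' resulting model equals `theta_deg` to floating-point precision.  Any
#' second bundle present is removed.
#'
#' @param template a template [ankle_landmarks()] set in the canonical
#'   frame (from [make_template_ankle()]).
#' @param theta_deg target running angle, in (0, 90) degrees.
#' @param length_mm neutral CFL length; defaults to the template
#'   configuration's value.
#' @return The landmark set with `cfl_insertion` repositioned.
#' @export
make_cfl_at_angle <- function(template, theta_deg, length_mm = NULL) {
  cfg <- attr(template, "template_config")
  if (is.null(cfg)) cfg <- template_config()
  if (is.null(length_mm)) length_mm <- cfg$cfl_length
  if (!is.finite(theta_deg) || theta_deg <= 0 || theta_deg >= 90) {
    stop("unsupported angle: running angle must be in (0, 90) degrees",
         call. = FALSE)
  }
  if (!is.finite(length_mm) || length_mm <= 0) {
    stop("invalid length: must be positive", call. = FALSE)
  }
  fr <- cfl_placement_frame(template, cfg$cfl_plane_tilt_deg)
  th <- deg2rad(theta_deg)
  u <- cos(th) * fr$d + sin(th) * fr$e
  origin <- landmark_point(template, "cfl_origin")
  out <- set_landmark(template, "cfl_insertion", "calcaneus",
                      origin + length_mm * u)
  out <- out[!out$name %in% c("cfl_origin_2", "cfl_insertion_2"), ]
  attr(out, "template_config") <- cfg
  class(out) <- c("ankle_landmarks", "data.frame")
  out
}

#' Two-crossing-bundle CFL variant
#'
#' Builds a CFL2 specimen: two origin-insertion bundles at distinct running
#' angles whose segments cross strictly between their endpoints in the
#' lateral (x-y) projection.  The bundle origins are offset 1.5 mm either
#' way along the in-plane posterior direction (smaller angle posterior) so
#' the segments cross; the construction verifies the crossing and fails if
#' the supplied angles do not produce one.
#'
#' @inheritParams make_cfl_at_angle
#' @param theta1_deg,theta2_deg the two running angles, distinct, in (0, 90).
#' @return The landmark set with both bundles
#'   (`cfl_origin`/`cfl_insertion` = bundle at `theta1_deg`,
#'   `cfl_origin_2`/`cfl_insertion_2` = bundle at `theta2_deg`).
#' @export
make_two_bundle_cfl <- function(template, theta1_deg, theta2_deg,
                                length_mm = NULL) {
  cfg <- attr(template, "template_config")
  if (is.null(cfg)) cfg <- template_config()
  if (is.null(length_mm)) length_mm <- cfg$cfl_length
  for (th in c(theta1_deg, theta2_deg)) {
    if (!is.finite(th) || th <= 0 || th >= 90) {
      stop("unsupported angle: running angles must be in (0, 90) degrees",
           call. = FALSE)
    }
  }
  if (theta1_deg == theta2_deg) {
    stop("bundles do not cross: the two running angles are equal",
         call. = FALSE)
  }
  fr <- cfl_placement_frame(template, cfg$cfl_plane_tilt_deg)
  # in-plane posterior unit direction for the origin offsets
  epost <- fr$e - sum(fr$e * fr$d) * fr$d
  epost <- epost / sqrt(sum(epost^2))
  base <- landmark_point(template, "cfl_origin")
  off <- 1.5 * epost
  o1 <- if (theta1_deg < theta2_deg) base + off else base - off
  o2 <- if (theta1_deg < theta2_deg) base - off else base + off
  u <- function(th) cos(deg2rad(th)) * fr$d + sin(deg2rad(th)) * fr$e
  i1 <- o1 + length_mm * u(theta1_deg)
  i2 <- o2 + length_mm * u(theta2_deg)
  if (!segments_cross_2d(o1[1:2], i1[1:2], o2[1:2], i2[1:2])) {
    stop("bundles do not cross in lateral projection for the supplied angles",
         call. = FALSE)
  }
  out <- set_landmark(template, "cfl_origin", "fibula", o1)
  out <- set_landmark(out, "cfl_insertion", "calcaneus", i1)
  out <- set_landmark(out, "cfl_origin_2", "fibula", o2)
  out <- set_landmark(out, "cfl_insertion_2", "calcaneus", i2)
  attr(out, "template_config") <- cfg
  validate_ankle_landmarks(out)
}

# Strict interior intersection of 2D segments a1-a2 and b1-b2, internal.
segments_cross_2d <- function(a1, a2, b1, b2) {
  da <- a2 - a1; db <- b2 - b1
  den <- da[1] * db[2] - da[2] * db[1]
  if (abs(den) < 1e-12) return(FALSE)
  w <- b1 - a1
  t <- (w[1] * db[2] - w[2] * db[1]) / den
  s <- (w[1] * da[2] - w[2] * da[1]) / den
  eps <- 1e-9
  t > eps && t < 1 - eps && s > eps && s < 1 - eps
}

# Add N(0, sd) noise to every coordinate using the current RNG stream.
perturb_landmarks <- function(landmarks, sd) {
  n <- nrow(landmarks)
  landmarks$x <- landmarks$x + stats::rnorm(n, 0, sd)
  landmarks$y <- landmarks$y + stats::rnorm(n, 0, sd)
  landmarks$z <- landmarks$z + stats::rnorm(n, 0, sd)
  landmarks
}

#' Simulate digitizer measurement noise
#'
#' Adds independent zero-mean Gaussian noise with the given SD to every
#' coordinate of every landmark, emulating the stated precision of an
#' articulated-arm digitizer (0.23 mm).  `sd = 0` returns the input
#' unchanged; the same seed always yields the same output.
#'
#' @param landmarks an [ankle_landmarks()] set.
#' @param sd noise standard deviation in mm (>= 0).
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (and advanced).
#' @return The perturbed landmark set.
#' @export
add_digitizer_noise <- function(landmarks, sd = 0.23, seed = NULL) {
  if (!is.finite(sd) || sd < 0) {
    stop("invalid parameter: noise sd must be >= 0", call. = FALSE)
  }
  if (sd == 0) return(landmarks)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  perturb_landmarks(landmarks, sd)
}

#' Cohort-sampling configuration
#'
#' Defaults reproduce the reference census: 81 feet allocated to the five
#' categories at proportions 14/81, 22/81, 29/81, 15/81, 1/81 by largest
#' remainder (deterministic), running angles uniform within each category's
#' interval, digitizer noise SD 0.23 mm.
#'
#' @param n cohort size.
#' @param proportions category proportions in the order of
#'   [cfl_categories()]; must sum to 1.
#' @param noise_sd digitizer noise SD (mm).
#' @param seed integer seed controlling all random draws.
#' @param template template [ankle_landmarks()] the specimens are built
#'   from.
#' @param cfl2_angle_ranges two-bundle angle ranges for CFL2 specimens:
#'   2 x 2 matrix, one row per bundle, columns (min, max) degrees.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n = 81,
                          proportions = c(14, 22, 29, 15, 1) / 81,
                          noise_sd = 0.23,
                          seed = 1L,
                          template = make_template_ankle(),
                          cfl2_angle_ranges = rbind(c(25, 35), c(50, 60))) {
  if (!is.finite(n) || n < 1) stop("empty input: n must be >= 1", call. = FALSE)
  if (length(proportions) != 5L || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must be 5 non-negative values summing to 1",
         call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("invalid parameter: noise sd must be >= 0", call. = FALSE)
  }
  structure(list(n = as.integer(n), proportions = proportions,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 template = template,
                 cfl2_angle_ranges = cfl2_angle_ranges),
            class = "cohort_config")
}

# Largest-remainder allocation of n among proportions, internal.
largest_remainder <- function(n, proportions) {
  quota <- n * proportions
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(quota - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  as.integer(counts)
}

# Category angle intervals for single-bundle draws, internal.
CATEGORY_INTERVALS <- rbind(CFL20 = c(20, 30), CFL30 = c(30, 40),
                            CFL40 = c(40, 50), CFL50 = c(50, 60))

#' Sample a synthetic cohort
#'
#' Allocates category counts deterministically by largest remainder (the
#' default configuration at n = 81 gives exactly 14/22/29/15/1), draws each
#' single-bundle specimen's running angle uniformly within its category
#' interval, builds CFL2 specimens as two crossing bundles, and perturbs
#' every landmark with digitizer noise.  Identical configurations
#' (including the seed) produce identical cohorts.
#'
#' @param config a [cohort_config()].
#' @return List of specimens; each is a list with `id`, `category` (true,
#'   by construction), `angle_deg` (bundle-1 true angle), `angles_deg`
#'   (all true bundle angles) and `landmarks` (noisy).
#' @export
sample_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stop("expected a 'cohort_config'", call. = FALSE)
  }
  set.seed(config$seed)
  counts <- largest_remainder(config$n, config$proportions)
  categories <- rep(cfl_categories(), counts)
  lapply(seq_along(categories), function(i) {
    cat_i <- categories[i]
    if (cat_i == "CFL2") {
      r <- config$cfl2_angle_ranges
      angles <- c(stats::runif(1, r[1, 1], r[1, 2]),
                  stats::runif(1, r[2, 1], r[2, 2]))
      lm <- make_two_bundle_cfl(config$template, angles[1], angles[2])
    } else {
      iv <- CATEGORY_INTERVALS[cat_i, ]
      angles <- stats::runif(1, iv[1], iv[2])
      lm <- make_cfl_at_angle(config$template, angles)
    }
    if (config$noise_sd > 0) lm <- perturb_landmarks(lm, config$noise_sd)
    list(id = i, category = cat_i, angle_deg = angles[1],
         angles_deg = angles, landmarks = lm)
  })
}
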