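# Named anatomical landmark sets.  A landmark set is a data.frame with one
# row per named 3D point and a body-segment tag saying which rigid segment
# the point moves with (fibula-fixed points include the tibia-fixed leg
# landmarks; the distinction does not matter for a two-hinge model).

LANDMARK_SEGMENTS <- c("fibula", "talus", "calcaneus")

REQUIRED_LANDMARKS <- c(
  fibula_shaft_proximal       = "fibula",
  lateral_malleolus_inferior  = "fibula",
  medial_malleolus_inferior   = "fibula",
  calcaneal_tuberosity_lateral = "calcaneus",
  talar_head_midpoint         = "talus",
  cfl_origin                  = "fibula",
  cfl_insertion               = "calcaneus"
)

SECOND_BUNDLE_LANDMARKS <- c(
  cfl_origin_2    = "fibula",
  cfl_insertion_2 = "calcaneus"
)

#' Landmark names required of every specimen
#'
#' @return Named character vector: landmark name -> expected segment tag.
#'   The optional second-bundle names (`cfl_origin_2`, `cfl_insertion_2`)
#'   are not included.
#' @export
required_landmark_names <- function() REQUIRED_LANDMARKS

#' Construct and validate an ankle landmark set
#'
#' @param name character vector of landmark names.
#' @param segment character vector of segment tags, each one of
#'   `"fibula"`, `"talus"`, `"calcaneus"`.
#' @param x,y,z numeric coordinates in mm.  The canonical frame is
#'   right-handed with, for a right foot, +x anterior, +y proximal and
#'   +z lateral; analysis functions are frame-invariant so any rigidly
#'   transformed frame is equally valid.
#' @return An object of class `ankle_landmarks` (a data.frame).
#' @export
ankle_landmarks <- function(name, segment, x, y, z) {
  df <- data.frame(name = as.character(name), segment = as.character(segment),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   stringsAsFactors = FALSE)
  validate_ankle_landmarks(df)
}

validate_ankle_landmarks <- function(df) {
  if (!all(c("name", "segment", "x", "y", "z") %in% names(df))) {
    stop("landmark set must have columns name, segment, x, y, z",
         call. = FALSE)
  }
  if (anyDuplicated(df$name)) {
    stop("duplicated landmark names: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
         call. = FALSE)
  }
  bad_seg <- setdiff(unique(df$segment), LANDMARK_SEGMENTS)
  if (length(bad_seg)) {
    stop("unknown segment tag(s): ", paste(bad_seg, collapse = ", "),
         "; allowed: ", paste(LANDMARK_SEGMENTS, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)) || !all(is.finite(df$z))) {
    stop("landmark coordinates must all be finite", call. = FALSE)
  }
  missing <- setdiff(names(REQUIRED_LANDMARKS), df$name)
  if (length(missing)) {
    stop("missing required landmark(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  second <- names(SECOND_BUNDLE_LANDMARKS) %in% df$name
  if (xor(second[1], second[2])) {
    stop("second-bundle landmarks must be present either both or neither ",
         "(cfl_origin_2, cfl_insertion_2)", call. = FALSE)
  }
  class(df) <- c("ankle_landmarks", "data.frame")
  df
}

#' Extract a landmark's coordinates
#'
#' @param landmarks an [ankle_landmarks()] set.
#' @param name landmark name.
#' @return Numeric length-3 point (mm).
#' @export
landmark_point <- function(landmarks, name) {
  i <- match(name, landmarks$name)
  if (is.na(i)) stop("no landmark named '", name, "'", call. = FALSE)
  c(landmarks$x[i], landmarks$y[i], landmarks$z[i])
}

# Replace (or add) one landmark, preserving attributes.  Internal.
set_landmark <- function(landmarks, name, segment, p) {
  i <- match(name, landmarks$name)
  if (is.na(i)) {
    row <- data.frame(name = name, segment = segment,
                      x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
    out <- rbind(as.data.frame(landmarks), row)
    attrs <- attributes(landmarks)
    class(out) <- class(landmarks)
    attr(out, "template_config") <- attr(landmarks, "template_config")
    rownames(out) <- NULL
    out
  } else {
    landmarks$x[i] <- p[1]; landmarks$y[i] <- p[2]; landmarks$z[i] <- p[3]
    landmarks$segment[i] <- segment
    landmarks
  }
}

has_second_bundle <- function(landmarks) {
  all(names(SECOND_BUNDLE_LANDMARKS) %in% landmarks$name)
}

# Apply a rigid transform (3x3 rotation matrix R, translation t) to every
# landmark.  Used by tests for frame-invariance; exported because it is
# generally useful for re-expressing digitized data in another frame.

#' Rigidly transform all landmarks
#'
#' Applies `p -> R p + t` to every landmark coordinate.
#'
#' @param landmarks an [ankle_landmarks()] set.
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric length-3 translation (mm).
#' @return The transformed landmark set.
#' @export
transform_landmarks <- function(landmarks, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(landmarks[, c("x", "y", "z")])
  new <- xyz %*% t(rotation)
  new <- sweep(new, 2, as.numeric(translation), "+")
  landmarks$x <- new[, 1]; landmarks$y <- new[, 2]; landmarks$z <- new[, 3]
  landmarks
}
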