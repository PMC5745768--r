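# Exact 3D primitives: points, unit directions, axes in space, rotation of
# points about an arbitrary axis, lengths and angles.  All angles at the
# public interface are in degrees; coordinates are in millimetres.

#' Construct an axis line in space
#'
#' An axis is an anchor point together with a unit direction.  The direction
#' supplied is normalised; a (near-)zero direction is rejected because it
#' does not define a line.
#'
#' @param anchor numeric length-3 point on the axis (mm).
#' @param direction numeric length-3 direction; need not be unit length.
#' @return An object of class `axis_line` with fields `anchor` and
#'   `direction` (unit norm).
#' @examples
#' axis_line(c(0, 0, 0), c(0, 0, 2))
#' @export
axis_line <- function(anchor, direction) {
  anchor <- as.numeric(anchor)
  direction <- as.numeric(direction)
  if (length(anchor) != 3L || length(direction) != 3L ||
      !all(is.finite(anchor)) || !all(is.finite(direction))) {
    stop("axis anchor and direction must be finite length-3 numerics",
         call. = FALSE)
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) {
    stop("degenerate axis: direction has (near-)zero length", call. = FALSE)
  }
  structure(list(anchor = anchor, direction = direction / nrm),
            class = "axis_line")
}

#' @export
print.axis_line <- function(x, ...) {
  cat(sprintf("axis: anchor (%.3f, %.3f, %.3f) mm, direction (%.6f, %.6f, %.6f)\n",
              x$anchor[1], x$anchor[2], x$anchor[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

# cross product, internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * (pi / 180)
rad2deg <- function(x) x * (180 / pi)

#' Rotate a point about an arbitrary axis
#'
#' Rodrigues rotation of a point about an axis line.  Positive angles follow
#' the right-hand rule about the axis direction.
#'
#' @param p numeric length-3 point (mm).
#' @param axis an [axis_line()].
#' @param angle_deg rotation angle in degrees.
#' @return The rotated point (numeric length-3).
#' @examples
#' rotate_point_about_axis(c(1, 0, 0), axis_line(c(0, 0, 0), c(0, 0, 1)), 90)
#' @export
rotate_point_about_axis <- function(p, axis, angle_deg) {
  if (!inherits(axis, "axis_line")) {
    stop("invalid axis: expected an 'axis_line' object", call. = FALSE)
  }
  k <- axis$direction
  if (abs(sqrt(sum(k^2)) - 1) > 1e-9) {
    stop("invalid axis: direction is not unit length", call. = FALSE)
  }
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p))) {
    stop("point must be a finite length-3 numeric", call. = FALSE)
  }
  if (!is.finite(angle_deg)) stop("angle must be finite", call. = FALSE)
  th <- deg2rad(angle_deg)
  v <- p - axis$anchor
  axis$anchor + v * cos(th) + cross3(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

# Rotate an n x 3 coordinate matrix about an axis (vectorised Rodrigues).
rotate_points_about_axis <- function(xyz, axis, angle_deg) {
  k <- axis$direction
  th <- deg2rad(angle_deg)
  v <- sweep(xyz, 2, axis$anchor)
  kv <- as.numeric(v %*% k)
  kxv <- cbind(k[2] * v[, 3] - k[3] * v[, 2],
               k[3] * v[, 1] - k[1] * v[, 3],
               k[1] * v[, 2] - k[2] * v[, 1])
  out <- v * cos(th) + kxv * sin(th) + outer(kv * (1 - cos(th)), k)
  sweep(out, 2, axis$anchor, "+")
}

#' Euclidean distance between two points
#'
#' @param p,q numeric length-3 points (mm).
#' @return Distance in mm.
#' @examples
#' segment_length(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
segment_length <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != 3L || length(q) != 3L ||
      !all(is.finite(p)) || !all(is.finite(q))) {
    stop("points must be finite length-3 numerics", call. = FALSE)
  }
  sqrt(sum((p - q)^2))
}

#' Angle between two directions
#'
#' Returns the unsigned 3D angle between two directions in degrees, in
#' \[0, 180\].  Computed with `atan2(|u x v|, u . v)`, which is numerically
#' stable for nearly parallel directions.
#'
#' @param u,v numeric length-3 directions (any non-zero length).
#' @return Angle in degrees.
#' @examples
#' angle_between_directions(c(1, 0, 0), c(0, 1, 0))  # 90
#' @export
angle_between_directions <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (!all(is.finite(u)) || !all(is.finite(v)) || nu < 1e-12 || nv < 1e-12) {
    stop("invalid direction: zero length or non-finite", call. = FALSE)
  }
  u <- u / nu
  v <- v / nv
  rad2deg(atan2(sqrt(sum(cross3(u, v)^2)), sum(u * v)))
}

# Perpendicular distance from a point to an axis line, internal.
point_axis_distance <- function(p, axis) {
  v <- as.numeric(p) - axis$anchor
  sqrt(sum(cross3(v, axis$direction)^2))
}
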