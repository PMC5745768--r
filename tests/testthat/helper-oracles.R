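# Independent oracles used across tests.

# Rotation oracle: rotate p about (anchor, unit k) by theta degrees via an
# explicitly constructed orthonormal basis (k, a, b) and 2D rotation of the
# in-plane coordinates -- a construction independent of the Rodrigues
# formula used by the implementation.
oracle_rotate <- function(p, anchor, k, theta_deg) {
  k <- k / sqrt(sum(k^2))
  seedv <- if (abs(k[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  a <- seedv - sum(seedv * k) * k
  a <- a / sqrt(sum(a^2))
  b <- c(k[2] * a[3] - k[3] * a[2],
         k[3] * a[1] - k[1] * a[3],
         k[1] * a[2] - k[2] * a[1])
  v <- p - anchor
  va <- sum(v * a); vb <- sum(v * b); vk <- sum(v * k)
  th <- theta_deg * pi / 180
  anchor + (va * cos(th) - vb * sin(th)) * a +
    (va * sin(th) + vb * cos(th)) * b + vk * k
}

# Pearson chi-squared statistic computed directly from the definition.
oracle_pearson <- function(counts) {
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  list(statistic = sum((counts - expected)^2 / expected),
       df = (nrow(counts) - 1) * (ncol(counts) - 1))
}

# Random unit vector.
runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Random rigid transform (rotation matrix + translation).
random_rigid <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
                2*(x*y + w*z), 1 - 2*(x^2+z^2), 2*(y*z - w*x),
                2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2+y^2)),
              3, 3, byrow = TRUE)
  list(R = R, t = stats::rnorm(3, 0, 50))
}
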