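# Shared independent oracles and small fixtures, all built in code.

# O(n^2) brute-force survivor set for radius outlier removal
brute_radius_survivors <- function(xyz, radius, min_neighbors) {
  n <- nrow(xyz)
  d2 <- as.matrix(stats::dist(xyz))^2
  counts <- rowSums(d2 <= radius^2) - 1L   # exclude self
  which(counts >= min_neighbors)
}

# dense polygonal (chord-sum) perimeter of an ellipse with half axes a, b
chord_ellipse_perimeter <- function(a, b, m = 1e6) {
  t <- seq(0, 2 * pi, length.out = m + 1)
  sum(sqrt(diff(a * cos(t))^2 + diff(b * sin(t))^2))
}

# random rotation matrix through the package's own Euler parametrization is
# avoided here; build one from QR of a Gaussian matrix instead
random_rotation <- function() {
  qd <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qd)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# angle (radians) between two rotations
rotation_angle <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(min(1, max(-1, (tr - 1) / 2)))
}

# nearest-neighbour distances from each row of A to the rows of B (chunked
# brute force)
nn_dists <- function(A, B, chunk = 500L) {
  out <- numeric(nrow(A))
  Bt <- t(B)
  b2 <- colSums(Bt^2)
  for (s in seq(1L, nrow(A), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(A))
    Ak <- A[idx, , drop = FALSE]
    d2 <- outer(rowSums(Ak^2), b2, `+`) - 2 * Ak %*% Bt
    out[idx] <- sqrt(pmax(0, apply(d2, 1L, min)))
  }
  out
}

# horizontal floor plane in the package's plane representation
floor_plane_z0 <- list(normal = c(0, 0, 1), offset = 0)

# the five cleaned example records of the study's record sheet and their
# normalized form (4-decimal print precision)
example_records_raw <- matrix(c(
  110, 115, 107, 120, 63, 1, 0, 1, 0, 193, 113.5,
  105, 116, 106, 119, 63, 1, 0, 1, 0, 192, 111.4,
  109, 120, 104, 125, 63, 1, 0, 1, 0, 194, 114.6,
  105, 112, 100, 123, 63, 1, 0, 1, 0, 192, 111.8,
  107, 116, 106, 118, 63, 1, 0, 1, 0, 189, 114.2),
  nrow = 5, byrow = TRUE,
  dimnames = list(NULL, c("chest", "abdomen", "waist", "length", "height",
                          "female", "male", "s21", "s23", "age", "weight")))

example_records_normalized <- matrix(c(
  0.3390, 0.3544, 0.3298, 0.3698, 0.1942, 0.0031, 0.0000, 0.0031, 0.0000, 0.5948,
  0.3270, 0.3612, 0.3301, 0.3706, 0.1962, 0.0031, 0.0000, 0.0031, 0.0000, 0.5979,
  0.3325, 0.3660, 0.3173, 0.3813, 0.1922, 0.0031, 0.0000, 0.0031, 0.0000, 0.5918,
  0.3287, 0.3506, 0.3131, 0.3851, 0.1972, 0.0031, 0.0000, 0.0031, 0.0000, 0.6011,
  0.3337, 0.3618, 0.3306, 0.3680, 0.1965, 0.0031, 0.0000, 0.0031, 0.0000, 0.5895),
  nrow = 5, byrow = TRUE,
  dimnames = list(NULL, c("chest", "abdomen", "waist", "length", "height",
                          "female", "male", "s21", "s23", "age")))

# feature_table built directly from the example raw records
example_feature_table <- function() {
  df <- as.data.frame(example_records_raw)
  structure(df, normalized = FALSE, class = c("feature_table", "data.frame"))
}
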