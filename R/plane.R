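# Shared plane machinery: total-least-squares fits and RANSAC plane search.
# Planes are stored as list(normal = unit 3-vector, offset = scalar) with the
# implicit equation normal . p = offset.

plane_fit_tls <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2L, ctr), nu = 0)
  normal <- sv$v[, 3L]
  list(normal = normal, offset = sum(normal * ctr))
}

plane_distance <- function(xyz, plane) {
  abs(as.vector(xyz %*% plane$normal) - plane$offset)
}

# signed height with the plane normal treated as "up"
plane_height <- function(xyz, plane) {
  as.vector(xyz %*% plane$normal) - plane$offset
}

# Classic 3-point-hypothesis RANSAC with inlier-count scoring, adaptive
# iteration cap (0.9999 confidence) and a least-squares refit on the winning
# consensus set. Deterministic for a fixed seed.
ransac_plane <- function(xyz, distance_threshold, n_iterations, seed,
                         confidence = 0.9999) {
  n <- nrow(xyz)
  if (n < 3L) stop("degenerate geometry: need at least 3 points for a plane")
  with_seed(seed, {
    best_cnt <- 0L
    best_plane <- NULL
    it <- 0L
    max_it <- n_iterations
    while (it < max_it) {
      it <- it + 1L
      s <- sample.int(n, 3L)
      p1 <- xyz[s[1L], ]; v1 <- xyz[s[2L], ] - p1; v2 <- xyz[s[3L], ] - p1
      nv <- c(v1[2] * v2[3] - v1[3] * v2[2],
              v1[3] * v2[1] - v1[1] * v2[3],
              v1[1] * v2[2] - v1[2] * v2[1])
      nn <- sqrt(sum(nv^2))
      if (nn < 1e-14) next
      hyp <- list(normal = nv / nn, offset = sum(nv / nn * p1))
      cnt <- sum(plane_distance(xyz, hyp) <= distance_threshold)
      if (cnt > best_cnt) {
        best_cnt <- cnt
        best_plane <- hyp
        w <- cnt / n
        need <- if (w >= 1) 1 else log(1 - confidence) / log(1 - w^3)
        max_it <- min(n_iterations, ceiling(need))
      }
    }
    if (is.null(best_plane)) stop("no plane found: all hypotheses degenerate")
    inl <- plane_distance(xyz, best_plane) <= distance_threshold
    refit <- plane_fit_tls(xyz[inl, , drop = FALSE])
    inl <- plane_distance(xyz, refit) <= distance_threshold
    list(plane = refit, inliers = inl, n_inliers = sum(inl))
  })
}

# Trimmed refinement used for calibration-grade fits: iteratively refit on
# points within 2.5 robust sigmas so edge points from adjacent cuboid faces
# cannot tilt the plane. Exact for noiseless faces.
plane_fit_trimmed <- function(xyz, n_rounds = 3L) {
  fit <- plane_fit_tls(xyz)
  keep <- rep(TRUE, nrow(xyz))
  for (i in seq_len(n_rounds)) {
    res <- plane_height(xyz, fit)
    sigma <- 1.4826 * stats::mad(res[keep], center = 0)
    keep_new <- abs(res) <= max(2.5 * sigma, 1e-9)
    if (sum(keep_new) < 3L) break
    keep <- keep_new
    fit <- plane_fit_tls(xyz[keep, , drop = FALSE])
  }
  fit
}
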