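# Independent oracles used to validate the package's own geometry and
# distance computations.  These deliberately use brute force / exhaustive
# scans, not the implementation under test.

# Exhaustive-rotation width scan: the width of the point set perpendicular
# to each direction, scanned over orientations in fine angular steps.
brute_min_width <- function(pts, step_deg = 0.1) {
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  min(vapply(th, function(a) {
    proj <- pts[, 1] * (-sin(a)) + pts[, 2] * cos(a)
    max(proj) - min(proj)
  }, numeric(1)))
}

# Brute-force exact Euclidean distance transform: per foreground pixel, the
# minimum centre-to-centre distance to any background pixel.
brute_edt <- function(mask) {
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  }
  out
}

# Random convex polygon: convex hull of n random points, optionally
# anisotropically stretched and rotated so widths differ across directions.
random_convex_polygon <- function(n = 12) {
  pts <- cbind(runif(n, 0, 40), runif(n, 0, 40))
  pts[, 1] <- pts[, 1] * runif(1, 0.3, 1)
  a <- runif(1, 0, pi)
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  pts <- pts %*% R
  pts[grDevices::chull(pts), , drop = FALSE]
}

# Direct evaluation of the geNorm stability definition for one gene:
# mean over other genes of sd across samples of log2 pairwise ratios.
brute_genorm_m <- function(qmat) {
  vapply(seq_len(ncol(qmat)), function(j) {
    others <- setdiff(seq_len(ncol(qmat)), j)
    mean(vapply(others, function(k) {
      r <- log2(qmat[, j] / qmat[, k])
      sqrt(sum((r - mean(r))^2) / (length(r) - 1))
    }, numeric(1)))
  }, numeric(1))
}
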