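# Internal helpers shared across the pipeline stages.

#' @importFrom stats rnorm rpois runif sd quantile lm coef residuals aggregate setNames
#' @importFrom utils write.csv read.csv head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  All package randomness goes through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-stream seeds: one master seed fans out to independent
# stage seeds.  Kept well below 2^31.
substream <- function(seed, k) {
  (abs(as.integer(seed)) %% 1000003L) * 1024L + as.integer(k)
}

# Otsu threshold on a numeric vector.  Degenerate (constant) input returns 0,
# so that strictly-positive comparison `x > thr` marks a saturated channel
# fully positive and an all-zero channel fully negative.
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x[is.finite(x)])
  if (length(x) == 0L) stop("otsu_threshold: no finite values")
  r <- range(x)
  if (diff(r) <= .Machine$double.eps * max(1, abs(r[2]))) return(0)
  as.numeric(EBImage::otsu(EBImage::Image(matrix(x, ncol = 1L)),
                           range = r, levels = levels))
}

# Positivity mask with the degenerate-channel convention above.
positive_mask <- function(x, threshold_method = c("otsu", "fixed"),
                          fixed_threshold = NULL, within = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed") {
    if (is.null(fixed_threshold)) stop("fixed threshold method requires `fixed_threshold`")
    thr <- fixed_threshold
  } else {
    vals <- if (is.null(within)) x else x[within]
    thr <- otsu_threshold(vals)
  }
  list(mask = x > thr, threshold = thr)
}

# Mean filter over a disc neighbourhood of the given radius (pixels).
local_mean_disc <- function(mat, radius_px) {
  radius_px <- max(1L, as.integer(round(radius_px)))
  side <- 2L * radius_px + 1L
  br <- EBImage::makeBrush(side, shape = "disc")
  br <- br / sum(br)
  out <- EBImage::filter2(EBImage::Image(mat), br, boundary = "replicate")
  matrix(EBImage::imageData(out), nrow = nrow(mat))
}

# Dilate a logical matrix with a disc brush of given radius (pixels).
dilate_disc <- function(mask, radius_px) {
  radius_px <- as.integer(round(radius_px))
  if (radius_px < 1L) return(mask)
  out <- EBImage::dilate(EBImage::Image(mask * 1), EBImage::makeBrush(2L * radius_px + 1L, "disc"))
  matrix(EBImage::imageData(out) > 0, nrow = nrow(mask))
}

geometric_mean <- function(x) exp(mean(log(x)))

# md5 of the canonical JSON serialization of a config list (base tools only).
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tf)
  unname(tools::md5sum(tf))
}

stop_myohisto <- function(msg, class) {
  stop(structure(class = c(class, "myohisto_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
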