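# Per-fibre shape metrics: area, perimeter, circularity, minimum/maximum
# Feret diameter, and the circularity exclusion filter used to drop
# longitudinally/obliquely sectioned fibres before size statistics.

# Convex hull polygon (0-based pixel-corner vertices, x right / y down) of a
# logical mask.  Every foreground pixel contributes its four corners, so a
# single pixel yields a unit square rather than a degenerate point.
mask_to_hull <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask_to_hull: empty region")
  x <- c(idx[, 2] - 1, idx[, 2], idx[, 2] - 1, idx[, 2])
  y <- c(idx[, 1] - 1, idx[, 1] - 1, idx[, 1], idx[, 1])
  pts <- unique(cbind(x, y))
  pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
}

#' Feret diameters of a region
#'
#' Minimum and maximum Feret diameter (calliper widths) of a binary mask or
#' polygon.  The minimum is computed by rotating callipers over the convex
#' hull: for each hull edge, the width is the largest vertex distance to the
#' edge's supporting line, and the minimum Feret diameter is the smallest
#' such width.  Masks are converted to hull polygons of pixel-corner
#' vertices before measurement, so concavities never affect the result.
#'
#' A degenerate (collinear) polygon gets `min_feret` equal to its maximum
#' extent together with `degenerate = TRUE`.
#'
#' @param region logical matrix (mask) or 2-column vertex matrix (polygon,
#'   pixel units).
#' @param pixel_size_um calibration applied to the result (default 1,
#'   i.e. pixel units).
#' @return list with `min_feret_um`, `max_feret_um`, `degenerate`, `hull`.
#' @export
feret_diameters <- function(region, pixel_size_um = 1) {
  poly <- if (is.matrix(region) && ncol(region) == 2L && !is.logical(region))
    region else mask_to_hull(region)
  hull <- poly[grDevices::chull(poly[, 1], poly[, 2]), , drop = FALSE]
  n <- nrow(hull)
  dmax <- sqrt(max(outer(poly[, 1], poly[, 1], "-")^2 +
                   outer(poly[, 2], poly[, 2], "-")^2))
  if (n < 3L) {
    return(list(min_feret_um = dmax * pixel_size_um,
                max_feret_um = dmax * pixel_size_um,
                degenerate = TRUE, hull = hull))
  }
  widths <- vapply(seq_len(n), function(i) {
    a <- hull[i, ]; b <- hull[if (i == n) 1L else i + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    max(abs((hull[, 1] - a[1]) * nrm[1] + (hull[, 2] - a[2]) * nrm[2]))
  }, numeric(1))
  w <- min(widths)
  degen <- !is.finite(w) || w <= 1e-12
  list(min_feret_um = (if (degen) dmax else w) * pixel_size_um,
       max_feret_um = dmax * pixel_size_um,
       degenerate = degen, hull = hull)
}

#' Minimum Feret diameter
#'
#' @inheritParams feret_diameters
#' @return length in micrometres (or pixels at the default calibration).
#' @export
min_feret <- function(region, pixel_size_um = 1) {
  feret_diameters(region, pixel_size_um)$min_feret_um
}

# Sub-pixel boundary perimeter: object contour from EBImage::ocontour,
# smoothed with a 3-point circular moving average.  Raw 8-connected contours
# overestimate staircase edges, which would bias circularity low and distort
# the 0.3 exclusion cutoff; the smoothing recovers near-polygonal lengths.
contour_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  sum(vapply(oc, function(p) {
    n <- nrow(p)
    if (n < 3L) return(0)
    ps <- (p + p[c(2:n, 1L), ] + p[c(n, 1:(n - 1L)), ]) / 3
    d <- ps - ps[c(2:n, 1L), , drop = FALSE]
    sum(sqrt(rowSums(d^2)))
  }, numeric(1)))
}

#' Circularity
#'
#' The classical shape factor `4 * pi * A / P^2`: 1 for a circle, smaller
#' for elongated shapes.  Raw values slightly above 1 (a discretization
#' artefact) are clipped to 1 and flagged.
#'
#' @param area_um2 region area (positive).
#' @param perimeter_um region perimeter (positive), measured with the same
#'   estimator throughout the pipeline.
#' @return circularity in `[0, 1]`, with attribute `clipped` when the raw
#'   value exceeded 1.
#' @export
circularity <- function(area_um2, perimeter_um) {
  if (any(area_um2 <= 0) || any(perimeter_um <= 0))
    stop("circularity: area and perimeter must be positive")
  raw <- 4 * pi * area_um2 / perimeter_um^2
  out <- pmin(raw, 1)
  attr(out, "clipped") <- raw > 1
  out
}

#' Per-fibre morphometry table
#'
#' Computes area, perimeter, circularity, Feret diameters and centroid for
#' every fibre in a label map, flagging border-touching fibres (their Feret
#' diameters are censored by the field edge).
#'
#' @param fibers a [fiber_label_map()].
#' @return data frame with one row per fibre: `fiber_id`, `area_um2`,
#'   `perimeter_um`, `circularity`, `min_feret_um`, `max_feret_um`,
#'   `centroid_x_um`, `centroid_y_um`, `border_touching`, `degenerate`.
#' @export
fiber_morphometry <- function(fibers) {
  stopifnot(inherits(fibers, "fiber_label_map"))
  ps <- fibers$pixel_size_um
  ids <- fiber_ids(fibers)
  lab <- fibers$labels
  idx <- which(lab > 0L, arr.ind = TRUE)
  lv <- lab[lab > 0L]
  rows <- split(idx[, 1], lv)
  cols <- split(idx[, 2], lv)
  out <- lapply(as.character(ids), function(key) {
    r <- rows[[key]]; c <- cols[[key]]
    rr <- range(r); cr <- range(c)
    sub <- matrix(FALSE, rr[2] - rr[1] + 3L, cr[2] - cr[1] + 3L)
    sub[cbind(r - rr[1] + 2L, c - cr[1] + 2L)] <- TRUE
    fer <- feret_diameters(sub, ps)
    per <- contour_perimeter(sub) * ps
    area <- length(r) * ps^2
    data.frame(fiber_id = as.integer(key),
               area_um2 = area,
               perimeter_um = per,
               circularity = as.numeric(circularity(area, per)),
               min_feret_um = fer$min_feret_um,
               max_feret_um = fer$max_feret_um,
               centroid_x_um = (mean(c) - 0.5) * ps,
               centroid_y_um = (mean(r) - 0.5) * ps,
               border_touching = as.integer(key) %in% fibers$border_ids,
               degenerate = fer$degenerate)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Circularity exclusion filter
#'
#' Marks fibres with circularity strictly below the threshold as excluded
#' (reason `"circularity"`), used to filter out longitudinally and obliquely
#' sectioned myofibers before CNF and Feret statistics.  Border-touching
#' fibres are excluded too (reason `"border"`) unless `exclude_border =
#' FALSE`.  A fibre at exactly the threshold is retained.
#'
#' @param metrics data frame from [fiber_morphometry()].
#' @param threshold circularity cutoff (default 0.3).
#' @param exclude_border also exclude border-touching fibres (default TRUE).
#' @return `metrics` with added `excluded` (logical) and `exclusion_reason`
#'   (`NA`, `"circularity"` or `"border"`).
#' @export
apply_circularity_filter <- function(metrics, threshold = 0.3,
                                     exclude_border = TRUE) {
  reason <- rep(NA_character_, nrow(metrics))
  circ <- metrics$circularity < threshold
  reason[circ] <- "circularity"
  if (exclude_border) reason[metrics$border_touching & is.na(reason)] <- "border"
  metrics$excluded <- !is.na(reason)
  metrics$exclusion_reason <- reason
  metrics
}

#' Fibre-size distribution summary
#'
#' Mean, SD and quantiles of the minimum Feret diameter over retained
#' fibres.  SD is reported as missing for a single fibre; an empty retained
#' set raises an explicit empty-summary condition.
#'
#' @param metrics data frame from [apply_circularity_filter()] (rows with
#'   `excluded = TRUE` are dropped; a table without the `excluded` column is
#'   used as-is).
#' @return list with `n`, `mean_min_feret_um`, `sd_min_feret_um`,
#'   `quantiles_um` (5/25/50/75/95%), and the retained per-fibre table.
#' @export
fiber_size_summary <- function(metrics) {
  kept <- if ("excluded" %in% names(metrics)) metrics[!metrics$excluded, , drop = FALSE]
          else metrics
  if (nrow(kept) == 0L)
    stop_myohisto("fiber_size_summary: no retained fibres", "myohisto_empty_summary")
  x <- kept$min_feret_um
  list(n = length(x),
       mean_min_feret_um = mean(x),
       sd_min_feret_um = if (length(x) > 1L) sd(x) else NA_real_,
       quantiles_um = quantile(x, c(.05, .25, .5, .75, .95), names = TRUE),
       fibers = kept)
}
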