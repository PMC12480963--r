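# Fibre and nucleus segmentation.
#
# Fibre detection is an interior-seeded watershed on the laminin ridge
# landscape: the laminin-positive boundary band is thresholded, fibre
# interiors are the low-laminin basins it encloses, and a watershed on the
# Euclidean distance map of the interiors splits any basins merged by leaky
# boundaries.  The algorithm is fully deterministic.

#' Segmentation parameters
#'
#' @param smoothing_sigma_um Gaussian smoothing applied to channels before
#'   thresholding, in micrometres (default 1).
#' @param boundary_threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold intensity threshold, required iff method is
#'   `"fixed"`.
#' @param min_fiber_area_um2 fibres smaller than this are dropped
#'   (default 80).
#' @param min_nucleus_area_um2 nuclei smaller than this are dropped
#'   (default 8).
#' @param seed_min_distance_um minimum distance between watershed seeds,
#'   used as the watershed tolerance scale (default 4).
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma_um = 1,
                                boundary_threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_fiber_area_um2 = 80,
                                min_nucleus_area_um2 = 8,
                                seed_min_distance_um = 4) {
  boundary_threshold_method <- match.arg(boundary_threshold_method)
  if (boundary_threshold_method == "fixed" && is.null(fixed_threshold))
    stop("segmentation_params: fixed_threshold required with method 'fixed'")
  if (boundary_threshold_method == "otsu" && !is.null(fixed_threshold))
    stop("segmentation_params: fixed_threshold only allowed with method 'fixed'")
  stopifnot(min_fiber_area_um2 > 0, min_nucleus_area_um2 > 0,
            seed_min_distance_um > 0, smoothing_sigma_um >= 0)
  structure(list(smoothing_sigma_um = smoothing_sigma_um,
                 boundary_threshold_method = boundary_threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_fiber_area_um2 = min_fiber_area_um2,
                 min_nucleus_area_um2 = min_nucleus_area_um2,
                 seed_min_distance_um = seed_min_distance_um),
            class = "segmentation_params")
}

smooth_px <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(mat), sigma = sigma_px)),
         nrow = nrow(mat))
}

#' Tissue mask
#'
#' Foreground tissue from total signal (fluorescence, Otsu threshold) or
#' total optical density (brightfield RGB, fixed OD threshold -- brightfield
#' histograms are typically multi-modal over glass / cytoplasm / nuclei,
#' where Otsu would latch onto the wrong valley): threshold, fill enclosed
#' holes, drop specks. A blank image raises an explicit no-tissue condition
#' rather than returning an empty mask silently.
#'
#' @param image a [channel_image], an RGB array, or a plain matrix with
#'   `pixel_size_um` supplied.
#' @param min_speck_area_um2 connected foreground components smaller than
#'   this are removed (default 200).
#' @param od_threshold summed-OD cutoff separating stained tissue from
#'   glass in brightfield input (default 0.15).
#' @param pixel_size_um calibration override for uncalibrated arrays.
#' @return list with logical `mask`, `tissue_area_um2`, `pixel_size_um`.
#' @export
tissue_mask <- function(image, min_speck_area_um2 = 200, od_threshold = 0.15,
                        pixel_size_um = NULL) {
  is_bf <- FALSE
  if (inherits(image, "channel_image")) {
    sig <- image$pixels
    ps <- image$pixel_size_um
  } else if (length(dim(image)) == 3L) {
    ps <- pixel_size_um %||% attr(image, "pixel_size_um")
    od <- rgb_to_od(image)
    sig <- od[, , 1] + od[, , 2] + od[, , 3]
    is_bf <- TRUE
  } else {
    sig <- as.matrix(image)
    ps <- pixel_size_um %||% attr(image, "pixel_size_um")
  }
  if (is.null(ps)) stop("tissue_mask: pixel size required")
  if (diff(range(sig)) <= 1e-9 * max(1, abs(max(sig))))
    stop_myohisto("tissue_mask: blank image, no tissue detected", "myohisto_no_tissue")
  thr <- if (is_bf) od_threshold else otsu_threshold(sig)
  mask <- sig > thr
  mask <- matrix(EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0,
                 nrow = nrow(mask))
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  areas <- table(lab[lab > 0])
  keep <- as.integer(names(areas)[areas * ps^2 >= min_speck_area_um2])
  mask <- matrix(as.vector(lab) %in% keep, nrow = nrow(mask))
  if (!any(mask))
    stop_myohisto("tissue_mask: no tissue above the speck threshold", "myohisto_no_tissue")
  list(mask = mask, tissue_area_um2 = sum(mask) * ps^2, pixel_size_um = ps)
}

#' Segment muscle fibres from the laminin channel
#'
#' Smooths the laminin channel, thresholds the boundary ridge, and labels
#' the enclosed low-laminin basins via a watershed on the Euclidean distance
#' map of the interiors.  Boundary (laminin band) pixels are assigned to
#' background label 0.  Fibres below the minimum area are removed; fibres
#' touching the image border are kept but flagged in `border_ids`.
#'
#' @param laminin [channel_image] of the laminin stain.
#' @param params [segmentation_params()].
#' @param tissue optional logical tissue mask restricting the segmentation;
#'   computed from the laminin band when omitted.
#' @return A [fiber_label_map()].
#' @export
segment_fibers <- function(laminin, params = segmentation_params(),
                           tissue = NULL) {
  stopifnot(inherits(laminin, "channel_image"))
  ps <- laminin$pixel_size_um
  sig <- smooth_px(laminin$pixels, params$smoothing_sigma_um / ps)
  if (diff(range(sig)) <= 1e-9 * max(1, abs(max(sig))))
    stop_myohisto("segment_fibers: constant laminin channel", "myohisto_quality")
  thr <- if (params$boundary_threshold_method == "fixed") params$fixed_threshold
         else otsu_threshold(sig)
  ridge <- sig > thr
  if (is.null(tissue)) {
    # close the ridge band and fill enclosed interiors to get the tissue
    closed <- EBImage::closing(EBImage::Image(ridge * 1), EBImage::makeBrush(5L, "disc"))
    tissue <- matrix(EBImage::imageData(EBImage::fillHull(closed)) > 0,
                     nrow = nrow(ridge))
  }
  interior <- tissue & !ridge
  if (!any(interior))
    stop_myohisto("segment_fibers: no fibre interiors found", "myohisto_quality")
  dm <- EBImage::distmap(EBImage::Image(interior * 1))
  tol <- max(1, params$seed_min_distance_um / ps / 2)
  lab <- EBImage::watershed(dm, tolerance = tol, ext = 1L)
  labels <- matrix(as.integer(EBImage::imageData(lab)), nrow = nrow(interior))
  labels[!interior] <- 0L
  # drop undersized fibres, relabel contiguously
  areas <- tabulate(labels[labels > 0L])
  keep <- which(areas * ps^2 >= params$min_fiber_area_um2)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  border <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
  fiber_label_map(labels, ps, border_ids = sort(border[border > 0L]))
}

#' Segment nuclei from the DAPI channel
#'
#' Threshold plus distance-transform watershed to split touching nuclei;
#' objects below the minimum nucleus area are removed.
#'
#' @param dapi [channel_image] of the DAPI stain.
#' @param params [segmentation_params()].
#' @return list with `labels` (integer matrix) and `centroids`: a data frame
#'   with `nucleus_id`, `row_px`, `col_px` (1-based pixel coordinates),
#'   `x_um`, `y_um` (0-based physical coordinates, x right, y down) and
#'   `area_um2`.
#' @export
segment_nuclei <- function(dapi, params = segmentation_params()) {
  stopifnot(inherits(dapi, "channel_image"))
  ps <- dapi$pixel_size_um
  sig <- smooth_px(dapi$pixels, params$smoothing_sigma_um / ps)
  if (diff(range(sig)) <= 1e-9 * max(1, abs(max(sig))))
    stop_myohisto("segment_nuclei: constant DAPI channel", "myohisto_quality")
  mask <- sig > otsu_threshold(sig)
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1L)
  labels <- matrix(as.integer(EBImage::imageData(lab)), nrow = nrow(mask))
  labels[!mask] <- 0L
  areas <- tabulate(labels[labels > 0L])
  keep <- which(areas * ps^2 >= params$min_nucleus_area_um2)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  idx <- which(labels > 0L, arr.ind = TRUE)
  lv <- labels[labels > 0L]
  if (length(lv) == 0L) {
    cent <- data.frame(nucleus_id = integer(0), row_px = numeric(0),
                       col_px = numeric(0), x_um = numeric(0), y_um = numeric(0),
                       area_um2 = numeric(0))
  } else {
    rows <- tapply(idx[, 1], lv, mean)
    cols <- tapply(idx[, 2], lv, mean)
    n    <- tapply(idx[, 1], lv, length)
    cent <- data.frame(nucleus_id = as.integer(names(rows)),
                       row_px = as.numeric(rows), col_px = as.numeric(cols),
                       x_um = (as.numeric(cols) - 0.5) * ps,
                       y_um = (as.numeric(rows) - 0.5) * ps,
                       area_um2 = as.numeric(n) * ps^2)
    cent <- cent[order(cent$nucleus_id), , drop = FALSE]
    rownames(cent) <- NULL
  }
  list(labels = labels, centroids = cent, pixel_size_um = ps)
}
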