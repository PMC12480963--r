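# Fluorescence marker quantification: per-fibre positivity (IgM, eMyHC),
# per-cell positivity (PDGFRA/FAPs), damage/repair/healthy region
# classification from F4/80 + eMyHC, and region-normalized p-SMAD2 scoring.
#
# Positivity thresholds default to Otsu computed within tissue per channel
# (the degenerate-channel convention of `otsu_threshold` applies: a constant
# channel thresholds at 0, so an all-zero channel scores no positives and a
# saturated one scores everything positive).

check_calibration <- function(marker, fibers) {
  if (abs(marker$pixel_size_um - fibers$pixel_size_um) > 1e-9)
    stop("calibration mismatch between marker channel and fibre map")
}

#' Fraction of marker-positive fibres
#'
#' A fibre is positive when the fraction of its interior pixels above the
#' intensity threshold exceeds `min_positive_area_fraction` (strictly).
#'
#' @param marker [channel_image] of the marker (e.g. IgM, eMyHC).
#' @param fibers a [fiber_label_map()].
#' @param retained_ids fibre ids forming the denominator (default: all
#'   fibres in the map).
#' @param threshold_method `"otsu"` (within fibre pixels) or `"fixed"`.
#' @param fixed_threshold threshold for the fixed method.
#' @param min_positive_area_fraction minimum positive area fraction for a
#'   positive call (default 0.3: whole-fibre sarcoplasmic staining).
#' @return list of class `marker_score`: `marker_name`,
#'   `positive_fiber_ids`, `n_fibers`, `value` (fraction), `threshold_used`.
#' @export
positive_fiber_fraction <- function(marker, fibers, retained_ids = NULL,
                                    threshold_method = c("otsu", "fixed"),
                                    fixed_threshold = NULL,
                                    min_positive_area_fraction = 0.3) {
  stopifnot(inherits(marker, "channel_image"), inherits(fibers, "fiber_label_map"))
  check_calibration(marker, fibers)
  ids <- retained_ids %||% fiber_ids(fibers)
  if (length(ids) == 0L) stop("positive_fiber_fraction: empty fibre set")
  pm <- positive_mask(marker$pixels, threshold_method, fixed_threshold,
                      within = fibers$labels > 0L)
  lv <- fibers$labels[fibers$labels > 0L]
  posv <- pm$mask[fibers$labels > 0L]
  frac <- tapply(posv, lv, mean)
  pos_ids <- as.integer(names(frac))[frac > min_positive_area_fraction]
  pos_ids <- intersect(pos_ids, ids)
  structure(list(marker_name = marker$channel_name,
                 positive_fiber_ids = sort(pos_ids),
                 n_fibers = length(ids),
                 value = length(pos_ids) / length(ids),
                 threshold_used = pm$threshold),
            class = "marker_score")
}

#' Density of marker-positive fibres per square millimetre of tissue
#'
#' @inheritParams positive_fiber_fraction
#' @param tissue logical tissue mask defining the reference area.
#' @return list of class `marker_score` with `value` = positives per mm^2.
#' @export
positive_fiber_density <- function(marker, fibers, tissue,
                                   retained_ids = NULL,
                                   threshold_method = c("otsu", "fixed"),
                                   fixed_threshold = NULL,
                                   min_positive_area_fraction = 0.3) {
  area_mm2 <- mask_area_mm2(tissue, fibers$pixel_size_um)
  if (area_mm2 <= 0) stop("positive_fiber_density: zero tissue area")
  sc <- positive_fiber_fraction(marker, fibers, retained_ids,
                                threshold_method, fixed_threshold,
                                min_positive_area_fraction)
  sc$value <- length(sc$positive_fiber_ids) / area_mm2
  sc$denominator_mm2 <- area_mm2
  sc
}

#' Fraction of marker-positive cells
#'
#' A cell is positive when the mean marker intensity within a fixed-radius
#' disc around its nucleus centroid exceeds the threshold (Otsu over the
#' per-cell means by default). Used for PDGFRA+ fibro-adipogenic
#' progenitors.
#'
#' @param marker [channel_image] of the marker (e.g. PDGFRA).
#' @param nuclei nucleus table with `nucleus_id`, `row_px`, `col_px`.
#' @param radius_um disc radius around the centroid (default 4).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold threshold for the fixed method.
#' @return list of class `marker_score` with `value` = positive-cell
#'   fraction and `positive_cell_ids`.
#' @export
positive_cell_fraction <- function(marker, nuclei, radius_um = 4,
                                   threshold_method = c("otsu", "fixed"),
                                   fixed_threshold = NULL) {
  stopifnot(inherits(marker, "channel_image"))
  if (nrow(nuclei) == 0L) stop("positive_cell_fraction: zero cells")
  threshold_method <- match.arg(threshold_method)
  off <- disc_offsets(radius_um / marker$pixel_size_um)
  px <- marker$pixels
  means <- vapply(seq_len(nrow(nuclei)), function(i) {
    rr <- round(nuclei$row_px[i]) + off$dr
    cc <- round(nuclei$col_px[i]) + off$dc
    ok <- rr >= 1L & rr <= nrow(px) & cc >= 1L & cc <= ncol(px)
    mean(px[cbind(rr[ok], cc[ok])])
  }, numeric(1))
  thr <- if (threshold_method == "fixed") {
    if (is.null(fixed_threshold)) stop("fixed threshold method requires `fixed_threshold`")
    fixed_threshold
  } else otsu_threshold(means)
  pos <- means > thr
  structure(list(marker_name = marker$channel_name,
                 positive_cell_ids = nuclei$nucleus_id[pos],
                 n_cells = nrow(nuclei),
                 value = mean(pos),
                 threshold_used = thr),
            class = "marker_score")
}

#' @export
print.marker_score <- function(x, ...) {
  cat(sprintf("<marker_score> %s: value %.4g (threshold %.4g)\n",
              x$marker_name, x$value, x$threshold_used))
  invisible(x)
}

#' Classify tissue into damage / repair / healthy regions
#'
#' Damage: tissue where the local F4/80-positive area fraction within a disc
#' neighbourhood exceeds its density threshold (macrophage-rich foci).
#' Repair: remaining tissue within or adjacent to eMyHC+ regenerating
#' fibres (configurable adjacency radius). Healthy: the rest. Classes
#' partition the tissue mask, precedence damage > repair > healthy.
#'
#' @param f480 [channel_image] of the F4/80 macrophage marker.
#' @param emyhc [channel_image] of the eMyHC regeneration marker.
#' @param fibers a [fiber_label_map()].
#' @param tissue logical tissue mask.
#' @param f480_radius_um disc radius for local macrophage density
#'   (default 20).
#' @param f480_density_threshold local positive-area fraction above which
#'   tissue is damage (default 0.5, the half-maximum of a solidly
#'   macrophage-infiltrated focus).
#' @param repair_radius_um adjacency radius around eMyHC+ fibres
#'   (default 25).
#' @param min_positive_area_fraction eMyHC fibre-positivity cutoff.
#' @return A [region_class_map()].
#' @export
classify_regions <- function(f480, emyhc, fibers, tissue,
                             f480_radius_um = 20,
                             f480_density_threshold = 0.5,
                             repair_radius_um = 25,
                             min_positive_area_fraction = 0.3) {
  if (is.null(f480) || is.null(emyhc))
    stop("classify_regions: both F4/80 and eMyHC channels are required")
  stopifnot(inherits(f480, "channel_image"), inherits(emyhc, "channel_image"))
  check_calibration(f480, fibers)
  ps <- f480$pixel_size_um
  pm <- positive_mask(f480$pixels, "otsu", within = tissue)
  density <- local_mean_disc((pm$mask & tissue) * 1, f480_radius_um / ps)
  damage <- density > f480_density_threshold & tissue
  emsc <- positive_fiber_fraction(emyhc, fibers,
                                  min_positive_area_fraction = min_positive_area_fraction)
  emy_mask <- matrix(fibers$labels %in% emsc$positive_fiber_ids,
                     nrow = nrow(fibers$labels))
  repair <- dilate_disc(emy_mask, repair_radius_um / ps) & tissue & !damage
  classes <- matrix(0L, nrow(tissue), ncol(tissue))
  classes[tissue] <- 1L
  classes[repair] <- 3L
  classes[damage] <- 2L
  region_class_map(classes, ps)
}

#' Region-normalized marker score (p-SMAD2)
#'
#' For each region class, the marker-positive area divided by the class
#' area ("locally normalized" positivity). Classes with zero area are
#' reported as missing, never as 0.
#'
#' @param marker [channel_image] (e.g. p-SMAD2).
#' @param regions a [region_class_map()].
#' @param threshold_method `"otsu"` (within tissue) or `"fixed"`.
#' @param fixed_threshold threshold for the fixed method.
#' @return data frame with `region_class`, `marker_area_um2`,
#'   `region_area_um2`, `normalized_score`.
#' @export
region_normalized_score <- function(marker, regions,
                                    threshold_method = c("otsu", "fixed"),
                                    fixed_threshold = NULL) {
  stopifnot(inherits(marker, "channel_image"),
            inherits(regions, "region_class_map"))
  if (abs(marker$pixel_size_um - regions$pixel_size_um) > 1e-9)
    stop("region_normalized_score: calibration mismatch")
  tissue <- regions$classes > 0L
  if (!any(tissue)) stop("region_normalized_score: all-zero region map")
  pm <- positive_mask(marker$pixels, threshold_method, fixed_threshold,
                      within = tissue)
  ps <- regions$pixel_size_um
  out <- lapply(names(regions$levels), function(cl) {
    sel <- regions$classes == regions$levels[[cl]]
    n <- sum(sel)
    data.frame(region_class = cl,
               marker_area_um2 = if (n > 0L) sum(pm$mask & sel) * ps^2 else NA_real_,
               region_area_um2 = n * ps^2,
               normalized_score = if (n > 0L) sum(pm$mask & sel) / n else NA_real_)
  })
  res <- do.call(rbind, out)
  attr(res, "threshold_used") <- pm$threshold
  res
}
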