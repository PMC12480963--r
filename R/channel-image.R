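#' Calibrated single-channel image
#'
#' Container for one fluorescence channel or one brightfield plane: a 2-D
#' non-negative intensity matrix plus the physical pixel size in micrometres.
#' All downstream stages require calibrated images; there is no implicit
#' default pixel size.
#'
#' @param pixels numeric matrix of non-negative intensities (rows = y, image
#'   row-major, 0-based pixel indexing in exported coordinates).
#' @param pixel_size_um positive pixel edge length in micrometres.
#' @param channel_name channel label, e.g. `"laminin"`, `"DAPI"`, `"IgM"`.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, pixel_size_um, channel_name = "unnamed") {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L) stop("channel_image: empty pixel array")
  if (!is.numeric(pixels)) stop("channel_image: pixels must be numeric")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("channel_image: intensities must be finite and non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("channel_image: pixel_size_um must be a single positive number")
  structure(list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
                 channel_name = as.character(channel_name)),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s: %d x %d px @ %.4g um/px, range [%.4g, %.4g]\n",
              x$channel_name, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Labelled muscle-fibre segmentation map
#'
#' Integer label matrix in which 0 marks background/interstitium (including
#' the laminin boundary band) and each positive integer one fibre. Carries
#' the pixel calibration so that all areas and distances can be reported in
#' physical units.
#'
#' @param labels integer matrix of non-negative labels.
#' @param pixel_size_um positive pixel edge length in micrometres.
#' @param border_ids integer vector of labels touching the image border
#'   (censored shapes, flagged for exclusion from morphometry).
#' @return An object of class `fiber_label_map`.
#' @export
fiber_label_map <- function(labels, pixel_size_um, border_ids = integer(0)) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop("fiber_label_map: labels must be non-negative")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("fiber_label_map: pixel_size_um must be positive")
  structure(list(labels = labels, pixel_size_um = as.numeric(pixel_size_um),
                 border_ids = as.integer(border_ids)),
            class = "fiber_label_map")
}

#' @export
print.fiber_label_map <- function(x, ...) {
  ids <- fiber_ids(x)
  cat(sprintf("<fiber_label_map> %d x %d px @ %.4g um/px, %d fibres (%d border-touching)\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_um, length(ids),
              length(x$border_ids)))
  invisible(x)
}

#' Fibre ids present in a label map
#' @param fibers a `fiber_label_map`.
#' @return sorted integer vector of positive labels present.
#' @export
fiber_ids <- function(fibers) {
  u <- sort(unique(as.vector(fibers$labels)))
  u[u > 0L]
}

#' Region-class map (damage / repair / healthy)
#'
#' Categorical per-pixel map partitioning the tissue into foci of active
#' damage (inflamed), active repair (regenerating) and relatively healthy
#' tissue; 0 is non-tissue background. Classes are mutually exclusive and
#' jointly cover the tissue mask.
#'
#' @param classes integer matrix with values 0 (background), 1 (healthy),
#'   2 (damage), 3 (repair).
#' @param pixel_size_um positive pixel size in micrometres.
#' @return An object of class `region_class_map`.
#' @export
region_class_map <- function(classes, pixel_size_um) {
  classes <- as.matrix(classes)
  storage.mode(classes) <- "integer"
  if (!all(classes %in% 0:3))
    stop("region_class_map: classes must be coded 0/1/2/3 (background/healthy/damage/repair)")
  structure(list(classes = classes, pixel_size_um = as.numeric(pixel_size_um),
                 levels = c(healthy = 1L, damage = 2L, repair = 3L)),
            class = "region_class_map")
}

#' @export
print.region_class_map <- function(x, ...) {
  tab <- table(factor(x$classes, levels = 0:3,
                      labels = c("background", "healthy", "damage", "repair")))
  cat("<region_class_map>\n"); print(tab)
  invisible(x)
}

# Area of one pixel in um^2 / tissue area of a logical mask in mm^2.
pixel_area_um2 <- function(pixel_size_um) pixel_size_um^2
mask_area_mm2 <- function(mask, pixel_size_um) sum(mask) * pixel_size_um^2 * 1e-6
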