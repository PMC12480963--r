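# Beer-Lambert optical-density conversion and colour deconvolution
# (Ruifrok-Johnston style linear unmixing), plus the two derived slide
# scores: Sirius Red collagen fraction and H&E myonecrosis fraction.

#' Stain model for colour deconvolution
#'
#' A stain model is the set of unit optical-density (OD) vectors describing
#' how each chromogen absorbs in R, G and B, together with the background
#' (unstained glass) intensity. With two stains the third basis vector is
#' completed as the unit cross product, giving a residual channel.
#'
#' @param stain_names character vector (2 or 3 names); the first two name the
#'   chromogens of interest.
#' @param stain_od_vectors matrix with one row per stain and 3 columns (R, G,
#'   B optical densities); rows are normalized to unit Euclidean norm.
#' @param background_intensity per-channel unstained intensity I0 (default
#'   255, 8-bit white).
#' @param od_floor intensity floor used when converting to OD so that zero
#'   pixels stay finite (default 0.5 on the 0-255 scale).
#' @param max_condition reject stain matrices whose condition number exceeds
#'   this bound (near-parallel vectors make unmixing ill-posed).
#' @return An object of class `stain_model`.
#' @export
stain_model <- function(stain_names, stain_od_vectors,
                        background_intensity = c(255, 255, 255),
                        od_floor = 0.5, max_condition = 100) {
  m <- as.matrix(stain_od_vectors)
  if (ncol(m) != 3L || !nrow(m) %in% 2:3)
    stop("stain_model: need a 2x3 or 3x3 OD-vector matrix")
  if (any(background_intensity <= 0))
    stop("stain_model: background_intensity must be positive")
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) stop("stain_model: zero stain vector")
  m <- m / norms
  if (nrow(m) == 2L) {
    third <- c(m[1, 2] * m[2, 3] - m[1, 3] * m[2, 2],
               m[1, 3] * m[2, 1] - m[1, 1] * m[2, 3],
               m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
    n3 <- sqrt(sum(third^2))
    if (n3 < 1e-8) stop("stain_model: stain vectors are parallel")
    m <- rbind(m, third / n3)
    stain_names <- c(stain_names[1:2], "residual")
  }
  if (kappa(m, exact = TRUE) > max_condition)
    stop("stain_model: stain matrix is ill-conditioned (near-parallel vectors)")
  structure(list(stain_names = stain_names, stain_matrix = m,
                 background_intensity = rep(background_intensity, length.out = 3L),
                 od_floor = od_floor),
            class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("<stain_model>", paste(x$stain_names, collapse = " / "), "\n")
  print(round(x$stain_matrix, 4))
  invisible(x)
}

#' Default Sirius Red / Fast Green stain model
#'
#' Sirius Red (collagen, red chromogen absorbing green and blue) and Fast
#' Green FCF (non-collagen protein counterstain absorbing red and blue).
#' The vectors are configuration defaults, overridable per dataset via
#' [stain_model()] or a YAML stain file.
#' @return A `stain_model`.
#' @export
stain_model_sirius_fastgreen <- function() {
  stain_model(c("sirius_red", "fast_green"),
              rbind(c(0.10, 0.72, 0.69),
                    c(0.70, 0.12, 0.70)))
}

#' Default haematoxylin / eosin stain model
#'
#' Classical Ruifrok-Johnston H&E absorption vectors.
#' @return A `stain_model`.
#' @export
stain_model_he <- function() {
  stain_model(c("haematoxylin", "eosin"),
              rbind(c(0.650, 0.704, 0.286),
                    c(0.072, 0.990, 0.105)))
}

#' Load a stain model from a YAML file
#' @param path YAML file with fields `stain_names`, `stain_od_vectors`
#'   (list of 3-vectors), optional `background_intensity`, `od_floor`.
#' @return A `stain_model`.
#' @export
read_stain_model <- function(path) {
  y <- yaml::read_yaml(path)
  stain_model(y$stain_names, do.call(rbind, y$stain_od_vectors),
              background_intensity = y$background_intensity %||% c(255, 255, 255),
              od_floor = y$od_floor %||% 0.5)
}

#' Convert an RGB image to optical density
#'
#' Per channel, `OD_c = -log10(max(I_c, floor) / I0_c)`, non-negative by
#' clipping intensities at the background.
#'
#' @param rgb H x W x 3 intensity array (0-background scale).
#' @param background_intensity per-channel background I0 (positive).
#' @param od_floor intensity floor keeping OD finite at zero intensity.
#' @return H x W x 3 OD array.
#' @export
rgb_to_od <- function(rgb, background_intensity = c(255, 255, 255),
                      od_floor = 0.5) {
  if (any(background_intensity <= 0))
    stop("rgb_to_od: background_intensity must be positive")
  od <- array(0, dim = dim(rgb))
  for (c in 1:3) {
    I0 <- rep(background_intensity, length.out = 3)[c]
    od[, , c] <- -log10(pmin(pmax(rgb[, , c], od_floor), I0) / I0)
  }
  od
}

#' Beer-Lambert forward model: stain densities to RGB intensities
#'
#' The inverse of deconvolution: `I_c = I0_c * 10^(-sum_s d_s * M[s, c])`.
#' Used by the synthetic-slide generator to render brightfield images from
#' ground-truth stain-density maps.
#'
#' @param densities H x W x S array (or list of matrices) of per-stain
#'   densities, S matching the model's stains (the residual channel may be
#'   omitted).
#' @param model a [stain_model()].
#' @return H x W x 3 intensity array on the background scale.
#' @export
od_to_rgb <- function(densities, model) {
  if (is.list(densities)) densities <- simplify2array(densities)
  if (length(dim(densities)) == 2L)
    densities <- array(densities, dim = c(dim(densities), 1L))
  ns <- dim(densities)[3]
  od <- array(0, dim = c(dim(densities)[1:2], 3L))
  for (s in seq_len(ns)) for (c in 1:3)
    od[, , c] <- od[, , c] + densities[, , s] * model$stain_matrix[s, c]
  out <- array(0, dim = dim(od))
  I0 <- rep(model$background_intensity, length.out = 3)
  for (c in 1:3) out[, , c] <- I0[c] * 10^(-od[, , c])
  out
}

#' Colour deconvolution: unmix OD into per-stain densities
#'
#' Solves the linear system OD = M' d per pixel with the model's stain
#' matrix M (rows = stains). Negative densities (out-of-gamut pixels) are
#' clipped to zero; the fraction of clipped pixels per stain is reported in
#' the `clip_fraction` attribute as a diagnostic for a wrong stain model.
#'
#' @param od H x W x 3 OD array from [rgb_to_od()].
#' @param model a [stain_model()].
#' @return named list of H x W density matrices (one per stain), with
#'   attribute `clip_fraction`.
#' @export
deconvolve <- function(od, model) {
  m <- model$stain_matrix
  dims <- dim(od)
  odm <- matrix(od, ncol = 3L)           # N x 3, column c = OD channel c
  dens <- odm %*% solve(m)               # solves d M = od row-wise
  clip <- colMeans(dens < -1e-12)
  dens[dens < 0] <- 0
  out <- lapply(seq_len(ncol(dens)), function(s)
    matrix(dens[, s], nrow = dims[1]))
  names(out) <- model$stain_names
  attr(out, "clip_fraction") <- setNames(clip, model$stain_names)
  out
}

#' Collagen fraction from a Sirius Red / Fast Green slide
#'
#' Deconvolves the RGB image, thresholds the Sirius Red pseudo-channel
#' within the tissue mask, and reports collagen-positive area normalized to
#' tissue area as a percentage.
#'
#' With `threshold_method = "otsu"` the threshold is computed within tissue
#' and floored at `min_od`: on a collagen-free section the Sirius Red channel
#' carries only noise, where an unguarded Otsu split would report spurious
#' positivity.
#'
#' @param rgb calibrated brightfield RGB array (0-255).
#' @param model a [stain_model()] with a `sirius_red` stain (default
#'   [stain_model_sirius_fastgreen()]).
#' @param tissue logical tissue mask (default: computed by [tissue_mask()]).
#' @param threshold_method `"otsu"` (within tissue, floored) or `"fixed"`.
#' @param fixed_threshold OD threshold when `threshold_method = "fixed"`.
#' @param min_od floor for the Otsu threshold, in OD units (default 0.15).
#' @param pixel_size_um calibration override if `rgb` carries none.
#' @return list with `tissue_area_um2`, `collagen_area_um2`,
#'   `collagen_percent`, `threshold`, `collagen_mask`.
#' @export
collagen_fraction <- function(rgb, model = stain_model_sirius_fastgreen(),
                              tissue = NULL,
                              threshold_method = c("otsu", "fixed"),
                              fixed_threshold = NULL, min_od = 0.15,
                              pixel_size_um = NULL) {
  threshold_method <- match.arg(threshold_method)
  ps <- pixel_size_um %||% attr(rgb, "pixel_size_um")
  if (is.null(ps)) stop("collagen_fraction: no pixel size on image and no override")
  if (is.null(tissue)) tissue <- tissue_mask(rgb, pixel_size_um = ps)$mask
  if (!any(tissue)) stop("collagen_fraction: empty tissue mask")
  dens <- deconvolve(rgb_to_od(rgb, model$background_intensity, model$od_floor),
                     model)
  sr <- dens[["sirius_red"]]
  if (is.null(sr)) stop("collagen_fraction: model has no 'sirius_red' stain")
  if (threshold_method == "fixed") {
    if (is.null(fixed_threshold)) stop("collagen_fraction: fixed_threshold required")
    thr <- fixed_threshold
  } else {
    thr <- max(otsu_threshold(sr[tissue]), min_od)
  }
  coll <- sr > thr & tissue
  list(tissue_area_um2 = sum(tissue) * ps^2,
       collagen_area_um2 = sum(coll) * ps^2,
       collagen_percent = 100 * sum(coll) / sum(tissue),
       threshold = thr,
       collagen_mask = coll)
}

#' Myonecrosis scoring from an H&E slide
#'
#' Necrotic tissue is scored as the union of (i) foci of mononuclear
#' infiltrate -- tissue where the local haematoxylin-positive area fraction
#' within a disc neighbourhood exceeds a density threshold -- and (ii)
#' degenerated fibres with fragmented sarcoplasm, flagged when the
#' coefficient of variation of eosin density inside a fibre exceeds a
#' cutoff (requires a fibre label map). The score is the union area as a
#' percentage of tissue area.
#'
#' @param rgb calibrated H&E RGB array (0-255).
#' @param model H&E [stain_model()] (default [stain_model_he()]).
#' @param tissue logical tissue mask (default: computed).
#' @param nuclear_density_radius_um disc radius for local nuclear density
#'   (default 20).
#' @param density_threshold local haematoxylin-positive area fraction above
#'   which tissue counts as infiltrated (default 0.45, about half the
#'   nuclear coverage of a packed mononuclear infiltrate, i.e. a
#'   half-maximum edge criterion).
#' @param fibers optional [fiber_label_map()] enabling the
#'   fragmented-sarcoplasm component.
#' @param frag_cv_cutoff eosin CV above which a fibre counts as fragmented
#'   (default 0.6).
#' @param min_od Otsu floor for the haematoxylin threshold (default 0.15).
#' @param pixel_size_um calibration override.
#' @return list with `infiltrate_mask` (logical), `necrotic_percent`,
#'   `fragmented_fiber_ids`, `threshold`.
#' @export
infiltrate_mask <- function(rgb, model = stain_model_he(), tissue = NULL,
                            nuclear_density_radius_um = 20,
                            density_threshold = 0.45, fibers = NULL,
                            frag_cv_cutoff = 0.6, min_od = 0.15,
                            pixel_size_um = NULL) {
  if (is.null(model)) stop("infiltrate_mask: a stain model is required")
  ps <- pixel_size_um %||% attr(rgb, "pixel_size_um")
  if (is.null(ps)) stop("infiltrate_mask: no pixel size on image and no override")
  if (is.null(tissue)) tissue <- tissue_mask(rgb, pixel_size_um = ps)$mask
  if (!any(tissue)) stop("infiltrate_mask: empty tissue mask")
  dens <- deconvolve(rgb_to_od(rgb, model$background_intensity, model$od_floor),
                     model)
  haem <- dens[["haematoxylin"]]
  thr <- max(otsu_threshold(haem[tissue]), min_od)
  nucpos <- haem > thr & tissue
  density <- local_mean_disc(nucpos * 1, nuclear_density_radius_um / ps)
  infil <- density > density_threshold & tissue
  frag_ids <- integer(0)
  if (!is.null(fibers)) {
    eos <- dens[["eosin"]]
    for (fid in fiber_ids(fibers)) {
      v <- eos[fibers$labels == fid]
      if (length(v) > 4L && mean(v) > 0 && sd(v) / mean(v) > frag_cv_cutoff) {
        frag_ids <- c(frag_ids, fid)
        infil <- infil | fibers$labels == fid
      }
    }
  }
  list(infiltrate_mask = infil,
       necrotic_percent = 100 * sum(infil) / sum(tissue),
       fragmented_fiber_ids = frag_ids,
       threshold = thr)
}
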