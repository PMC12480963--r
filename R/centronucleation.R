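# Centronucleation: nucleus-to-fibre assignment, Euclidean distance to the
# fibre border, internal-nucleus classification and the %CNF summary.
#
# A nucleus belongs to the fibre whose label lies under its centroid; its
# border distance is the exact Euclidean distance transform of that fibre's
# interior evaluated at the centroid pixel.  A fibre is a centronucleated
# fibre (CNF) when it contains at least one internal nucleus.

#' Assign nuclei to fibres
#'
#' @param nuclei centroid table from [segment_nuclei()] (needs `nucleus_id`,
#'   `row_px`, `col_px`, `area_um2`) or any data frame with those columns.
#' @param fibers a [fiber_label_map()].
#' @param pixel_size_um calibration of the nucleus table; must match the
#'   label map's.
#' @return data frame of nucleus records: input columns plus `fiber_id`
#'   (0 = interstitial, i.e. centroid on background/laminin band).
#' @export
assign_nuclei <- function(nuclei, fibers,
                          pixel_size_um = fibers$pixel_size_um) {
  stopifnot(inherits(fibers, "fiber_label_map"))
  if (abs(pixel_size_um - fibers$pixel_size_um) > 1e-9)
    stop("assign_nuclei: calibration mismatch between nuclei and fibre map")
  r <- pmin(pmax(round(nuclei$row_px), 1L), nrow(fibers$labels))
  c <- pmin(pmax(round(nuclei$col_px), 1L), ncol(fibers$labels))
  nuclei$fiber_id <- fibers$labels[cbind(r, c)]
  nuclei
}

#' Euclidean distance from nucleus centroids to their fibre border
#'
#' For each record with `fiber_id > 0`, evaluates the exact Euclidean
#' distance map of that fibre's pixel set at the nucleus centroid pixel and
#' scales it to micrometres.  Records with `fiber_id = 0` (interstitial) get
#' `NA`; calling the scalar form on one is an error.
#'
#' @param records nucleus records from [assign_nuclei()].
#' @param fibers a [fiber_label_map()].
#' @return `records` with an added `dist_to_border_um` column.
#' @export
distance_to_border <- function(records, fibers) {
  stopifnot(inherits(fibers, "fiber_label_map"))
  ps <- fibers$pixel_size_um
  lab <- fibers$labels
  d <- rep(NA_real_, nrow(records))
  for (fid in unique(records$fiber_id)) {
    if (fid <= 0L) next
    sel <- which(records$fiber_id == fid)
    pix <- which(lab == fid, arr.ind = TRUE)
    rr <- range(pix[, 1]); cr <- range(pix[, 2])
    sub <- matrix(0, rr[2] - rr[1] + 3L, cr[2] - cr[1] + 3L)
    sub[cbind(pix[, 1] - rr[1] + 2L, pix[, 2] - cr[1] + 2L)] <- 1
    dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(sub)))
    r <- pmin(pmax(round(records$row_px[sel]), 1L), nrow(lab)) - rr[1] + 2L
    c <- pmin(pmax(round(records$col_px[sel]), 1L), ncol(lab)) - cr[1] + 2L
    inside <- r >= 1L & r <= nrow(sub) & c >= 1L & c <= ncol(sub)
    d[sel][inside] <- dm[cbind(r[inside], c[inside])] * ps
    d[sel][!inside] <- 0
  }
  records$dist_to_border_um <- d
  records
}

#' Classify internal nuclei and summarize the CNF percentage
#'
#' A nucleus is internal when its border distance exceeds the rule's cutoff:
#' either an absolute distance `d0` in micrometres
#' (`rule = list(absolute_um = d0)`) or a fraction of the fibre's equivalent
#' radius `r_eq = sqrt(area / pi)` (`rule = list(relative = alpha)`, default
#' `alpha = 0.3`).  A fibre is a CNF when it contains at least one internal
#' nucleus; the percentage is taken over retained fibres only (those
#' surviving the circularity/border filter).
#'
#' @param records nucleus records with `dist_to_border_um` (from
#'   [distance_to_border()]).
#' @param fibers a [fiber_label_map()].
#' @param metrics filtered morphometry table from
#'   [apply_circularity_filter()]; its non-excluded `fiber_id`s define the
#'   denominator.  Omit to use all fibres in the map.
#' @param rule `list(relative = alpha)` or `list(absolute_um = d0)`.
#' @return list of class `cnf_summary`: `n_fibers_retained`, `n_cnf`,
#'   `cnf_percent`, `records` (with `is_internal`), `cnf_fiber_ids`.
#' @export
classify_cnf <- function(records, fibers, metrics = NULL,
                         rule = list(relative = 0.3)) {
  stopifnot(inherits(fibers, "fiber_label_map"))
  ps <- fibers$pixel_size_um
  retained <- if (is.null(metrics)) fiber_ids(fibers)
              else metrics$fiber_id[!isTRUE_vec(metrics$excluded)]
  if (length(retained) == 0L)
    stop_myohisto("classify_cnf: no retained fibres", "myohisto_empty_summary")
  areas <- tabulate(fibers$labels[fibers$labels > 0L]) * ps^2
  if (!is.null(rule$absolute_um)) {
    cutoff <- rep(rule$absolute_um, nrow(records))
  } else {
    alpha <- rule$relative %||% 0.3
    r_eq <- sqrt(areas / pi)
    cutoff <- ifelse(records$fiber_id > 0L, alpha * r_eq[records$fiber_id], Inf)
  }
  records$is_internal <- records$fiber_id > 0L &
    !is.na(records$dist_to_border_um) & records$dist_to_border_um > cutoff
  cnf_ids <- intersect(unique(records$fiber_id[records$is_internal]), retained)
  structure(list(n_fibers_retained = length(retained),
                 n_cnf = length(cnf_ids),
                 cnf_percent = 100 * length(cnf_ids) / length(retained),
                 cnf_fiber_ids = sort(cnf_ids),
                 records = records,
                 rule = rule),
            class = "cnf_summary")
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' @export
print.cnf_summary <- function(x, ...) {
  cat(sprintf("<cnf_summary> %d / %d retained fibres centronucleated (%.1f%%)\n",
              x$n_cnf, x$n_fibers_retained, x$cnf_percent))
  invisible(x)
}
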