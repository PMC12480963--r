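# Study orchestration: run all stages on each sample, aggregate per-group
# summaries (mean, SD, n -- descriptives only; inferential statistics are
# deliberately left to external routines), and emit a reproducibility
# manifest.  Each stage failure is recorded per sample without aborting the
# study.

#' Default per-stage pipeline parameters
#' @return nested list of stage parameter blocks.
#' @export
default_params <- function() {
  list(segmentation = segmentation_params(),
       morphometry = list(circularity_threshold = 0.3, exclude_border = TRUE),
       cnf = list(rule = list(relative = 0.3)),
       stainsep = list(threshold_method = "otsu", min_od = 0.15,
                       nuclear_density_radius_um = 20, density_threshold = 0.45),
       markers = list(min_positive_area_fraction = 0.3,
                      f480_radius_um = 20, f480_density_threshold = 0.5,
                      repair_radius_um = 25, cell_radius_um = 4))
}

#' Analyse one slide (fluorescence channels + optional brightfield)
#'
#' Runs segmentation, morphometry, CNF classification and the marker and
#' brightfield quantifications that the provided channels allow, returning
#' one metrics row plus the per-fibre and per-nucleus tables.
#'
#' @param channels named list of [channel_image]s; `laminin` and `DAPI`
#'   drive segmentation/CNF; optional `IgM`, `eMyHC`, `F4-80`, `PDGFRA`,
#'   `pSMAD2` drive marker scores.
#' @param brightfield optional list with `sirius_fastgreen` and/or `he`
#'   calibrated RGB arrays.
#' @param params parameter blocks, see [default_params()].
#' @return list with `metrics` (one-row data frame), `fibers`, `nuclei`,
#'   `regions`, `psmad2_scores`.
#' @export
analyze_slide <- function(channels, brightfield = NULL,
                          params = default_params()) {
  lam <- channels$laminin
  if (is.null(lam)) stop("analyze_slide: a laminin channel is required")
  tis <- tissue_mask(lam)
  fibers <- segment_fibers(lam, params$segmentation, tissue = tis$mask)
  morph <- fiber_morphometry(fibers)
  morph <- apply_circularity_filter(morph,
                                    threshold = params$morphometry$circularity_threshold,
                                    exclude_border = params$morphometry$exclude_border)
  retained <- morph$fiber_id[!morph$excluded]
  size <- fiber_size_summary(morph)
  metrics <- data.frame(n_fibers = nrow(morph),
                        n_retained = length(retained),
                        mean_min_feret_um = size$mean_min_feret_um,
                        sd_min_feret_um = size$sd_min_feret_um,
                        tissue_area_mm2 = tis$tissue_area_um2 * 1e-6)

  nuclei <- NULL; cnf <- NULL
  if (!is.null(channels$DAPI)) {
    seg <- segment_nuclei(channels$DAPI, params$segmentation)
    nuclei <- assign_nuclei(seg$centroids, fibers)
    nuclei <- distance_to_border(nuclei, fibers)
    cnf <- classify_cnf(nuclei, fibers, morph, rule = params$cnf$rule)
    metrics$cnf_percent <- cnf$cnf_percent
    metrics$n_cnf <- cnf$n_cnf
    nuclei <- cnf$records
  }
  if (!is.null(channels$IgM)) {
    sc <- positive_fiber_fraction(channels$IgM, fibers, retained,
                                  min_positive_area_fraction = params$markers$min_positive_area_fraction)
    metrics$igm_fiber_fraction <- sc$value
  }
  if (!is.null(channels$eMyHC)) {
    sc <- positive_fiber_density(channels$eMyHC, fibers, tis$mask, retained,
                                 min_positive_area_fraction = params$markers$min_positive_area_fraction)
    metrics$emyhc_per_mm2 <- sc$value
  }
  if (!is.null(channels$PDGFRA) && !is.null(nuclei)) {
    sc <- positive_cell_fraction(channels$PDGFRA, nuclei,
                                 radius_um = params$markers$cell_radius_um)
    metrics$fap_cell_fraction <- sc$value
  }
  regions <- NULL; psc <- NULL
  if (!is.null(channels$`F4-80`) && !is.null(channels$eMyHC)) {
    regions <- classify_regions(channels$`F4-80`, channels$eMyHC, fibers,
                                tis$mask,
                                f480_radius_um = params$markers$f480_radius_um,
                                f480_density_threshold = params$markers$f480_density_threshold,
                                repair_radius_um = params$markers$repair_radius_um)
    if (!is.null(channels$pSMAD2)) {
      psc <- region_normalized_score(channels$pSMAD2, regions)
      for (i in seq_len(nrow(psc)))
        metrics[[paste0("psmad2_", psc$region_class[i])]] <- psc$normalized_score[i]
    }
  }
  if (!is.null(brightfield$sirius_fastgreen)) {
    fr <- collagen_fraction(brightfield$sirius_fastgreen,
                            threshold_method = params$stainsep$threshold_method,
                            min_od = params$stainsep$min_od)
    metrics$collagen_percent <- fr$collagen_percent
  }
  if (!is.null(brightfield$he)) {
    nm <- infiltrate_mask(brightfield$he,
                          nuclear_density_radius_um = params$stainsep$nuclear_density_radius_um,
                          density_threshold = params$stainsep$density_threshold)
    metrics$necrotic_percent <- nm$necrotic_percent
  }
  list(metrics = metrics, fibers = morph, nuclei = nuclei,
       regions = regions, psmad2_scores = psc, label_map = fibers)
}

#' Run the full study pipeline from a configuration
#'
#' The configuration (a list, or a path to a YAML file) holds a sample
#' sheet and optional stage parameter overrides. Each sample entry either
#' names image files (`fluorescence`, optional `sirius_fastgreen`, `he`,
#' with `pixel_size_um` if the files carry no calibration) or a phantom
#' `preset` (demo mode, `seed` offset by the sample index). An optional
#' `qpcr` block (`plate_csv`, `reference_genes`, `control_group`) runs the
#' expression stage; image stages are skipped when no samples are listed.
#'
#' Stage failures are caught per sample and recorded in the `errors`
#' column; the study continues.
#'
#' @param config list or YAML path. Fields: `samples` (list of
#'   `list(id =, group =, preset =|fluorescence =, ...)`), `qpcr`,
#'   `params` overrides, `seed`, `out_dir`.
#' @return list with `metrics` (per-sample data frame), `summary`
#'   (per-group long table), `qpcr` results and the `manifest` (also
#'   written to `out_dir` if given).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$samples) && is.null(config$qpcr))
    stop("run_pipeline: config has neither samples nor a qpcr block")
  for (s in config$samples) {
    for (f in intersect(names(s), c("fluorescence", "sirius_fastgreen", "he")))
      if (!file.exists(s[[f]])) stop("run_pipeline: missing file: ", s[[f]])
  }
  if (!is.null(config$qpcr$plate_csv) && !file.exists(config$qpcr$plate_csv))
    stop("run_pipeline: missing file: ", config$qpcr$plate_csv)
  params <- utils::modifyList(default_params(), config$params %||% list())
  seed <- config$seed %||% 1L

  rows <- list(); errors <- list()
  for (i in seq_along(config$samples)) {
    s <- config$samples[[i]]
    res <- tryCatch({
      if (!is.null(s$preset)) {
        ph <- generate_phantom(phantom_preset(s$preset,
                                              seed = substream(seed, 100L + i)))
        analyze_slide(ph$channels, ph$brightfield, params)
      } else {
        chs <- read_image(s$fluorescence, pixel_size_um = s$pixel_size_um)
        bf <- list()
        if (!is.null(s$sirius_fastgreen))
          bf$sirius_fastgreen <- read_image(s$sirius_fastgreen,
                                            pixel_size_um = s$pixel_size_um)
        if (!is.null(s$he))
          bf$he <- read_image(s$he, pixel_size_um = s$pixel_size_um)
        analyze_slide(chs, bf, params)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[s$id]] <- conditionMessage(res)
    } else {
      rows[[s$id]] <- cbind(data.frame(sample = s$id, group = s$group),
                            res$metrics)
    }
  }
  metrics <- if (length(rows)) {
    all_cols <- unique(unlist(lapply(rows, names)))
    do.call(rbind, lapply(rows, function(r) {
      r[setdiff(all_cols, names(r))] <- NA
      r[all_cols]
    }))
  } else NULL
  if (!is.null(metrics)) rownames(metrics) <- NULL

  qpcr_res <- NULL
  if (!is.null(config$qpcr)) {
    plate <- qpcr_plate(read.csv(config$qpcr$plate_csv))
    q <- sample_quantities(plate)
    qpcr_res <- normalization_and_fold_change(
      q, config$qpcr$reference_genes, config$qpcr$control_group)
    qpcr_res$quantities <- q
  }

  summary <- if (!is.null(metrics)) summarize_groups(metrics, "group") else NULL
  manifest <- list(config_hash = config_hash(config), seed = seed,
                   n_samples = length(config$samples),
                   errors = errors)
  if (!is.null(config$out_dir)) {
    tabs <- list()
    if (!is.null(metrics)) tabs$metrics <- metrics
    if (!is.null(summary)) tabs$group_summary <- summary
    if (!is.null(qpcr_res)) {
      tabs$fold_changes <- qpcr_res$fold_changes
      tabs$normalized_quantities <- qpcr_res$normalized
    }
    manifest <- write_results(tabs, config$out_dir, config = config, seed = seed)
  }
  list(metrics = metrics, summary = summary, qpcr = qpcr_res,
       manifest = manifest, errors = errors)
}

#' Per-group descriptive summary (mean, SD, n)
#'
#' Long-format summary over every numeric metric column: mean, SD (missing
#' when n = 1) and n per group. Hypothesis testing is intentionally out of
#' scope; the table is shaped for direct consumption by standard
#' statistics environments.
#'
#' @param metrics per-sample metrics data frame.
#' @param keys character vector of grouping columns (default `"group"`).
#' @return long data frame: keys, `metric`, `mean`, `sd`, `n`.
#' @export
summarize_groups <- function(metrics, keys = "group") {
  if (is.null(metrics) || nrow(metrics) == 0L)
    stop_myohisto("summarize_groups: empty metrics table", "myohisto_empty_summary")
  num <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  num <- setdiff(num, keys)
  out <- list()
  for (m in num) {
    sp <- split(metrics[[m]], metrics[keys], drop = TRUE)
    for (g in names(sp)) {
      v <- sp[[g]][!is.na(sp[[g]])]
      if (length(v) == 0L) next
      out[[length(out) + 1L]] <-
        data.frame(group = g, metric = m, mean = mean(v),
                   sd = if (length(v) > 1L) sd(v) else NA_real_,
                   n = length(v))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
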