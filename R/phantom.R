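# Ground-truthed synthetic muscle cross-sections.
#
# The phantom emulates a transverse dystrophic muscle section: a tessellation
# of convex-ish fibres separated by a thin laminin-positive boundary band,
# peripheral vs central nuclei at a controlled CNF fraction, fibre-size
# (minimum Feret) distributions, focal lesions of mononuclear infiltrate,
# IgM+ fibres, small eMyHC+ regenerating fibres, interstitial collagen, and
# matched brightfield renderings (Sirius Red/Fast Green, H&E) produced with
# the same Beer-Lambert forward model the analysis inverts.
#
# The fluorescence stack and the two brightfield images represent serial
# sections of one block: lesion hypercellularity is rendered in the H&E
# haematoxylin plane, not in DAPI, so the CNF ground truth stays exact.
#
# All randomness flows from `spec$seed` through fixed sub-streams
# (geometry, nuclei, marker identity, density fields, noise), so the same
# spec reproduces bit-identical images and tables.

# Grid spacing calibration: a jittered-grid cell of spacing s loses the
# boundary band and the threshold transition, leaving an interior whose hull
# min-Feret averages s - boundary - ~1px (measured on truth labels).
.spacing_px <- function(feret_px, boundary_px) feret_px + boundary_px - 0.5

#' Phantom specification
#'
#' Parameters of one synthetic muscle cross-section. All fractions are in
#' `[0, 1]`; the field must be able to hold at least 25 fibres (and at least
#' `n_fibers_target`) at the requested fibre size, otherwise generation
#' fails with an error naming the violated constraint.
#'
#' @param field_size_px integer (height, width) of the field in pixels.
#' @param pixel_size_um pixel edge length in micrometres.
#' @param n_fibers_target minimum number of fibres the field must hold.
#' @param fiber_minferet_mean_um,fiber_minferet_cv target mean and
#'   coefficient of variation of the fibre minimum Feret diameter.
#' @param boundary_thickness_px thickness of the laminin boundary band.
#' @param cnf_fraction fraction of fibres given one central nucleus.
#' @param nuclei_per_fiber_mean mean peripheral nuclei per fibre (Poisson,
#'   at least one).
#' @param collagen_fraction fraction of tissue area rendered as collagen.
#' @param necrotic_fraction fraction of tissue area covered by infiltrate
#'   lesions.
#' @param igm_positive_fraction fraction of fibres rendered IgM-positive.
#' @param emyhc_count_per_mm2 density of eMyHC+ regenerating fibres.
#' @param pdgfra_positive_fraction fraction of cells rendered PDGFRA+ (FAPs).
#' @param psmad2_class_positivity named positive-area fractions of the
#'   p-SMAD2 channel within the damage / repair / healthy region classes.
#' @param marker_snr signal-to-noise ratio of the fluorescence rendering
#'   (Gaussian noise with SD = mean / marker_snr).
#' @param seed master integer seed.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(field_size_px = c(700L, 700L), pixel_size_um = 1,
                         n_fibers_target = 300L,
                         fiber_minferet_mean_um = 30, fiber_minferet_cv = 0.15,
                         boundary_thickness_px = 3L,
                         cnf_fraction = 0, nuclei_per_fiber_mean = 2,
                         collagen_fraction = 0.02, necrotic_fraction = 0,
                         igm_positive_fraction = 0, emyhc_count_per_mm2 = 0,
                         pdgfra_positive_fraction = 0,
                         psmad2_class_positivity = c(damage = 0, repair = 0,
                                                     healthy = 0),
                         marker_snr = 10, seed = 1L) {
  spec <- list(field_size_px = as.integer(rep(field_size_px, length.out = 2L)),
               pixel_size_um = pixel_size_um,
               n_fibers_target = as.integer(n_fibers_target),
               fiber_minferet_mean_um = fiber_minferet_mean_um,
               fiber_minferet_cv = fiber_minferet_cv,
               boundary_thickness_px = as.integer(boundary_thickness_px),
               cnf_fraction = cnf_fraction,
               nuclei_per_fiber_mean = nuclei_per_fiber_mean,
               collagen_fraction = collagen_fraction,
               necrotic_fraction = necrotic_fraction,
               igm_positive_fraction = igm_positive_fraction,
               emyhc_count_per_mm2 = emyhc_count_per_mm2,
               pdgfra_positive_fraction = pdgfra_positive_fraction,
               psmad2_class_positivity = psmad2_class_positivity,
               marker_snr = marker_snr,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  fr <- c(cnf_fraction = s$cnf_fraction, collagen_fraction = s$collagen_fraction,
          necrotic_fraction = s$necrotic_fraction,
          igm_positive_fraction = s$igm_positive_fraction,
          pdgfra_positive_fraction = s$pdgfra_positive_fraction,
          s$psmad2_class_positivity)
  if (any(fr < 0 | fr > 1))
    stop("phantom_spec: fraction out of [0, 1]: ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "))
  if (s$pixel_size_um <= 0) stop("phantom_spec: pixel_size_um must be positive")
  if (s$fiber_minferet_mean_um <= 0 || s$fiber_minferet_cv < 0)
    stop("phantom_spec: fibre size parameters must be positive")
  if (s$marker_snr <= 0) stop("phantom_spec: marker_snr must be positive")
  if (s$emyhc_count_per_mm2 < 0) stop("phantom_spec: emyhc_count_per_mm2 must be non-negative")
  g <- phantom_grid(s)
  if (g$n < max(25L, s$n_fibers_target))
    stop(sprintf(paste0("phantom_spec: field %dx%d px holds only %d fibres of ",
                        "mean min-Feret %.3g um; needs >= %d (constraint: field ",
                        "large enough for n_fibers_target)"),
                 s$field_size_px[1], s$field_size_px[2], g$n,
                 s$fiber_minferet_mean_um, max(25L, s$n_fibers_target)))
  invisible(s)
}

phantom_grid <- function(s, margin_px = 12L) {
  sp <- .spacing_px(s$fiber_minferet_mean_um / s$pixel_size_um,
                    s$boundary_thickness_px)
  nr <- floor((s$field_size_px[1] - 2L * margin_px) / sp)
  nc <- floor((s$field_size_px[2] - 2L * margin_px) / sp)
  list(margin = margin_px, spacing = sp, nr = nr, nc = nc, n = max(0L, nr * nc))
}

#' Phantom presets mirroring wild-type and dystrophic muscle
#'
#' Parameter sets whose ordering mimics the age/genotype trends of the
#' mdx5Cv model: CNF absent in wild type and around 60/55/50% at 3/6/12
#' months in dystrophic muscle, collagen increasing with age in the
#' dystrophic presets, necrosis and IgM positivity peaking at 3 months,
#' smaller fibre calibres in the dystrophic presets.
#'
#' @param name one of `"wt"`, `"mdx_3m"`, `"mdx_6m"`, `"mdx_12m"`.
#' @param seed master seed passed through to [phantom_spec()].
#' @param ... overrides forwarded to [phantom_spec()].
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name, seed = 1L, ...) {
  presets <- list(
    wt = list(field_size_px = c(860L, 860L),
              cnf_fraction = 0.00, fiber_minferet_mean_um = 38,
              fiber_minferet_cv = 0.12, collagen_fraction = 0.02,
              necrotic_fraction = 0.00, igm_positive_fraction = 0.00,
              emyhc_count_per_mm2 = 0),
    mdx_3m = list(cnf_fraction = 0.60, fiber_minferet_mean_um = 29,
                  fiber_minferet_cv = 0.18, collagen_fraction = 0.05,
                  necrotic_fraction = 0.12, igm_positive_fraction = 0.08,
                  emyhc_count_per_mm2 = 25),
    mdx_6m = list(cnf_fraction = 0.55, fiber_minferet_mean_um = 30,
                  fiber_minferet_cv = 0.18, collagen_fraction = 0.10,
                  necrotic_fraction = 0.05, igm_positive_fraction = 0.02,
                  emyhc_count_per_mm2 = 12),
    mdx_12m = list(cnf_fraction = 0.50, fiber_minferet_mean_um = 31,
                   fiber_minferet_cv = 0.18, collagen_fraction = 0.14,
                   necrotic_fraction = 0.04, igm_positive_fraction = 0.02,
                   emyhc_count_per_mm2 = 8))
  if (!name %in% names(presets))
    stop("phantom_preset: unknown preset '", name, "'; valid presets: ",
         paste(names(presets), collapse = ", "))
  args <- utils::modifyList(c(presets[[name]], list(seed = seed)), list(...))
  do.call(phantom_spec, args)
}

# Disc pixel offsets (arr.ind) of radius r around origin.
disc_offsets <- function(r) {
  d <- as.integer(ceiling(r))
  g <- expand.grid(dr = -d:d, dc = -d:d)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# Paint value discs at (row, col) centres into a matrix (bounded).
paint_discs <- function(mat, rows, cols, r, value) {
  off <- disc_offsets(r)
  for (i in seq_along(rows)) {
    rr <- rows[i] + off$dr; cc <- cols[i] + off$dc
    ok <- rr >= 1L & rr <= nrow(mat) & cc >= 1L & cc <= ncol(mat)
    mat[cbind(rr[ok], cc[ok])] <- value
  }
  mat
}

# Exact-count blob mask: the k highest pixels of a smoothed uniform field,
# restricted to `within`.
blob_mask <- function(dims, within, k, sigma_px = 5) {
  mask <- matrix(FALSE, dims[1], dims[2])
  if (k <= 0L) return(mask)
  g <- smooth_px(matrix(runif(prod(dims)), dims[1], dims[2]), sigma_px)
  v <- g[within]
  ord <- order(v, decreasing = TRUE)[seq_len(min(k, length(v)))]
  wi <- which(within)
  mask[wi[ord]] <- TRUE
  mask
}

#' Generate a ground-truthed synthetic muscle cross-section
#'
#' Builds the fibre tessellation (seeded region growing on a jittered grid
#' with per-fibre growth weights), places nuclei, marker identities, lesions
#' and collagen, and renders the fluorescence channels plus two brightfield
#' slides through the Beer-Lambert forward model of [od_to_rgb()].
#'
#' Central nuclei are placed at the fibre's interior distance-map maximum
#' (always deeper than 0.5 of the equivalent radius for these convex-ish
#' cells); peripheral nuclei sit within ~3 px of the boundary band.
#'
#' @param spec a [phantom_spec()] or [phantom_preset()].
#' @return list of class `phantom` with elements `channels` (named list of
#'   [channel_image]: laminin, DAPI, IgM, eMyHC, F4-80, PDGFRA, p-SMAD2),
#'   `brightfield` (list `sirius_fastgreen`, `he`: calibrated RGB arrays)
#'   and `truth` (class `phantom_truth`; see Details).
#'
#' @details `truth` carries `fiber_labels` ([fiber_label_map()]),
#'   `nucleus_table` (with true centrality flags and border distances),
#'   `tissue_mask`, `collagen_mask`, `infiltrate_mask`, `region_class_map`,
#'   `igm_fiber_ids`, `emyhc_fiber_ids`, `pdgfra_nucleus_ids`, a per-fibre
#'   table, and the realized scalar fractions `true_cnf_fraction`,
#'   `true_collagen_fraction`, `true_necrotic_fraction`,
#'   `true_psmad2_positivity`, all recomputable from the stored masks.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  H <- spec$field_size_px[1]; W <- spec$field_size_px[2]
  ps <- spec$pixel_size_um
  g <- phantom_grid(spec)

  ## --- geometry: jittered grid + weighted region growing ------------------
  geom <- with_seed(substream(spec$seed, 1L), {
    sr <- (H - 2 * g$margin) / g$nr
    sc <- (W - 2 * g$margin) / g$nc
    centres <- expand.grid(r = g$margin + (seq_len(g$nr) - 0.5) * sr,
                           c = g$margin + (seq_len(g$nc) - 0.5) * sc)
    jit_r <- runif(g$n, -0.28 * sr, 0.28 * sr)
    jit_c <- runif(g$n, -0.28 * sc, 0.28 * sc)
    sdlog <- sqrt(log(1 + spec$fiber_minferet_cv^2))
    w <- exp(rnorm(g$n, 0, sdlog))
    list(seed_r = centres$r + jit_r, seed_c = centres$c + jit_c, w = w,
         sr = sr, sc = sc)
  })
  lab <- matrix(0L, H, W)
  best <- matrix(Inf, H, W)
  win <- ceiling(2.5 * max(geom$sr, geom$sc) * max(geom$w))
  for (k in seq_len(g$n)) {
    rws <- max(1L, floor(geom$seed_r[k] - win)):min(H, ceiling(geom$seed_r[k] + win))
    cls <- max(1L, floor(geom$seed_c[k] - win)):min(W, ceiling(geom$seed_c[k] + win))
    dd <- outer((rws - geom$seed_r[k])^2, (cls - geom$seed_c[k])^2, "+") / geom$w[k]^2
    sub <- best[rws, cls]
    upd <- dd < sub
    if (any(upd)) {
      sub[upd] <- dd[upd]
      best[rws, cls] <- sub
      labsub <- lab[rws, cls]
      labsub[upd] <- k
      lab[rws, cls] <- labsub
    }
  }
  tissue <- matrix(FALSE, H, W)
  tissue[(g$margin + 1L):(H - g$margin), (g$margin + 1L):(W - g$margin)] <- TRUE
  lab[!tissue] <- 0L

  ## boundary band: label-change edges + tissue perimeter ring, dilated
  edge <- matrix(FALSE, H, W)
  edge[-H, ] <- edge[-H, ] | (lab[-H, ] != lab[-1, ])
  edge[-1, ] <- edge[-1, ] | (lab[-1, ] != lab[-H, ])
  edge[, -W] <- edge[, -W] | (lab[, -W] != lab[, -1])
  edge[, -1] <- edge[, -1] | (lab[, -1] != lab[, -W])
  edge <- edge & tissue
  bt <- spec$boundary_thickness_px
  band <- dilate_disc(edge, max(1L, floor(bt / 2)))
  interior <- lab
  interior[band | !tissue] <- 0L
  # relabel contiguously
  present <- sort(unique(interior[interior > 0L]))
  remap <- integer(max(present))
  remap[present] <- seq_along(present)
  pos <- interior > 0L
  interior[pos] <- remap[interior[pos]]
  n_fib <- length(present)
  fibers <- fiber_label_map(interior, ps)

  areas_px <- tabulate(interior[pos], nbins = n_fib)
  r_eq_px <- sqrt(areas_px / pi)
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image((interior > 0L) * 1)))

  ## --- nuclei -------------------------------------------------------------
  pix_idx <- which(pos)
  pix_lab <- interior[pos]
  idx_by_fib <- split(pix_idx, pix_lab)
  nuc <- with_seed(substream(spec$seed, 2L), {
    rows <- list(); k <- 0L
    # nuclei are solid bodies: enforce a minimum centre separation so two
    # generated nuclei never merge into one DAPI object
    blocked <- matrix(FALSE, H, W)
    min_sep <- 7
    claim <- function(p) {
      blocked <<- paint_discs(blocked, (p - 1L) %% H + 1L, (p - 1L) %/% H + 1L,
                              min_sep, TRUE)
      p
    }
    dmax_by_fib <- vapply(idx_by_fib, function(ii) max(dm[ii]), numeric(1))
    cnf_ok <- which(dmax_by_fib > 0.55 * r_eq_px)
    n_cnf <- round(spec$cnf_fraction * n_fib)
    if (n_cnf > length(cnf_ok))
      stop("generate_phantom: fibres too elongated to place ", n_cnf,
           " central nuclei")
    cnf_ids <- if (n_cnf > 0L) sort(sample(cnf_ok, n_cnf)) else integer(0)
    for (f in cnf_ids) {
      ii <- idx_by_fib[[f]]
      k <- k + 1L
      rows[[k]] <- c(claim(ii[which.max(dm[ii])]), f, 1L)
    }
    for (f in seq_len(n_fib)) {
      ii <- idx_by_fib[[f]]
      n_peri <- max(1L, rpois(1L, spec$nuclei_per_fiber_mean))
      peri_pool <- ii[dm[ii] >= 1.5 & dm[ii] <= pmin(3.5, 0.25 * r_eq_px[f])]
      if (length(peri_pool) == 0L) peri_pool <- ii[dm[ii] <= 2.5]
      for (p in sample(peri_pool)) {
        if (n_peri == 0L) break
        if (blocked[p]) next
        k <- k + 1L
        rows[[k]] <- c(claim(p), f, 0L)
        n_peri <- n_peri - 1L
      }
    }
    # interstitial cells on the boundary band
    band_idx <- sample(which(band))
    n_int <- round(0.4 * n_fib)
    for (p in band_idx) {
      if (n_int == 0L) break
      if (blocked[p]) next
      k <- k + 1L
      rows[[k]] <- c(claim(p), 0L, 0L)
      n_int <- n_int - 1L
    }
    m <- do.call(rbind, rows)
    data.frame(nucleus_id = seq_len(nrow(m)),
               row_px = (m[, 1] - 1L) %% H + 1L,
               col_px = (m[, 1] - 1L) %/% H + 1L,
               fiber_id = m[, 2], is_central = m[, 3] == 1L,
               dist_to_border_um = dm[m[, 1]] * ps)
  })
  true_cnf_ids <- sort(unique(nuc$fiber_id[nuc$is_central]))
  true_cnf_fraction <- length(true_cnf_ids) / n_fib

  ## --- marker identities ----------------------------------------------------
  mk <- with_seed(substream(spec$seed, 3L), {
    igm_ids <- sort(sample(n_fib, round(spec$igm_positive_fraction * n_fib)))
    tissue_mm2 <- sum(tissue) * ps^2 * 1e-6
    n_em <- round(spec$emyhc_count_per_mm2 * tissue_mm2)
    em_ids <- sort(order(areas_px)[seq_len(min(n_em, n_fib))])
    n_fap <- round(spec$pdgfra_positive_fraction * nrow(nuc))
    inter <- which(nuc$fiber_id == 0L)
    fap <- if (n_fap <= length(inter)) sample(inter, n_fap)
           else c(inter, sample(which(nuc$fiber_id > 0L), n_fap - length(inter)))
    list(igm_ids = igm_ids, em_ids = em_ids, fap_ids = sort(nuc$nucleus_id[fap]))
  })

  ## --- density fields: lesions, collagen, p-SMAD2 --------------------------
  fld <- with_seed(substream(spec$seed, 4L), {
    n_tis <- sum(tissue)
    # infiltrate lesions: discs accumulated to an exact pixel count
    target <- round(spec$necrotic_fraction * n_tis)
    lesion <- matrix(FALSE, H, W)
    got <- 0L
    tis_idx <- which(tissue)
    while (got < target) {
      ctr <- tis_idx[sample.int(length(tis_idx), 1L)]
      cr <- (ctr - 1L) %% H + 1L; cc <- (ctr - 1L) %/% H + 1L
      rad <- runif(1L, 25, 45) / ps
      off <- disc_offsets(rad)
      rr <- cr + off$dr; ccd <- cc + off$dc
      ok <- rr >= 1L & rr <= H & ccd >= 1L & ccd <= W
      cand <- cbind(rr[ok], ccd[ok])
      new <- cand[tissue[cand] & !lesion[cand], , drop = FALSE]
      if (nrow(new) == 0L) next
      need <- target - got
      if (nrow(new) > need) {
        d2 <- (new[, 1] - cr)^2 + (new[, 2] - cc)^2
        new <- new[order(d2)[seq_len(need)], , drop = FALSE]
      }
      lesion[new] <- TRUE
      got <- got + nrow(new)
    }
    collagen <- blob_mask(c(H, W), tissue, round(spec$collagen_fraction * n_tis),
                          sigma_px = 6)
    # region classes: damage = lesions; repair = dilated eMyHC fibres; rest healthy
    emy_mask <- matrix(interior %in% mk$em_ids, H, W)
    repair <- dilate_disc(emy_mask, 25 / ps) & tissue & !lesion
    classes <- matrix(0L, H, W)
    classes[tissue] <- 1L
    classes[repair] <- 3L
    classes[lesion] <- 2L
    pp <- spec$psmad2_class_positivity
    pp <- setNames(rep(pp, length.out = 3L),
                   names(pp) %||% c("damage", "repair", "healthy"))
    psmad2 <- matrix(FALSE, H, W)
    realized <- c(damage = NA_real_, repair = NA_real_, healthy = NA_real_)
    for (cl in c("damage", "repair", "healthy")) {
      code <- c(damage = 2L, repair = 3L, healthy = 1L)[[cl]]
      within <- classes == code
      kpos <- round(pp[[cl]] * sum(within))
      psmad2 <- psmad2 | blob_mask(c(H, W), within, kpos, sigma_px = 3)
      realized[cl] <- if (sum(within) > 0L) kpos / sum(within) else NA_real_
    }
    list(lesion = lesion, collagen = collagen, classes = classes,
         psmad2 = psmad2, psmad2_realized = realized)
  })

  ## --- rendering ------------------------------------------------------------
  rend <- with_seed(substream(spec$seed, 5L), {
    noisy <- function(m) {
      m <- m + rnorm(length(m), 0, m / spec$marker_snr)
      m[m < 0] <- 0
      m
    }
    lam <- matrix(8, H, W); lam[!tissue] <- 0; lam[band] <- 180
    dap <- matrix(0, H, W)
    dap <- paint_discs(dap, nuc$row_px, nuc$col_px, 3 / ps, 200)
    igm <- matrix(0, H, W); igm[matrix(interior %in% mk$igm_ids, H, W)] <- 160
    emy <- matrix(0, H, W); emy[matrix(interior %in% mk$em_ids, H, W)] <- 170
    f480 <- matrix(0, H, W); f480[fld$lesion] <- 150
    fap <- nuc[nuc$nucleus_id %in% mk$fap_ids, ]
    pdg <- matrix(0, H, W)
    pdg <- paint_discs(pdg, fap$row_px, fap$col_px, 4 / ps, 150)
    psm <- matrix(0, H, W); psm[fld$psmad2] <- 170
    chs <- list(laminin = lam, DAPI = dap, IgM = igm, eMyHC = emy,
                `F4-80` = f480, PDGFRA = pdg, pSMAD2 = psm)
    chs <- lapply(chs, noisy)

    # Sirius Red / Fast Green brightfield
    srfg_model <- stain_model_sirius_fastgreen()
    sr_d <- matrix(0, H, W); sr_d[tissue] <- 0.03; sr_d[fld$collagen] <- 1.1
    fg_d <- matrix(0, H, W); fg_d[tissue & !fld$collagen] <- 0.85
    fg_d[fld$collagen] <- 0.05
    srfg <- od_to_rgb(list(sr_d, fg_d), srfg_model)
    # H&E brightfield: nuclei + dense lesion nuclei in haematoxylin,
    # eosin over sarcoplasm, ragged and reduced inside lesions
    he_model <- stain_model_he()
    hae <- matrix(0, H, W)
    hae <- paint_discs(hae, nuc$row_px, nuc$col_px, 3 / ps, 0.8)
    les_idx <- which(fld$lesion)
    if (length(les_idx) > 0L) {
      n_les_nuc <- round(0.12 * length(les_idx))
      ctrs <- sample(les_idx, n_les_nuc, replace = TRUE)
      hae <- paint_discs(hae, (ctrs - 1L) %% H + 1L, (ctrs - 1L) %/% H + 1L,
                         2 / ps, 0.9)
    }
    eos <- matrix(0, H, W); eos[tissue] <- 0.55
    eos[fld$lesion] <- 0.25 * runif(sum(fld$lesion))
    qz <- function(x) pmin(pmax(round(x + rnorm(length(x), 0, 1.0)), 0), 255)
    srfg[] <- qz(srfg); he <- od_to_rgb(list(hae, eos), he_model); he[] <- qz(he)
    list(channels = chs, srfg = srfg, he = he)
  })

  channels <- lapply(names(rend$channels), function(nm)
    channel_image(rend$channels[[nm]], ps, nm))
  names(channels) <- names(rend$channels)
  brightfield <- list(sirius_fastgreen = calibrated_rgb(rend$srfg, ps),
                      he = calibrated_rgb(rend$he, ps))

  fiber_table <- data.frame(fiber_id = seq_len(n_fib),
                            area_um2 = areas_px * ps^2,
                            is_cnf = seq_len(n_fib) %in% true_cnf_ids,
                            is_igm = seq_len(n_fib) %in% mk$igm_ids,
                            is_emyhc = seq_len(n_fib) %in% mk$em_ids)
  truth <- structure(list(
    fiber_labels = fibers,
    nucleus_table = nuc,
    fiber_table = fiber_table,
    tissue_mask = tissue,
    collagen_mask = fld$collagen,
    infiltrate_mask = fld$lesion,
    region_class_map = region_class_map(fld$classes, ps),
    psmad2_mask = fld$psmad2,
    igm_fiber_ids = mk$igm_ids,
    emyhc_fiber_ids = mk$em_ids,
    pdgfra_nucleus_ids = mk$fap_ids,
    true_cnf_fraction = true_cnf_fraction,
    true_collagen_fraction = sum(fld$collagen) / sum(tissue),
    true_necrotic_fraction = sum(fld$lesion) / sum(tissue),
    true_psmad2_positivity = fld$psmad2_realized,
    n_fibers = n_fib), class = "phantom_truth")

  structure(list(spec = spec, channels = channels, brightfield = brightfield,
                 truth = truth),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %dx%d px, %d fibres, CNF %.2f, collagen %.3f, necrotic %.3f\n",
              x$spec$field_size_px[1], x$spec$field_size_px[2],
              x$truth$n_fibers, x$truth$true_cnf_fraction,
              x$truth$true_collagen_fraction, x$truth$true_necrotic_fraction))
  invisible(x)
}

#' Write a phantom to disk (images, tables, ground-truth scalars)
#'
#' @param phantom result of [generate_phantom()].
#' @param out_dir output directory.
#' @return manifest from [write_results()], invisibly.
#' @export
write_phantom <- function(phantom, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_ome_tiff(phantom$channels, file.path(out_dir, "fluorescence.ome.tif"))
  write_rgb_png(phantom$brightfield$sirius_fastgreen,
                file.path(out_dir, "sirius_fastgreen.png"))
  write_rgb_png(phantom$brightfield$he, file.path(out_dir, "he.png"))
  tr <- phantom$truth
  scalars <- list(true_cnf_fraction = tr$true_cnf_fraction,
                  true_collagen_fraction = tr$true_collagen_fraction,
                  true_necrotic_fraction = tr$true_necrotic_fraction,
                  true_psmad2_positivity = as.list(tr$true_psmad2_positivity),
                  n_fibers = tr$n_fibers)
  writeLines(jsonlite::toJSON(scalars, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "ground_truth.json"))
  write_results(list(nucleus_table = tr$nucleus_table,
                     fiber_table = tr$fiber_table),
                out_dir,
                masks = list(fiber_labels = tr$fiber_labels$labels),
                config = unclass(phantom$spec), seed = phantom$spec$seed,
                pixel_size_um = phantom$spec$pixel_size_um)
}
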