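# RT-qPCR relative quantification: standard-curve fitting and amplification
# efficiency, relative quantities, geNorm gene-stability M and pairwise
# variation V, normalization factors, and per-group fold changes.
#
# Conventions: Ct is log-scale, so technical replicates are aggregated by
# geometric mean on the quantity scale; geNorm ratios use log2, as in the
# original description of the method.

#' Validate and classify a long-format qPCR plate table
#'
#' @param df data frame with columns `gene`, `sample`, `group`, `replicate`,
#'   `ct`, `is_dilution_standard` (logical) and `dilution_factor` (relative
#'   input for standard rows, NA otherwise).
#' @return the validated data frame, classed `qpcr_plate`.
#' @export
qpcr_plate <- function(df) {
  need <- c("gene", "sample", "group", "replicate", "ct",
            "is_dilution_standard", "dilution_factor")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("qpcr_plate: missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$ct))) stop("qpcr_plate: non-finite Ct values")
  structure(df, class = c("qpcr_plate", "data.frame"))
}

#' Simulate a qPCR plate with known ground truth
#'
#' Ct values follow the log-linear amplification model
#' `Ct = intercept - log10(quantity) / log10(1 + E) + N(0, noise_sd_ct)`,
#' with per-gene efficiency E. Each gene also gets a 10-fold dilution
#' series of `dilution_steps` points for standard-curve fitting.
#' Deterministic under `seed`.
#'
#' @param genes character vector of gene names.
#' @param groups character vector of group names (first = control by
#'   convention).
#' @param n_per_group biological samples per group.
#' @param efficiencies named per-gene amplification efficiencies in (0, 1].
#' @param base_quantities genes x groups matrix of true mean quantities
#'   (positive; dimnames must match `genes`/`groups`).
#' @param noise_sd_ct replicate Gaussian noise SD in Ct units.
#' @param dilution_steps number of 10-fold dilution points (>= 3).
#' @param n_replicates technical replicates per well (default 2).
#' @param intercepts optional named per-gene Ct at quantity 1 (default 24).
#' @param seed integer seed.
#' @return A [qpcr_plate()] with attribute `true_quantities` (long table of
#'   the noise-free per-sample quantities).
#' @export
generate_qpcr_plate <- function(genes, groups, n_per_group, efficiencies,
                                base_quantities, noise_sd_ct = 0.1,
                                dilution_steps = 5L, n_replicates = 2L,
                                intercepts = NULL, seed = 1L) {
  if (any(efficiencies <= 0 | efficiencies > 1))
    stop("generate_qpcr_plate: efficiencies must be in (0, 1]")
  if (dilution_steps < 3L) stop("generate_qpcr_plate: dilution_steps must be >= 3")
  bq <- as.matrix(base_quantities)
  if (any(bq <= 0)) stop("generate_qpcr_plate: quantities must be positive")
  effs <- rep(efficiencies, length.out = length(genes))
  names(effs) <- genes
  ic <- intercepts %||% setNames(rep(24, length(genes)), genes)
  ct_of <- function(g, q) ic[[g]] - log10(q) / log10(1 + effs[[g]])
  with_seed(seed, {
    rows <- list(); truth <- list(); k <- 0L
    for (gi in seq_along(genes)) for (grp in seq_along(groups)) {
      for (s in seq_len(n_per_group)) {
        sample_id <- sprintf("%s_%02d", groups[grp], s)
        q <- bq[gi, grp]
        truth[[length(truth) + 1L]] <-
          data.frame(gene = genes[gi], sample = sample_id,
                     group = groups[grp], quantity = q)
        for (r in seq_len(n_replicates)) {
          k <- k + 1L
          rows[[k]] <- data.frame(
            gene = genes[gi], sample = sample_id, group = groups[grp],
            replicate = r,
            ct = ct_of(genes[gi], q) + rnorm(1L, 0, noise_sd_ct),
            is_dilution_standard = FALSE, dilution_factor = NA_real_)
        }
      }
    }
    for (gi in seq_along(genes)) for (d in seq_len(dilution_steps)) {
      rel <- 10^(-(d - 1L))
      for (r in seq_len(n_replicates)) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          gene = genes[gi], sample = sprintf("std_%d", d), group = "standard",
          replicate = r,
          ct = ct_of(genes[gi], rel) + rnorm(1L, 0, noise_sd_ct),
          is_dilution_standard = TRUE, dilution_factor = rel)
      }
    }
    plate <- qpcr_plate(do.call(rbind, rows))
    attr(plate, "true_quantities") <- do.call(rbind, truth)
    plate
  })
}

#' Fit a dilution-series standard curve
#'
#' Least-squares fit of mean Ct against log10 relative input over the
#' gene's dilution standards; amplification efficiency
#' `E = 10^(-1/slope) - 1`. A slope of -3.3219 corresponds to 100%
#' efficiency. Non-negative slopes flag the curve invalid; efficiencies
#' outside (0.8, 1.1) are flagged with a warning band note.
#'
#' @param plate a [qpcr_plate()].
#' @param gene gene name.
#' @return list of class `standard_curve`: `gene`, `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `valid`, `warning_band`.
#' @export
fit_standard_curve <- function(plate, gene) {
  std <- plate[plate$is_dilution_standard & plate$gene == gene, , drop = FALSE]
  pts <- unique(std$dilution_factor)
  if (length(pts) < 3L)
    stop("fit_standard_curve: gene '", gene, "' has ", length(pts),
         " dilution points; need >= 3")
  mct <- aggregate(ct ~ dilution_factor, std, mean)
  fit <- lm(ct ~ log10(dilution_factor), data = mct)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  ss_tot <- sum((mct$ct - mean(mct$ct))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else NA_real_
  eff <- if (slope < 0) 10^(-1 / slope) - 1 else NA_real_
  structure(list(gene = gene, slope = slope, intercept = intercept,
                 r_squared = r2, efficiency = eff,
                 valid = slope < 0,
                 warning_band = is.na(eff) || eff < 0.8 || eff > 1.1),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> %s: slope %.4f, E = %.1f%%, r2 = %.4f%s\n",
              x$gene, x$slope, 100 * x$efficiency, x$r_squared,
              if (!x$valid) " [INVALID]" else if (x$warning_band) " [warning band]" else ""))
  invisible(x)
}

#' Relative quantity from a Ct value
#'
#' `quantity = 10^((ct - intercept) / slope)`; `ct = intercept` maps to
#' quantity 1.
#'
#' @param ct numeric Ct value(s).
#' @param curve a [fit_standard_curve()] result.
#' @return positive relative quantity.
#' @export
relative_quantity <- function(ct, curve) {
  if (!curve$valid) stop("relative_quantity: invalid standard curve for ", curve$gene)
  10^((ct - curve$intercept) / curve$slope)
}

#' Per-sample relative quantities, replicates aggregated geometrically
#'
#' @param plate a [qpcr_plate()].
#' @param curves named list of standard curves (one per gene; default:
#'   fitted from the plate's dilution series).
#' @return data frame `gene`, `sample`, `group`, `quantity`, `replicate_cv`.
#' @export
sample_quantities <- function(plate, curves = NULL) {
  sm <- plate[!plate$is_dilution_standard, , drop = FALSE]
  genes <- unique(sm$gene)
  if (is.null(curves))
    curves <- setNames(lapply(genes, fit_standard_curve, plate = plate), genes)
  out <- lapply(split(sm, list(sm$gene, sm$sample), drop = TRUE), function(d) {
    q <- relative_quantity(d$ct, curves[[d$gene[1]]])
    data.frame(gene = d$gene[1], sample = d$sample[1], group = d$group[1],
               quantity = geometric_mean(q),
               replicate_cv = if (length(q) > 1L) sd(q) / mean(q) else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# samples x genes quantity matrix from the long table
quantity_matrix <- function(quantities) {
  m <- with(quantities, tapply(quantity, list(sample, gene), mean))
  if (any(is.na(m))) stop("quantity table is not complete over samples x genes")
  m
}

#' geNorm gene-stability measure M
#'
#' For gene j, `M_j` is the mean over all other genes k of the standard
#' deviation across samples of `log2(q_j / q_k)`: genes whose expression
#' ratios to all other candidates are most constant get the lowest M.
#'
#' @param quantities long table from [sample_quantities()] (or any data
#'   frame with `gene`, `sample`, `quantity`), or a samples x genes matrix.
#' @return named numeric vector of M values.
#' @export
genorm_m <- function(quantities) {
  m <- if (is.matrix(quantities)) quantities else quantity_matrix(quantities)
  if (ncol(m) < 2L) stop("genorm_m: need at least 2 genes")
  if (nrow(m) < 2L) stop("genorm_m: need at least 2 samples")
  if (any(m <= 0)) stop("genorm_m: nonpositive quantity")
  lg <- log2(m)
  vapply(seq_len(ncol(m)), function(j) {
    mean(vapply(setdiff(seq_len(ncol(m)), j), function(k)
      sd(lg[, j] - lg[, k]), numeric(1)))
  }, numeric(1)) |> setNames(colnames(m))
}

#' geNorm stability ranking by iterative exclusion
#'
#' Repeatedly drops the least stable (highest M) gene and recomputes M,
#' producing the geNorm ranking; the final pair is reported in arbitrary
#' order (M is identical for the last two genes).
#'
#' @inheritParams genorm_m
#' @return list with `ranking` (least to most stable) and `m_steps`.
#' @export
genorm_rank <- function(quantities) {
  m <- if (is.matrix(quantities)) quantities else quantity_matrix(quantities)
  dropped <- character(0); steps <- list()
  while (ncol(m) > 2L) {
    M <- genorm_m(m)
    steps[[length(steps) + 1L]] <- M
    worst <- names(which.max(M))
    dropped <- c(dropped, worst)
    m <- m[, setdiff(colnames(m), worst), drop = FALSE]
  }
  steps[[length(steps) + 1L]] <- genorm_m(m)
  list(ranking = c(dropped, colnames(m)), m_steps = steps)
}

#' geNorm pairwise variation V(n/n+1)
#'
#' `V_n = sd(log2(NF_n / NF_{n+1}))` across samples, where NF_n is the
#' geometric mean of the n most stable genes; small V means the (n+1)-th
#' gene adds nothing to the normalization factor.
#'
#' @inheritParams genorm_m
#' @return data frame `n`, `comparison`, `v`.
#' @export
genorm_v <- function(quantities) {
  m <- if (is.matrix(quantities)) quantities else quantity_matrix(quantities)
  if (ncol(m) < 3L) stop("genorm_v: need at least 3 genes")
  ranking <- rev(genorm_rank(m)$ranking)  # most stable first
  out <- lapply(2:(ncol(m) - 1L), function(n) {
    nf_n  <- apply(log2(m[, ranking[1:n], drop = FALSE]), 1, mean)
    nf_n1 <- apply(log2(m[, ranking[1:(n + 1L)], drop = FALSE]), 1, mean)
    data.frame(n = n, comparison = sprintf("V%d/%d", n, n + 1L),
               v = sd(nf_n - nf_n1))
  })
  do.call(rbind, out)
}

#' Normalization factors and per-group fold changes
#'
#' The per-sample normalization factor is the geometric mean of the
#' reference genes' quantities, rescaled to overall geometric mean 1;
#' normalized quantity = quantity / NF; the fold change of each group is
#' the ratio of its geometric mean normalized quantity to the control
#' group's. Works with a single reference gene or a geNorm multi-reference
#' set.
#'
#' @param quantities long table from [sample_quantities()].
#' @param reference_genes character vector of reference gene names
#'   (e.g. `"Hprt"`).
#' @param control_group name of the control group (fold change 1 by
#'   construction up to sampling noise).
#' @return list with `normalization_factors` (per sample), `normalized`
#'   (long table with `normalized_quantity`), `fold_changes` (gene x group
#'   table).
#' @export
normalization_and_fold_change <- function(quantities, reference_genes,
                                          control_group) {
  if (length(reference_genes) == 0L)
    stop("normalization_and_fold_change: empty reference set")
  if (!control_group %in% quantities$group)
    stop("normalization_and_fold_change: control group '", control_group,
         "' not present")
  if (!all(reference_genes %in% quantities$gene))
    stop("normalization_and_fold_change: missing reference gene(s): ",
         paste(setdiff(reference_genes, quantities$gene), collapse = ", "))
  m <- quantity_matrix(quantities)
  nf <- apply(m[, reference_genes, drop = FALSE], 1, geometric_mean)
  nf <- nf / geometric_mean(nf)
  quantities$normalized_quantity <-
    quantities$quantity / nf[quantities$sample]
  targets <- setdiff(unique(quantities$gene), reference_genes)
  fc <- lapply(targets, function(g) {
    d <- quantities[quantities$gene == g, ]
    ctrl <- geometric_mean(d$normalized_quantity[d$group == control_group])
    gm <- tapply(d$normalized_quantity, d$group, geometric_mean) / ctrl
    data.frame(gene = g, group = names(gm), fold_change = as.numeric(gm))
  })
  list(normalization_factors = nf,
       normalized = quantities,
       fold_changes = do.call(rbind, fc))
}
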