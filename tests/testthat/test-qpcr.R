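# Standard curves, relative quantities, geNorm statistics and fold changes.

perfect_plate <- function() {
  generate_qpcr_plate(genes = c("Col3a1", "Hprt"), groups = c("wt", "mdx"),
                      n_per_group = 3, efficiencies = c(1, 1),
                      base_quantities = rbind(c(1, 2), c(1, 1)),
                      noise_sd_ct = 0, dilution_steps = 5, seed = 2)
}

test_that("a perfect 10-fold dilution series gives slope -3.3219, E = 100%", {
  plate <- perfect_plate()
  cv <- fit_standard_curve(plate, "Col3a1")
  expect_equal(cv$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(cv$efficiency, 1, tolerance = 1e-3)
  expect_equal(cv$r_squared, 1, tolerance = 1e-9)
  # closed-form efficiency at slope -3.5
  fake <- cv; fake$slope <- -3.5
  expect_equal(10^(-1 / fake$slope) - 1, 0.9307, tolerance = 1e-4)
})

test_that("too few dilution points and nonpositive inputs error", {
  plate <- perfect_plate()
  two <- plate[!(plate$is_dilution_standard & plate$dilution_factor <= 1e-2), ]
  expect_error(fit_standard_curve(qpcr_plate(two), "Col3a1"), ">= 3")
  expect_error(generate_qpcr_plate("g", "a", 2, efficiencies = 1.5,
                                   base_quantities = matrix(1),
                                   seed = 1), "efficienc")
  expect_error(generate_qpcr_plate("g", "a", 2, efficiencies = 1,
                                   base_quantities = matrix(-1),
                                   seed = 1), "positive")
})

test_that("relative quantities invert the curve exactly", {
  plate <- perfect_plate()
  cv <- fit_standard_curve(plate, "Hprt")
  expect_equal(relative_quantity(cv$intercept, cv), 1)
  expect_equal(relative_quantity(cv$intercept + cv$slope, cv), 10)
  q <- sample_quantities(plate)
  truth <- attr(plate, "true_quantities")
  merged <- merge(q, truth, by = c("gene", "sample"), suffixes = c("", "_true"))
  expect_equal(merged$quantity, merged$quantity_true, tolerance = 1e-9)
})

test_that("noise-free generated quantities are recovered within 1 percent", {
  plate <- generate_qpcr_plate(genes = c("a", "b"), groups = c("g1", "g2"),
                               n_per_group = 4, efficiencies = c(0.9, 0.95),
                               base_quantities = rbind(c(1, 3), c(2, 0.5)),
                               noise_sd_ct = 0, seed = 5)
  q <- sample_quantities(plate)
  truth <- attr(plate, "true_quantities")
  m <- merge(q, truth, by = c("gene", "sample"), suffixes = c("", "_true"))
  expect_equal(m$quantity, m$quantity_true, tolerance = 0.01)
})

test_that("generation under a fixed seed is reproducible; E=1 gives dCt -3.3219", {
  p1 <- perfect_plate(); p2 <- perfect_plate()
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  # quantities 1 vs 10 at E = 1, no noise
  pl <- generate_qpcr_plate("g", c("a", "b"), 1, efficiencies = 1,
                            base_quantities = matrix(c(1, 10), 1),
                            noise_sd_ct = 0, seed = 3)
  cts <- tapply(pl$ct[!pl$is_dilution_standard],
                pl$group[!pl$is_dilution_standard], mean)
  expect_equal(unname(cts["b"] - cts["a"]), -1 / log10(2), tolerance = 1e-9)
})

test_that("geNorm M: proportional genes are perfectly stable", {
  q <- data.frame(gene = rep(c("a", "b"), each = 4),
                  sample = rep(sprintf("s%d", 1:4), 2),
                  quantity = c(1, 2, 4, 8, 3, 6, 12, 24))
  M <- genorm_m(q)
  expect_true(all(M < 1e-10))
  expect_error(genorm_m(transform(q, quantity = quantity - 1)), "onpositive")
})

test_that("geNorm M matches the brute-force definition on a toy table", {
  withr::local_seed(77)
  qm <- matrix(exp(rnorm(12)), 4, 3,
               dimnames = list(sprintf("s%d", 1:4), c("a", "b", "c")))
  expect_equal(unname(genorm_m(qm)), brute_genorm_m(qm), tolerance = 1e-12)
})

test_that("M grows with noise; M is invariant to relabelling and rescaling", {
  withr::local_seed(55)
  base <- matrix(exp(rnorm(40, 0, 0.1)), 10, 4,
                 dimnames = list(sprintf("s%d", 1:10), letters[1:4]))
  Ms <- vapply(c(0.05, 0.3, 1), function(sg) {
    noisy <- base
    noisy[, "a"] <- noisy[, "a"] * exp(rnorm(10, 0, sg))
    genorm_m(noisy)[["a"]]
  }, numeric(1))
  expect_true(all(diff(Ms) > 0))
  M0 <- genorm_m(base)
  expect_equal(genorm_m(base[sample(10), ]), M0)
  scaled <- base; scaled[, "b"] <- scaled[, "b"] * 1000
  expect_equal(genorm_m(scaled), M0)
  # the noisiest gene is dropped first in the ranking
  noisy <- base; noisy[, "c"] <- noisy[, "c"] * exp(rnorm(10, 0, 2))
  expect_equal(genorm_rank(noisy)$ranking[1], "c")
})

test_that("adding a gene equal to the reference geometric mean leaves NF unchanged", {
  withr::local_seed(9)
  q1 <- exp(rnorm(6)); q2 <- exp(rnorm(6))
  q3 <- sqrt(q1 * q2) * 5
  long <- data.frame(gene = rep(c("a", "b", "c", "t"), each = 6),
                     sample = rep(sprintf("s%d", 1:6), 4),
                     group = rep(rep(c("wt", "tr"), each = 3), 4),
                     quantity = c(q1, q2, q3, exp(rnorm(6))))
  nf2 <- normalization_and_fold_change(long, c("a", "b"), "wt")
  nf3 <- normalization_and_fold_change(long, c("a", "b", "c"), "wt")
  expect_equal(nf2$normalization_factors, nf3$normalization_factors,
               tolerance = 1e-12)
  v <- genorm_v(long[long$gene != "t", ])
  expect_s3_class(v, "data.frame")
})

test_that("normalization absorbs per-sample scale; fold changes are exact", {
  q <- expand.grid(sample = sprintf("s%d", 1:6), gene = c("Hprt", "Tgfb1"))
  q$group <- rep(c("wt", "wt", "wt", "mdx", "mdx", "mdx"), 2)
  q$quantity <- 1
  q$quantity[q$gene == "Tgfb1" & q$group == "mdx"] <- 2
  res <- normalization_and_fold_change(q, "Hprt", "wt")
  expect_true(all(abs(res$normalization_factors - 1) < 1e-12))
  fc <- res$fold_changes
  expect_equal(fc$fold_change[fc$group == "mdx"], 2)
  expect_equal(fc$fold_change[fc$group == "wt"], 1)
  # multiplying one sample's quantities by a constant changes nothing
  q2 <- q
  q2$quantity[q2$sample == "s5"] <- q2$quantity[q2$sample == "s5"] * 37
  res2 <- normalization_and_fold_change(q2, "Hprt", "wt")
  expect_equal(res2$fold_changes$fold_change, fc$fold_change, tolerance = 1e-12)
  expect_error(normalization_and_fold_change(q, "Hprt", "sham"), "control group")
  expect_error(normalization_and_fold_change(q, character(0), "wt"), "reference")
})

test_that("generated fold changes survive realistic noise within 15 percent", {
  fc_true <- c(0.5, 1, 2, 4)
  plate <- generate_qpcr_plate(
    genes = c("t1", "t2", "t3", "t4", "Hprt"),
    groups = c("wt", "mdx"), n_per_group = 6,
    efficiencies = rep(0.95, 5),
    base_quantities = rbind(cbind(1, fc_true), c(1, 1)),
    noise_sd_ct = 0.1, seed = 8)
  q <- sample_quantities(plate)
  res <- normalization_and_fold_change(q, "Hprt", "wt")
  fc <- res$fold_changes
  got <- fc$fold_change[fc$group == "mdx"][match(c("t1", "t2", "t3", "t4"),
                                                 fc$gene[fc$group == "mdx"])]
  expect_true(all(abs(got / fc_true - 1) < 0.15))
})
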