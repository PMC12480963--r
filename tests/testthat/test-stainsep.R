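# Optical density conversion, colour deconvolution round trips, collagen
# and myonecrosis scoring.

test_that("rgb_to_od hits its closed forms and the floor contract", {
  px <- array(0, c(1, 3, 3))
  px[1, 1, ] <- 255                  # background -> OD 0
  px[1, 2, ] <- 25.5                 # background/10 -> OD 1
  px[1, 3, ] <- 0                    # floored
  od <- rgb_to_od(px, c(255, 255, 255), od_floor = 0.5)
  expect_equal(od[1, 1, ], c(0, 0, 0))
  expect_equal(od[1, 2, ], c(1, 1, 1))
  expect_equal(od[1, 3, ], rep(-log10(0.5 / 255), 3))
  expect_true(all(is.finite(od)))
  expect_error(rgb_to_od(px, c(0, 255, 255)), "positive")
})

test_that("deconvolution recovers pure stains and the identity model", {
  m <- stain_model_sirius_fastgreen()
  od <- array(0, c(2, 2, 3))
  for (c in 1:3) od[, , c] <- 0.8 * m$stain_matrix[1, c]
  d <- deconvolve(od, m)
  expect_equal(d$sirius_red, matrix(0.8, 2, 2), tolerance = 1e-12)
  expect_equal(d$fast_green, matrix(0, 2, 2), tolerance = 1e-12)
  ident <- stain_model(c("r", "g", "b"), diag(3))
  od2 <- array(runif(12), c(2, 2, 3))
  d2 <- deconvolve(od2, ident)
  expect_equal(d2$r, od2[, , 1])
  expect_equal(d2$b, od2[, , 3])
  expect_error(stain_model(c("a", "b"),
                           rbind(c(0.6, 0.7, 0.3), c(0.6, 0.7, 0.300001))),
               "parallel|conditioned")
})

test_that("forward-compose / deconvolve round trip is exact to 1e-6", {
  m <- stain_model_sirius_fastgreen()
  withr::local_seed(3)
  n <- 1e5
  d_true <- cbind(runif(n, 0, 2), runif(n, 0, 2))
  dens <- array(0, c(n, 1, 2))
  dens[, 1, 1] <- d_true[, 1]; dens[, 1, 2] <- d_true[, 2]
  rgb <- od_to_rgb(dens, m)                     # float intensities, no quantization
  rec <- deconvolve(rgb_to_od(rgb, m$background_intensity, od_floor = 1e-30), m)
  expect_lt(max(abs(rec$sirius_red[, 1] - d_true[, 1])), 1e-6)
  expect_lt(max(abs(rec$fast_green[, 1] - d_true[, 2])), 1e-6)
  expect_lt(max(attr(rec, "clip_fraction")[1:2]), 1e-6)
})

test_that("negative-density clipping is reported, not silent", {
  m <- stain_model_sirius_fastgreen()
  od <- array(0, c(1, 1, 3))
  od[1, 1, ] <- -0.5 * m$stain_matrix[1, ] + 0.5 * m$stain_matrix[2, ]
  d <- deconvolve(od, m)
  expect_equal(d$sirius_red[1, 1], 0)
  expect_gt(attr(d, "clip_fraction")["sirius_red"], 0)
})

test_that("collagen fraction spans its closed-form extremes", {
  m <- stain_model_sirius_fastgreen()
  tis <- matrix(TRUE, 40, 40)
  pure_fg <- od_to_rgb(list(matrix(0, 40, 40), matrix(0.9, 40, 40)), m)
  r0 <- collagen_fraction(pure_fg, m, tissue = tis, pixel_size_um = 1)
  expect_equal(r0$collagen_percent, 0)
  pure_sr <- od_to_rgb(list(matrix(1.1, 40, 40), matrix(0, 40, 40)), m)
  r100 <- collagen_fraction(pure_sr, m, tissue = tis, pixel_size_um = 1,
                            threshold_method = "fixed", fixed_threshold = 0.5)
  expect_equal(r100$collagen_percent, 100)
  expect_error(collagen_fraction(pure_sr, m, tissue = matrix(FALSE, 40, 40),
                                 pixel_size_um = 1), "empty tissue")
})

test_that("generated collagen fractions are recovered within 3 points", {
  ph <- small_phantom(collagen_fraction = 0.2, seed = 19)
  r <- collagen_fraction(ph$brightfield$sirius_fastgreen,
                         tissue = ph$truth$tissue_mask)
  expect_lte(abs(r$collagen_percent - 20), 3)
})

test_that("collagen percent is invariant to uniform illumination rescale", {
  ph <- small_phantom(collagen_fraction = 0.1, seed = 19, key = "illum")
  rgb <- ph$brightfield$sirius_fastgreen
  base <- collagen_fraction(rgb, tissue = ph$truth$tissue_mask)
  m2 <- stain_model(c("sirius_red", "fast_green"),
                    stain_model_sirius_fastgreen()$stain_matrix[1:2, ],
                    background_intensity = rep(255 * 1.6, 3))
  scaled <- rgb * 1.6
  attr(scaled, "pixel_size_um") <- attr(rgb, "pixel_size_um")
  r2 <- collagen_fraction(scaled, m2, tissue = ph$truth$tissue_mask)
  expect_equal(r2$collagen_percent, base$collagen_percent, tolerance = 0.02)
})

test_that("necrosis scoring recovers generated lesion burden", {
  ph0 <- small_phantom(necrotic_fraction = 0, seed = 19)
  r0 <- infiltrate_mask(ph0$brightfield$he, tissue = ph0$truth$tissue_mask)
  expect_equal(r0$necrotic_percent, 0)
  ph <- small_phantom(necrotic_fraction = 0.15, seed = 19)
  r <- infiltrate_mask(ph$brightfield$he, tissue = ph$truth$tissue_mask)
  expect_lte(abs(r$necrotic_percent - 15), 3)
})

test_that("full-tissue infiltrate saturates at exactly 100 percent", {
  m <- stain_model_he()
  withr::local_seed(8)
  hae <- matrix(0.05, 60, 60)
  idx <- which(matrix(runif(3600) < 0.6, 60, 60))
  hae[idx] <- 0.9                          # packed nuclei everywhere
  rgb <- od_to_rgb(list(hae, matrix(0.4, 60, 60)), m)
  r <- infiltrate_mask(rgb, m, tissue = matrix(TRUE, 60, 60), pixel_size_um = 1)
  expect_equal(r$necrotic_percent, 100)
})

test_that("fragmented-sarcoplasm fibres join the necrotic mask", {
  m <- stain_model_he()
  withr::local_seed(12)
  eos <- matrix(0.5, 50, 50)
  lab <- matrix(0L, 50, 50)
  lab[5:20, 5:20] <- 1L                    # uniform fibre
  lab[30:45, 30:45] <- 2L                  # ragged fibre
  eos[lab == 2L] <- sample(c(0.08, 0.95), sum(lab == 2L), replace = TRUE)
  rgb <- od_to_rgb(list(matrix(0.02, 50, 50), eos), m)
  r <- infiltrate_mask(rgb, m, tissue = matrix(TRUE, 50, 50), pixel_size_um = 1,
                       fibers = fiber_label_map(lab, 1))
  expect_identical(r$fragmented_fiber_ids, 2L)
})
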