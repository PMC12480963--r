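# Marker positivity (per fibre, per cell, per region class).

test_that("fibre positivity hits its trivial extremes", {
  ph <- small_phantom(seed = 5, cnf_fraction = 0, collagen_fraction = 0)
  fib <- ph$truth$fiber_labels
  zero <- channel_image(matrix(0, nrow(fib$labels), ncol(fib$labels)), 1, "m")
  expect_equal(positive_fiber_fraction(zero, fib)$value, 0)
  sat <- channel_image(matrix(200, nrow(fib$labels), ncol(fib$labels)), 1, "m")
  expect_equal(positive_fiber_fraction(sat, fib,
                                       min_positive_area_fraction = 0)$value, 1)
})

test_that("generated IgM-positive fibres are identified", {
  ph <- small_phantom(igm_positive_fraction = 0.1, seed = 29)
  fib <- ph$truth$fiber_labels
  sc <- positive_fiber_fraction(ph$channels$IgM, fib)
  expect_lte(abs(sc$value - 0.1), 0.03)
  expect_setequal(sc$positive_fiber_ids, ph$truth$igm_fiber_ids)
})

test_that("positive-fibre density uses the exact tissue area", {
  lab <- matrix(0L, 500, 500)                      # 1 mm^2 at 2 um/px
  id <- 0L
  for (i in 0:3) for (j in 0:2) {
    id <- id + 1L
    lab[40 + i * 110 + 1:20, 40 + j * 150 + 1:20] <- id
  }
  fib <- fiber_label_map(lab, 2)
  img <- matrix(0, 500, 500)
  img[lab > 0] <- 100                               # all 12 fibres positive
  d <- positive_fiber_density(channel_image(img, 2, "eMyHC"), fib,
                              tissue = matrix(TRUE, 500, 500),
                              threshold_method = "fixed", fixed_threshold = 50)
  expect_equal(d$value, 12)
  expect_equal(positive_fiber_density(channel_image(img * 0, 2, "eMyHC"), fib,
                                      matrix(TRUE, 500, 500))$value, 0)
})

test_that("generated eMyHC density is recovered within 10 percent", {
  ph <- small_phantom(emyhc_count_per_mm2 = 60, seed = 37)
  sc <- positive_fiber_density(ph$channels$eMyHC, ph$truth$fiber_labels,
                               ph$truth$tissue_mask)
  gen <- length(ph$truth$emyhc_fiber_ids) / myohisto:::mask_area_mm2(
    ph$truth$tissue_mask, 1)
  expect_lte(abs(sc$value - gen) / gen, 0.1)
})

test_that("cell positivity recovers the generated FAP fraction", {
  ph <- small_phantom(pdgfra_positive_fraction = 0.25, seed = 41)
  nuc <- ph$truth$nucleus_table
  sc <- positive_cell_fraction(ph$channels$PDGFRA, nuc)
  expect_lte(abs(sc$value - 0.25), 0.05)
  zero <- channel_image(ph$channels$PDGFRA$pixels * 0, 1, "PDGFRA")
  expect_equal(positive_cell_fraction(zero, nuc)$value, 0)
  sat <- channel_image(ph$channels$PDGFRA$pixels * 0 + 90, 1, "PDGFRA")
  expect_equal(positive_cell_fraction(sat, nuc, threshold_method = "fixed",
                                      fixed_threshold = 10)$value, 1)
  expect_error(positive_cell_fraction(zero, nuc[0, ]), "zero cells")
})

test_that("region classes partition tissue; silent channels mean healthy", {
  ph <- small_phantom(seed = 5, cnf_fraction = 0, collagen_fraction = 0)
  fib <- ph$truth$fiber_labels
  tis <- ph$truth$tissue_mask
  dims <- dim(fib$labels)
  zero <- channel_image(matrix(0, dims[1], dims[2]), 1, "x")
  reg <- classify_regions(zero, zero, fib, tis)
  expect_equal(sum(reg$classes > 0), sum(tis))
  expect_true(all(reg$classes[tis] == 1L))
})

test_that("phantom regions are recovered at >= 90 percent pixel accuracy", {
  ph <- small_phantom(necrotic_fraction = 0.12, emyhc_count_per_mm2 = 40,
                      seed = 43)
  reg <- classify_regions(ph$channels$`F4-80`, ph$channels$eMyHC,
                          ph$truth$fiber_labels, ph$truth$tissue_mask)
  tr <- ph$truth$region_class_map$classes
  on <- tr > 0 & reg$classes > 0
  expect_gte(mean(reg$classes[on] == tr[on]), 0.90)
})

test_that("region-normalized score: constructed half-coverage and saturation", {
  cls <- matrix(0L, 60, 60)
  cls[1:60, 1:20] <- 2L; cls[1:60, 21:40] <- 3L; cls[1:60, 41:60] <- 1L
  reg <- region_class_map(cls, 1)
  img <- matrix(0, 60, 60)
  img[1:30, 1:20] <- 120                       # half of the damage class
  sc <- region_normalized_score(channel_image(img, 1, "pSMAD2"), reg,
                                threshold_method = "fixed", fixed_threshold = 50)
  got <- setNames(sc$normalized_score, sc$region_class)
  expect_equal(got[["damage"]], 0.5)
  expect_equal(got[["repair"]], 0)
  expect_equal(got[["healthy"]], 0)
  sat <- region_normalized_score(channel_image(img * 0 + 200, 1, "pSMAD2"), reg)
  expect_true(all(sat$normalized_score == 1))
  # empty class reported as missing, never zero
  cls2 <- cls; cls2[cls2 == 3L] <- 1L
  sc2 <- region_normalized_score(channel_image(img, 1, "pSMAD2"),
                                 region_class_map(cls2, 1),
                                 threshold_method = "fixed", fixed_threshold = 50)
  expect_true(is.na(sc2$normalized_score[sc2$region_class == "repair"]))
  expect_error(region_normalized_score(channel_image(img, 1, "p"),
                                       region_class_map(cls * 0L, 1)),
               "all-zero")
})

test_that("a class score ignores what happens in the other classes", {
  img <- matrix(0, 60, 60)
  img[1:30, 1:20] <- 120
  mk <- channel_image(img, 1, "pSMAD2")
  cls_a <- matrix(1L, 60, 60); cls_a[, 1:20] <- 2L; cls_a[, 21:30] <- 3L
  cls_b <- matrix(1L, 60, 60); cls_b[, 1:20] <- 2L; cls_b[, 21:55] <- 3L
  s_a <- region_normalized_score(mk, region_class_map(cls_a, 1),
                                 threshold_method = "fixed", fixed_threshold = 50)
  s_b <- region_normalized_score(mk, region_class_map(cls_b, 1),
                                 threshold_method = "fixed", fixed_threshold = 50)
  expect_equal(s_a$normalized_score[s_a$region_class == "damage"],
               s_b$normalized_score[s_b$region_class == "damage"])
})

test_that("generated per-class p-SMAD2 positivity is recovered", {
  ph <- small_phantom(necrotic_fraction = 0.12, emyhc_count_per_mm2 = 40,
                      psmad2_class_positivity = c(damage = 0.6, repair = 0.3,
                                                  healthy = 0.05),
                      seed = 43, key = "psmad2")
  sc <- region_normalized_score(ph$channels$pSMAD2, ph$truth$region_class_map)
  got <- setNames(sc$normalized_score, sc$region_class)
  expect_lte(abs(got[["damage"]] - 0.6), 0.05)
  expect_lte(abs(got[["repair"]] - 0.3), 0.05)
  expect_lte(abs(got[["healthy"]] - 0.05), 0.05)
})
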