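# Tissue mask, fibre watershed and nucleus segmentation against constructed
# fixtures and phantom ground truth.

test_that("blank images raise an explicit no-tissue signal", {
  blank <- channel_image(matrix(5, 60, 60), 1)
  expect_error(tissue_mask(blank), class = "myohisto_no_tissue")
})

test_that("tissue_mask is idempotent and covers the phantom tissue", {
  ph <- small_phantom(seed = 5, cnf_fraction = 0, collagen_fraction = 0)
  tm <- tissue_mask(ph$channels$laminin)
  expect_gte(mean(tm$mask[ph$truth$tissue_mask]), 0.99)
  tm2 <- tissue_mask(channel_image(tm$mask * 1, 1))
  expect_identical(tm2$mask, tm$mask)
})

test_that("a 2x2 grid of interiors separated by bright lines yields 4 fibres", {
  img <- matrix(10, 42, 42)
  img[20:21, ] <- 200
  img[, 20:21] <- 200
  fib <- segment_fibers(channel_image(img, 1), tissue = matrix(TRUE, 42, 42),
                        params = segmentation_params(smoothing_sigma_um = 0))
  expect_length(fiber_ids(fib), 4)
  expect_true(all(fib$labels[5, 5] != 0, fib$labels[30, 30] != 0))
  expect_equal(fib$labels[20, 10], 0L)          # line pixels are background
  expect_setequal(fib$border_ids, fiber_ids(fib))  # all touch the field border
})

test_that("constant laminin raises a quality error", {
  expect_error(segment_fibers(channel_image(matrix(7, 50, 50), 1)),
               class = "myohisto_quality")
})

test_that("phantom fibres are recovered with F1 >= 0.90 at IoU 0.5", {
  ph <- small_phantom(seed = 5, cnf_fraction = 0, collagen_fraction = 0)
  tis <- tissue_mask(ph$channels$laminin)$mask
  fib <- segment_fibers(ph$channels$laminin, tissue = tis)
  tl <- ph$truth$fiber_labels$labels; dl <- fib$labels
  on <- tl > 0 & dl > 0
  pairs <- table(tl[on], dl[on])
  ta <- tabulate(tl[tl > 0]); da <- tabulate(dl[dl > 0])
  best <- apply(pairs, 1, max)
  match_j <- as.integer(colnames(pairs))[apply(pairs, 1, which.max)]
  iou <- best / (ta[as.integer(rownames(pairs))] + da[match_j] - best)
  tp <- sum(iou >= 0.5)
  prec <- tp / sum(da > 0); rec <- tp / ph$truth$n_fibers
  f1 <- 2 * prec * rec / (prec + rec)
  expect_gte(f1, 0.90)
  # interiors never overlap by construction of a label map
  expect_true(all(table(dl[dl > 0]) >= 1))
})

test_that("fibre detection quality does not improve as SNR halves", {
  f1_at <- function(snr) {
    ph <- small_phantom(marker_snr = snr, cnf_fraction = 0,
                        collagen_fraction = 0, seed = 13)
    tl <- ph$truth$fiber_labels$labels
    fib <- tryCatch(segment_fibers(ph$channels$laminin,
                                   tissue = ph$truth$tissue_mask),
                    error = function(e) NULL)
    if (is.null(fib)) return(0)
    dl <- fib$labels
    on <- tl > 0 & dl > 0
    pairs <- table(tl[on], dl[on])
    ta <- tabulate(tl[tl > 0]); da <- tabulate(dl[dl > 0])
    best <- apply(pairs, 1, max)
    match_j <- as.integer(colnames(pairs))[apply(pairs, 1, which.max)]
    iou <- best / (ta[as.integer(rownames(pairs))] + da[match_j] - best)
    tp <- sum(iou >= 0.5)
    prec <- tp / sum(da > 0); rec <- tp / max(1, max(tl))
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  f1 <- vapply(c(16, 8, 4, 2), f1_at, numeric(1))
  expect_true(all(diff(f1) <= 0.02))   # non-increasing up to desk-scale jitter
  expect_gte(f1[1], 0.9)
})

test_that("nuclei: disjoint disks give exact centroids, touching disks split", {
  img <- matrix(0, 60, 60)
  for (ctr in list(c(15, 15), c(40, 45))) {
    for (r in 1:60) for (c in 1:60)
      if ((r - ctr[1])^2 + (c - ctr[2])^2 <= 25) img[r, c] <- 180
  }
  seg <- segment_nuclei(channel_image(img, 1),
                        segmentation_params(smoothing_sigma_um = 0))
  expect_equal(nrow(seg$centroids), 2)
  got <- seg$centroids[order(seg$centroids$row_px), ]
  expect_equal(got$row_px, c(15, 40), tolerance = 0.5)
  expect_equal(got$col_px, c(15, 45), tolerance = 0.5)

  img2 <- matrix(0, 40, 40)
  for (ctr in list(c(20, 14), c(20, 23))) {   # overlapping, two EDT maxima
    for (r in 1:40) for (c in 1:40)
      if ((r - ctr[1])^2 + (c - ctr[2])^2 <= 36) img2[r, c] <- 180
  }
  seg2 <- segment_nuclei(channel_image(img2, 1),
                         segmentation_params(smoothing_sigma_um = 0))
  expect_equal(nrow(seg2$centroids), 2)
})

test_that("phantom nuclei are recovered within 2 um at >= 95% recall", {
  ph <- small_phantom(seed = 5, cnf_fraction = 0, collagen_fraction = 0)
  seg <- segment_nuclei(ph$channels$DAPI)
  tn <- ph$truth$nucleus_table
  d2 <- outer(tn$row_px, seg$centroids$row_px, "-")^2 +
        outer(tn$col_px, seg$centroids$col_px, "-")^2
  expect_gte(mean(sqrt(apply(d2, 1, min)) <= 2), 0.95)
})
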