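# Shared small phantoms, generated once per test run and cached.  Tests use
# these desk-scale fields (~120 fibres) except where a criterion explicitly
# needs the full preset geometry.

.phantom_cache <- new.env(parent = emptyenv())

small_phantom <- function(..., key = NULL) {
  args <- utils::modifyList(
    list(field_size_px = c(340L, 340L), n_fibers_target = 25L,
         fiber_minferet_mean_um = 24, fiber_minferet_cv = 0.12,
         nuclei_per_fiber_mean = 2, seed = 42L),
    list(...))
  key <- key %||% paste(deparse(args), collapse = "")
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(do.call(phantom_spec, args))
  .phantom_cache[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Label map with ten 15x15 squares and ten 40x2 elongated bars, spaced on a
# grid -- the bars measure well below the 0.3 circularity cutoff.
squares_and_bars_labels <- function(pixel_size_um = 1) {
  m <- matrix(0L, 120, 235)
  id <- 0L
  for (i in 0:4) for (j in 0:1) {       # 10 squares
    id <- id + 1L
    m[10 + j * 55 + 1:15, 5 + i * 42 + 1:15] <- id
  }
  for (i in 0:4) for (j in 0:1) {       # 10 bars
    id <- id + 1L
    m[95 + j * 8 + 1:2, 5 + i * 46 + 1:40] <- id
  }
  fiber_label_map(m, pixel_size_um)
}
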