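# Small scenes for unit tests, and a memoised store so expensive scenes
# are generated once per run.

.scene_cache <- new.env(parent = emptyenv())

test_scene <- function(seed = 7L, ...) {
  key <- paste0("s", seed, "_", paste(deparse(list(...)), collapse = ""))
  if (!is.null(.scene_cache[[key]])) return(.scene_cache[[key]])
  args <- utils::modifyList(list(size = 384L, n_hyphae = 2L, n_bacteria = 6L,
                                 n_filaments = 5L, seed = seed), list(...))
  sc <- suppressWarnings(generate_scene(do.call(scene_params, args)))
  .scene_cache[[key]] <- sc
  sc
}

# crisp capsule-shaped rod mask (for measurement tests on exact masks)
capsule_mask <- function(dims, center, length_px, width_px, angle) {
  rr <- matrix(seq_len(dims[1L]), dims[1L], dims[2L]) - center[1L]
  cc <- matrix(seq_len(dims[2L]), dims[1L], dims[2L], byrow = TRUE) - center[2L]
  u <- cos(angle) * rr + sin(angle) * cc
  v <- -sin(angle) * rr + cos(angle) * cc
  hl <- (length_px - width_px) / 2
  d2 <- pmax(abs(u) - hl, 0)^2 + v^2
  d2 <= (width_px / 2)^2
}

# crisp solid ellipse mask
ellipse_mask <- function(dims, center, a, b, angle) {
  rr <- matrix(seq_len(dims[1L]), dims[1L], dims[2L]) - center[1L]
  cc <- matrix(seq_len(dims[2L]), dims[1L], dims[2L], byrow = TRUE) - center[2L]
  u <- cos(angle) * rr + sin(angle) * cc
  v <- -sin(angle) * rr + cos(angle) * cc
  (u / a)^2 + (v / b)^2 <= 1
}
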