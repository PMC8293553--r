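# Small-canvas scene parameters for fast unit tests (the full published
# geometry is exercised in the acceptance suite).
small_scene <- function(n = 8L, seed = 1L, ...) {
  scene_params(canvas_px = c(600L, 440L), n_tubercles = n,
               radius_range_mm = c(0.3, 1.2), seed = seed, ...)
}

# uniform RGB canvas
flat_image <- function(h, w, rgb = c(255, 255, 255)) {
  img <- array(0, dim = c(h, w, 3L))
  for (k in 1:3) img[, , k] <- rgb[k]
  img
}
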