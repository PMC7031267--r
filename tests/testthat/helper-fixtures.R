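# Shared fixtures built in code. Scenes are cached per (preset, seed,
# overrides) so tests that reuse a configuration do not re-render it.

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(preset, seed, ...) {
  key <- paste(preset, seed, deparse(list(...)), collapse = "|")
  if (is.null(.scene_cache[[key]])) {
    .scene_cache[[key]] <- generate_scene(scene_preset(preset, seed = seed, ...))
  }
  .scene_cache[[key]]
}

# Hand-built piecewise-constant trajectory for excursion-rule tests.
manual_trajectory <- function(times, A, t_end,
                              p = model_params(transient = 0)) {
  n <- length(times)
  states <- cbind(G_A = rep(1L, n), BG_A = 0L, G_B = 1L, R_A = 0L,
                  R_B = 0L, A = as.integer(A), B = 0L)
  structure(list(times = times, states = states, t_end = t_end,
                 params = p, seed = NA_integer_),
            class = "pulse_trajectory")
}

# Full processed lowmag image set (channels background-subtracted, mask,
# depth map, per-image ratio profile) for gradient tests.
lowmag_pipeline <- function(seed, bin_width_um = 2, ...) {
  cfg <- scene_preset("lowmag", seed = seed, ...)
  sc <- generate_scene(cfg)
  rfp <- subtract_background(sc$channels$rfp, cfg$background)
  yfp <- subtract_background(sc$channels$yfp, cfg$background)
  yfp <- correct_bleedthrough(yfp, rfp, cfg$bleed_through)
  bm <- segment_biofilm(rfp)
  dm <- depth_map(bm, cfg$pixel_size_um)
  list(cfg = cfg, scene = sc, rfp = rfp, yfp = yfp, mask = bm, depth = dm,
       profile = ratio_gradient(yfp, rfp, dm, bin_width_um = bin_width_um))
}

sample_skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3
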