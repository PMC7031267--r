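#!/usr/bin/env Rscript
# Render the three synthetic study scenes (low-magnification gradient
# band, high-magnification single-cell field, deep spore-density scene)
# with their ground truth, and the bleed-through control (RFP-only strain
# emulation).

library(biofilmpulse)

out <- "results/scenes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scenes <- list(
  lowmag = scene_preset("lowmag", seed = 31),
  lowmag_strip = scene_preset("lowmag", seed = 12, agar_strip_px = 30,
                              blob_radius_px = 40,
                              band_thickness_um = 120),
  highmag = scene_preset("highmag", seed = 41),
  sporedensity = scene_preset("sporedensity", seed = 51),
  rfp_only = scene_preset("lowmag", seed = 61, yfp_scale_top = 0,
                          bleed_through = 0.06)
)

for (nm in names(scenes)) {
  sc <- generate_scene(scenes[[nm]])
  files <- write_scene(sc, file.path(out, nm))
  cat(sprintf("%-13s %4d objects (%d spores) -> %d files\n", nm,
              nrow(sc$truth), sum(sc$truth$is_spore), length(files)))
}
cat("wrote", out, "\n")
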