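# biofilmpulse

Stochastic pulsing of the general stress response sigma factor σ^B^ lets
*Bacillus subtilis* biofilms keep two mutually exclusive cell states —
σ^B^-active and sporulating — in the same layer: both activities peak at
the air-facing top of the biofilm even though σ^B^ represses sporulation
in single cells. `biofilmpulse` packages the two computational halves of
that analysis for people studying noisy gene regulation in structured
microbial communities:

1. **A two-regulator pulsing model.** Two two-stage
   transcription–translation modules (`A` = sporulation, `B` = σ^B^),
   with `B` able to bind the `A` gene and block its transcription
   (`B + G_A ⇌ BG_A`). Transcription rates scale with a stress multiplier
   ζ ∈ [5×10⁻⁵, 5×10⁻³] standing in for biofilm depth (bottom → top).
   Exact Doob–Gillespie simulation; a run "produces a spore" when `A`
   spends more than 30 simulated minutes contiguously above the
   threshold θ = 1, the rounded 20th percentile of the Γ(ζ·s_A/ε, β/δ)
   stationary approximation of the isolated `A` module. Ensemble sweeps
   across the gradient reproduce the signature predictions: doubling the
   repressor pulse frequency `s_B` suppresses sporulation at the top and
   shifts its peak to an interior depth.
2. **A biofilm image-quantification pipeline with a synthetic ground
   truth.** Biofilm segmentation (Otsu → local-maxima watershed →
   25-px-disc erosion filtering → 10%-area rule, with removal
   provenance), Euclidean depth maps from the air-facing surface,
   ratiometric YFP/RFP gradients versus depth (top 2 µm excluded),
   bleed-through estimation and correction, single-cell and spore
   segmentation, a Gaussian-mixture filter for out-of-plane cells,
   depth-band histograms, spore-density profiles (d ± 1 µm windows every
   0.5 µm from 2 to 140 µm), and reporter anticorrelation with a shuffle
   null. A scene generator renders multi-channel cross-sections with
   per-cell ground truth so every estimator is validated by recovery.

The simulator core is compiled (Rcpp); simulation, spore classification
and the master-equation/moment oracles are validated against each other
in the test suite.

## Worked example

Scaled-down gradient sweep (10 ζ points × 1,000 replicates per
condition; the full-scale profile is 20 × 10,000 with the same call):

```r
library(biofilmpulse)

z    <- zeta_grid(10)                       # 5e-5 ... 5e-3, log-even
s025 <- run_sweep(model_params(s_B = 0.25), n_replicates = 1000,
                  seed = 101, zetas = z)
s05  <- run_sweep(model_params(s_B = 0.5),  n_replicates = 1000,
                  seed = 202, zetas = z)

s025$spore_fraction[10]                     # 0.255  at the gradient top
s05$spore_fraction[10]                      # 0.049  under doubled s_B
which.max(s05$spore_fraction)               # 8      interior peak (of 10)
spore_fraction_test(s025, s05)$p.value      # 1.2e-37
```

Doubling the repressor pulse frequency cuts top-of-gradient sporulation
from 25.5% to 4.9% of simulated cells and moves the sporulation peak away
from the top — the model's core prediction. `plot_sweep(s025, s05)` draws
the two curves; `compare_conditions()` adds per-position Wilson/Newcombe
intervals.

On the imaging side:

```r
cfg <- scene_preset("lowmag", seed = 31)    # 590 x 236 um band scene
sc  <- generate_scene(cfg)
rfp <- subtract_background(sc$channels$rfp, cfg$background)
yfp <- subtract_background(sc$channels$yfp, cfg$background)
bm  <- segment_biofilm(rfp)                 # Otsu/watershed/erosion
dm  <- depth_map(bm, cfg$pixel_size_um)     # um from the air interface
ratio_gradient(yfp, rfp, dm, bin_width_um = 2)
#> # A tibble: 74 x 3  (depth, value, n)  -- ratio halves every 20 um,
#> #   matching the configured gradient; top 2 um excluded
```

The numbered scripts under `analysis/` run the full workflow (example
trajectories, the two-condition sweep, scene rendering, and the complete
quantification pass) and write their tables under `results/`.

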