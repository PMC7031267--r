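---
title: "Methods: stochastic sigma-factor pulsing and biofilm image quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic sigma-factor pulsing and biofilm image quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

In *Bacillus subtilis* biofilms, the general stress response sigma factor
σ^B^ and the sporulation programme are both most active near the
air-facing top of the biofilm, even though σ^B^ represses sporulation in
individual cells. The resolution of this apparent paradox is dynamic: σ^B^
is expressed in stochastic pulses, so at any moment only a fraction of
cells sit in the high-σ^B^, sporulation-repressed state, and the two
mutually exclusive cell states can coexist in the same biofilm layer.

`biofilmpulse` implements two tightly coupled pieces of that analysis:

1. a stochastic two-regulator pulsing model, simulated exactly, with a
   spore-decision rule and ensemble sweeps across a stress gradient; and
2. the image-quantification pipeline used on biofilm cross-sections
   (segmentation, depth maps, ratiometric gradients, spore-density
   profiles, single-cell heterogeneity statistics), validated against a
   synthetic scene generator with per-cell ground truth standing in for
   the microscopy data.

# The pulsing model

## Reaction network

Two transcription–translation modules ("A" = sporulation, "B" = σ^B^),
each a standard two-stage bursty expression model, plus one interaction:
the B protein can bind the A gene and block its transcription,

- `G_A -> G_A + R_A` at rate `zeta * s_A`, `R_A -> R_A + A` at `beta`,
  `R_A -> 0` at `delta`, `A -> 0` at `epsilon`;
- the same four reactions for `G_B`, `R_B`, `B` with scale `s_B`;
- `B + G_A <-> BG_A` with binding rate `b_B * B * G_A` and unbinding rate
  `u_B * BG_A`.

The reversible repression reaction is implemented as two irreversible
channels; binding sequesters one B molecule and unbinding releases it.
Gene copy conservation (`G_A + BG_A = 1`, `G_B = 1`) holds at every event
and is asserted in the tests. The model is deliberately phenomenological:
it produces pulses and mutual exclusion, and does not attempt the
RsbQP/RsbV/RsbW biochemistry of the real operon, nor any spatial coupling
between cells — the stress multiplier `zeta` is the only proxy for depth.

## Parameters

| name | default | unit | meaning |
|------|---------|------|---------|
| `beta` | 0.05 | s⁻¹ | translation rate |
| `s_A` | 0.7 | s⁻¹ | transcription scale, sporulation module |
| `s_B` | 0.25 (or 0.5) | s⁻¹ | transcription scale, stress module |
| `zeta` | 5×10⁻⁵ – 5×10⁻³ | – | stress / gradient position (bottom – top) |
| `delta` | 0.005 | s⁻¹ per molecule | mRNA degradation |
| `epsilon` | 0.005 | s⁻¹ per molecule | protein degradation |
| `b_B` | 1.0 | s⁻¹ per molecule | repressor binding to `G_A` |
| `u_B` | 0.1 | s⁻¹ | repressor unbinding |
| `theta` | 1 | molecules | pulse threshold |
| `spore_min_duration` | 1800 | s | minimum excursion to call a spore |
| `transient` | 390 | s | discarded initial time |
| `t_total` | 21,600 | s | total simulated time |

The rates keep both modules in the pulsatile regime across the whole
gradient: neither module dominates outright at high stress. The total run
length is an explicit parameter. Its default, six simulated hours,
comfortably exceeds `transient + spore_min_duration` (the validated
invariant) and lets several pulse cycles develop; results in this package
are reported for that horizon and reproduce under other horizons well
above the invariant bound.

## Simulation and decision rules

Sample paths are drawn with the exact Doob–Gillespie algorithm (direct
method, compiled core) from the initial condition `G_A = G_B = 1`, all
other species absent. Two deliberate edge-case choices:

- **zero total propensity** (possible only for pathological parameter
  sets, since the gene reactions never all vanish under the defaults)
  advances the clock directly to `t_total`;
- **the transient cut** carries the state in force at `t = transient`
  over as the boundary state, and that straddling segment *is*
  time-weighted into stationary averages from the cut onward.

The pulse threshold θ is defined as the 20th percentile of the stationary
law of A with the repressor gene absent, taken from the Gamma
approximation of the two-stage model (shape = burst frequency per protein
lifetime `zeta*s_A/epsilon`, scale = burst size `beta/delta`). At the top
of the gradient this quantile is ≈ 0.92, i.e. 1 after rounding, and the
default pipeline uses the fixed integer θ = 1 throughout; per-`zeta`
recomputation is available (`compute_theta()`, `theta_rounded()`) but
note the tension inherent in the definition: at low `zeta` the Gamma
quantile is far below 1, so a recomputed integer threshold would be 0.
The package defaults to the fixed θ = 1.

"Above threshold" is strict (`A > theta`; for integer counts and θ = 1
this means A ≥ 2), reading "exceeds" literally — with molecule counts
this choice changes results, so it is fixed and documented. A run
produces a spore when the longest *contiguous* excursion above θ lasts
strictly more than 30 simulated minutes (1800 s). "Final B" is the count
in force at `t_total`.

## Ensembles and reproducibility

`run_sweep()` evaluates the gradient `zeta = 10^g`, `g` even on
`[log10 5e-5, log10 5e-3]` (20 points at full scale), with 10,000
replicates per point at full scale. Per-replicate seeds derive from the
root seed by a counter scheme (`(root * 1000003 + counter) mod (2^31-1) + 1`),
so ensembles are reproducible, order-independent within a call, and every
derived seed is a valid 32-bit integer. The desk-scale profile used by the
tests, the analysis scripts and the acceptance checks is 10 grid points ×
1,000 replicates per condition; the full profile is supported unchanged.

## Oracles

The simulator is validated against three independent references, none of
which shares code with the sampling path:

1. **closed-form moments** of the two-stage model (mean mRNA
   `zeta*s/delta`, mean protein `zeta*s*beta/(delta*epsilon)`, protein
   Fano factor `1 + beta/(delta+epsilon)`), checked within three standard
   errors of replicate time averages;
2. the **Gamma approximation**, whose mean must equal the closed-form
   protein mean, with the quantile cross-checked against Monte-Carlo
   sampling;
3. the **truncated chemical master equation**: the stationary law of the
   enumerated `(R, A)` state space is obtained by a direct sparse
   null-space solve (one balance equation replaced by normalisation).
   The truncation is accepted only if boundary mass < 10⁻⁶. On a
   down-scaled instance (`zeta*s = 0.1`, `delta = 0.1`, `beta = 0.1`,
   `epsilon = 0.05`; mean mRNA 1, mean protein 2) the time-weighted SSA
   occupancy over 10⁶ s must match the master-equation law within total
   variation 0.02. The oracle covers the single-gene subsystem; the
   nine-reaction network is validated through its conservation laws,
   degenerate limits and the moment checks instead.

# The synthetic scene generator

`generate_scene()` renders multi-channel biofilm cross-sections with the
air interface at the top edge and full per-object ground truth (centre,
exact Euclidean depth to the configured top boundary, true channel
amplitudes, spore flag). It emulates the statistical structure the
quantification pipeline assumes:

- a biofilm band below a flat or sinusoidally wrinkled top boundary;
- cells as anisotropic Gaussian-profiled ellipses (kernels truncated at
  two long-axis sigmas) with Normal constitutive (RFP) amplitudes and an
  optional dimmer mixture component for out-of-focal-plane cells;
- a long-tailed Gamma law for the stress-reporter (YFP) amplitude whose
  scale halves every `yfp_halflife_um` (default 20 µm) of depth — the
  expression gradient to be recovered;
- spores as small bright discs in a dedicated reporter channel, dim in
  the constitutive channel, placed with probability decaying
  exponentially from the top;
- an optional sporulation (CFP) channel whose mean-normalised per-cell
  values anticorrelate with YFP at a configured least-squares slope;
- an autofluorescent agar strip attached below the band through a dim
  partial-volume seam (the seam stays above the Otsu threshold, so strip
  and biofilm form one connected foreground — the situation the
  watershed/erosion step exists to resolve), an optional isolated blob,
  additive background, RFP→YFP bleed-through added before noise, and
  Gaussian noise with clipping at zero.

Three presets define the study conditions. **lowmag** (0.59 µm/px,
1000 × 400 px ≈ 590 × 236 µm) carries a diffuse biomass base intensity in
the constitutive channel — at this magnification individual cells are
unresolved and the band reads as a continuous textured region, which is
what makes a single global Otsu threshold appropriate; its YFP law uses
Gamma shape 2. **highmag** (0.05 µm/px) has no base signal, sparser
cells with a minimum spacing, and an exponential (shape 1, CV 1) YFP law:
near the surface the single-cell distribution is strongly long-tailed,
and the depth band histograms inherit that tail. **sporedensity**
(0.1 µm/px, 110 µm deep) adds spores. The field of view and density of
each preset were chosen once so that per-bin statistics are well powered
(≈ 100 cells per 2-µm depth bin per lowmag image); they are study
conditions, not tuning knobs.

What the generator does *not* emulate: optical point-spread functions,
3-D sectioning, uneven illumination, spectral overlap beyond a single
linear bleed-through coefficient, cell crowding with strong overlap, or
time dependence. Passing the recovery tests therefore demonstrates that
the pipeline inverts its own generative assumptions faithfully — it does
not certify performance on real confocal data, whose reported single-cell
statistics (CVs, measured bleed-through, the −0.31 anticorrelation slope
on real cells) are outside what a synthetic fixture can reproduce. The
values −0.31 and 0.06 appear here as generator settings so the estimators
can be checked against a known truth.

# The quantification pipeline

**Background and bleed-through.** Mean background is subtracted pixelwise
with clipping at zero. The bleed-through fraction is estimated from
single-reporter controls as mean excess YFP over mean RFP in the
foreground, and removed as `yfp - fraction * rfp`.

**Biofilm segmentation** (`segment_biofilm()`): global Otsu threshold;
breakup of the foreground into sub-segments of similar intensity by a
watershed of the Gaussian-smoothed channel flooded from local maxima,
with maxima of prominence below `watershed_tolerance` (default 0.05 of
the normalised range) merged into their neighbours; erosion of every
sub-segment with a disc of radius 25 px — sub-segments erased entirely
are taken to be thin autofluorescent agar and discarded, all others are
restored to their pre-erosion shape; re-joining; and removal of connected
components below 10% of the image area. Every removal is logged with the
rule that triggered it. Prominence-based merging was chosen over a
minimum seed separation: on a near-homogeneous band, separation-limited
seeds produce Voronoi-like sub-segments whose inradius can fall below the
erosion radius, so the erosion step would delete genuine biofilm
interior; prominence merging keeps the band in a few large basins while a
structure behind a dim seam still founds its own. The smoothing sigma
(half the erosion radius) must stay below the thinnest structure to be
isolated.

**Depth maps** (`depth_map()`): the air region is the background
connected to the top image edge; the surface is the set of foreground
pixels 4-adjacent to it; depth is the Euclidean distance transform to
that surface, exactly zero on it. The Euclidean metric (rather than
per-column vertical distance) is the honest choice under wrinkled tops.
A mask touching all four image edges has no identifiable surface and is
refused.

**Gradients and profiles.** The ratiometric gradient is
`mean(YFP)/mean(RFP)` over foreground pixels per depth bin (default
1 µm; the analyses here use 2 µm), with the top 2 µm discarded in all
depth-resolved outputs — near the air interface cell density falls and
the biofilm start is ambiguous. Per-image profiles are combined as mean ±
SEM across images. The spore-density profile counts spores and cells in
sliding windows d ± 1 µm, d = 2, 2.5, …, 140 µm, reporting either
`spores/(cells+spores)` or spores per foreground pixel; windows without
objects have no ratio and are reported as `NA`.

**Single cells.** Cell segmentation (unspecified in the source
procedure beyond "custom software") uses the standard recipe: Gaussian
smoothing, Otsu threshold (within the biofilm mask when given),
distance-transform watershed to split touching cells, area gates; it is
validated purely by truth-table recovery (one-to-one matching and an
intensity-recovery regression) rather than against any reference masks.
Spores are gated by area (0.25–1 × median cell area) and circularity
(> 0.8). The out-of-plane filter fits a two-component Gaussian mixture to
per-cell constitutive intensity and removes cells below (bright mean −
bright SD), refusing to filter when Ashman's D < 2. Depth-band histograms
normalise per-cell YFP by the band's mean RFP for that image, making them
gain-invariant. The anticorrelation analysis fits an ordinary
least-squares slope of mean-normalised CFP on YFP and compares it with
the slope distribution under random permutations of the CFP column; the
shuffle null distinguishes genuine anticorrelation from mere absence of
correlation.

For sparse high-magnification scenes, `biofilm_mask_from_cells()` derives
the biofilm extent as the smoothed support of the cell signal (heavy
blur, Otsu, hole filling, largest component); its top surface sits within
about a cell spacing of the true boundary, a bias small against the ±1 µm
windows and binomial CIs it feeds.

Manual quality-control exclusions applied to real data (damaged or folded
regions, cells that moved between sequential scans) are represented only
as an optional user-supplied exclusion mask, never automated.

# Numerical choices and degenerate inputs

- Strict inequalities in both decision rules (`A > theta`, duration
  `> 1800 s`), fixed above.
- `zeta_grid()` requires at least two points; parameter validation
  enforces non-negative rates, `zeta > 0` and
  `t_total > transient + spore_min_duration`.
- The CME solve refuses truncations whose boundary mass exceeds 10⁻⁶ and
  tiny negative solver residuals (> −10⁻¹²) are clipped to zero before
  renormalising.
- Constant images yield empty cell-record sets, not errors; empty depth
  bands and empty Otsu foregrounds are errors.
- The bivariate generator does not clip at zero: its values emulate
  background-subtracted, mean-normalised intensities, and clipping would
  bias the configured slope.
- Mixture fits use `mclust`'s default (hierarchical-clustering)
  initialisation; shuffle permutations take an explicit seed.

# Problem sizes

The test suite and acceptance checks run at desk scale, chosen so the
whole suite completes in about a minute of compute: sweeps of 10 × 1,000
replicates per condition, master-equation checks on a ≈ 300-state
truncation with a 10⁶ s occupancy run, four lowmag images for the
gradient, and single scenes for the other imaging checks. The full-scale
profiles (20 × 10,000 sweeps, more and larger images) use the same code
paths with different arguments.

# Known limitations

- The model is qualitative; it fits nothing to data and cannot speak to
  the biochemical mechanism of either pathway or to biofilm growth.
- The imaging validation certifies self-consistency against the
  generator's assumptions, not real-microscope performance (no PSF, no
  3-D, no illumination artefacts).
- `theta` recomputation per stress level is provided but the default is
  the fixed value 1, with the low-`zeta` inconsistency documented above.
- The spore-density profile inherits the depth bias of whichever mask
  provides its depth reference (≈ 1 µm for `biofilm_mask_from_cells()`).
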