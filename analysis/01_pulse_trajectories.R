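#!/usr/bin/env Rscript
# Example sample paths of the two-regulator pulsing model at the top of
# the stress gradient: both regulators pulse, and excursions of the
# sporulation species A above the threshold theta = 1 are what the spore
# rule scores. Writes one trajectory per condition plus its spore outcome.

library(biofilmpulse)

out <- "results/trajectories"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (s_B in c(0.25, 0.5)) {
  p <- model_params(zeta = 5e-3, s_B = s_B)
  traj <- simulate_pulses(p, seed = 1000 + round(100 * s_B))
  f <- file.path(out, sprintf("trajectory_top_sB%.2f.csv", s_B))
  write_trajectory(traj, f)
  outc <- spore_outcome(traj)
  cat(sprintf(
    "s_B = %.2f: %d events; longest A-excursion %.0f s; final B %d; spore: %s\n",
    s_B, length(traj$times) - 1L, outc$longest_excursion, outc$final_B,
    outc$is_spore
  ))
  cat("  wrote", f, "\n")
}
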