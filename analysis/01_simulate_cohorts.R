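#!/usr/bin/env Rscript
# Generate the synthetic study cohorts used by the downstream analyses:
# a chemotactically responding ("responder") neutrophil cohort with
# wound-directed bias and arrest, and a non-responding ("nonresponder")
# cohort of unbiased persistent random walkers at the same intrinsic
# speed. 50 cells each, 2 h at 1 min frame interval, emulating tail-fin
# wound time lapses starting at 1 hpw.

library(woundtrack)

dir.create("results/tracks", showWarnings = FALSE, recursive = TRUE)

v_true <- 6    # um/min, typical interstitial neutrophil speed
tau_true <- 10 # min persistence

responder <- simulate_cohort(simulation_config(
  n_cells = 50, duration = 120, dt = 1, v_true = v_true,
  tau_true = tau_true, bias = 0.5, arrest_radius = 20, seed = 2001,
  group = "responder"))
nonresponder <- simulate_cohort(simulation_config(
  n_cells = 50, duration = 120, dt = 1, v_true = v_true,
  tau_true = tau_true, bias = 0, seed = 2002, group = "nonresponder"))

write_tracks(responder, "results/tracks/responder.csv")
write_tracks(nonresponder, "results/tracks/nonresponder.csv")

cat("Simulated two 50-cell cohorts (2 h at 1 min/frame):\n")
for (nm in c("responder", "nonresponder")) {
  co <- get(nm)
  wf <- default_wound()
  arr <- mean(vapply(co$tracks, function(tr)
    arrival_status(tr, wf)$arrived, logical(1)))
  cat(sprintf("  %-13s arrival fraction within 20 um of the wound: %.2f\n",
              nm, arr))
}
cat("Track tables written under results/tracks/ (generic_csv dialect).\n")
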