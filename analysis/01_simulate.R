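#!/usr/bin/env Rscript
# Stage 1 — synthesize the study sessions.
#
# Derives the three stimulus intensities from the subject's printed sensory
# and motor thresholds, then generates one full synthetic session (12 runs:
# 2 repetitions x 3 intensities x 2 wrists, 700 ms epochs at 1250 Hz) for
# the blind-like three-stage network and one for the sighted-like control
# network (no couplings into visual areas). All later stages regenerate
# the same sessions deterministically from the seed, so only summary
# tables are written here.

suppressPackageStartupMessages(library(mipath))
dir.create("results", showWarnings = FALSE)
seed <- 42

levels <- rbind(
  data.frame(side = "left", t(derive_intensities(stimulus_thresholds(2.2, 5.3, "left")))),
  data.frame(side = "right", t(derive_intensities(stimulus_thresholds(1.8, 3.8, "right")))))
write.csv(levels, "results/stimulus_intensities.csv", row.names = FALSE)
cat("stimulus intensities (mA):\n"); print(levels)

design <- session_design(trials_per_run = 60L)
for (nm in c("blind_like", "sighted_like")) {
  net <- if (nm == "blind_like") blind_like_network() else sighted_like_network()
  session <- generate_session(design, net, seed = seed)
  runs <- do.call(rbind, lapply(session$runs, function(r)
    data.frame(condition = r$condition, side = r$side, rep = r$rep,
               n_trials = r$n_trials, run_seed = r$seed)))
  write.csv(runs, sprintf("results/session_runs_%s.csv", nm), row.names = FALSE)
  cat(sprintf("\n%s session: %d runs, %d ROIs, %d couplings planted\n",
              nm, length(session$runs), length(net$nodes), nrow(net$couplings)))
}
write.csv(blind_like_network()$couplings, "results/planted_couplings.csv",
          row.names = FALSE)
cat("\nplanted couplings written to results/planted_couplings.csv\n")
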