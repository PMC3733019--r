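#!/usr/bin/env Rscript
# Stage 3 — combinatorial statistical activation maps.
#
# Grid-level check of the contrast machinery on a 17^3 representation
# grid: (a) with no planted effect, the intersection of the four
# combinatorial Motor-vs-Supra t maps at the corrected threshold
# P < 1e-4 should mark nothing; (b) a planted focal Motor > Supra
# amplitude increase should come back as one contiguous active cluster
# at the planted position. The merged Motor-vs-(Supra+Sub) contrast set
# is also built to show the 4- and 8-map combinatorics.

suppressPackageStartupMessages(library(mipath))
dir.create("results", showWarnings = FALSE)
seed <- 42
grid <- source_grid(c(17, 17, 17), spacing = 8)
des <- session_design(epoch_window = c(0, 6.4), trials_per_run = 30L,
                      repetitions = 1L)
axis <- design_times(des)

# (a) null: four runs of pure noise
null_runs <- generate_cdv_dataset(des, list(), seed = seed, grid = grid,
                                  run_scales = c(M1 = 1, M2 = 1, S1 = 1, S2 = 1),
                                  n_trials = 30L, noise_sd = 1)
nm <- lapply(null_runs, cdv_moduli)
null_maps <- combinatorial_contrasts(nm[1:2], nm[3:4], axis = axis)
null_act <- intersect_activation(null_maps, alpha = 1e-4)
cat(sprintf("null data: %d combinatorial maps, %d active cells after intersection\n",
            length(null_maps), sum(null_act$active)))

# (b) planted focus at (64, 64, 64) mm, Motor twice the Supra/Sub amplitude
src <- list(position = c(64, 64, 64), direction = c(0, 0, 1),
            amplitude = 5, window_ms = c(1, 6))
runs <- generate_cdv_dataset(des, list(src), seed = seed + 1, grid = grid,
                             run_scales = c(Motor1 = 1, Motor2 = 1,
                                            Supra1 = 0.5, Supra2 = 0.5,
                                            Sub1 = 0.25, Sub2 = 0.25),
                             n_trials = 30L, noise_sd = 1)
mods <- lapply(runs, cdv_moduli)
maps4 <- combinatorial_contrasts(mods[1:2], mods[3:4], axis = axis)
maps8 <- combinatorial_contrasts(mods[1:2], mods[3:4], axis = axis,
                                 merge = mods[5:6])
cat(sprintf("Motor vs Supra: %d maps; Motor vs merged Supra/Sub: %d maps\n",
            length(maps4), length(maps8)))

act <- intersect_activation(maps4, alpha = 1e-4)
cl <- activation_clusters(act, grid)
write.csv(cl, "results/activation_clusters.csv", row.names = FALSE)
cat("planted focus recovery:\n"); print(cl)
cat("cluster table written to results/activation_clusters.csv\n")
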