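#!/usr/bin/env Rscript
# Stage 2 — regional SNR and ROI selection.
#
# Computes the moving-window SNR (6.4 ms window, 0.8 ms step) of every
# region's single-trial RAC ensemble in the first Motor run (left wrist)
# and applies the selection rule: keep ROIs whose SNR exceeds 0.2 at any
# window center in the first 100 ms. In the sighted-like control the
# visual areas carry only background noise, so the same rule drops them.

suppressPackageStartupMessages(library(mipath))
dir.create("results", showWarnings = FALSE)
seed <- 42
design <- session_design(trials_per_run = 60L)

tabs <- list()
for (nm in c("blind_like", "sighted_like")) {
  net <- if (nm == "blind_like") blind_like_network() else sighted_like_network()
  session <- generate_session(design, net, seed = seed)
  run1 <- session_runs(session, "Motor", "left")[[1]]
  snrs <- lapply(run1$racs, compute_snr)
  sel <- select_rois(snrs, threshold = 0.2, window = c(0, 100))
  tabs[[nm]] <- data.frame(
    network = nm, roi = names(snrs),
    max_snr_0_100 = vapply(snrs, function(s)
      max(s$snr[s$centers >= 0 & s$centers <= 100]), numeric(1)),
    selected = names(snrs) %in% sel)
  cat(sprintf("%s: selected %d/%d ROIs: %s\n", nm, length(sel),
              length(snrs), paste(sel, collapse = ", ")))
}
write.csv(do.call(rbind, tabs), "results/roi_snr.csv", row.names = FALSE)
cat("SNR table written to results/roi_snr.csv\n")
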