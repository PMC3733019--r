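# mipath

Tracing fast cortical pathways in source-space MEG with time-delayed
Rényi mutual information.

After a brief electrical pulse to the median nerve, activity sweeps from
the thalamus through primary and secondary somatosensory cortex within a
few tens of milliseconds — and, in congenitally blind subjects, onward
through posterior parietal areas BA7/BA40 into visual cortex. `mipath`
implements the analysis chain that traces such pathways from
single-trial source reconstructions: regional activation curves,
combinatorial statistical activation maps, Morlet scalograms, and —
its core — time-delayed mutual-information connectivity with
influence-diagram extraction. It is written for MEG/EEG methodologists
who want the full chain runnable, testable and auditable on synthetic
sessions with known planted ground truth.

## The core statistic

For two regional activation curves (RACs) $X$ and $Y$, the time-delayed
mutual information between the 24 ms window of $X$ centered at latency
$t$ and the window of $Y$ centered at $t + \tau$ is computed from
order-4 Rényi entropies over 10 uniform amplitude bins:

$$H_\alpha(X) = \frac{1}{1-\alpha} \ln \sum_i p_x^\alpha(i), \qquad
  I_\alpha(X, Y; \tau) = H_\alpha(X) + H_\alpha(Y) - H_\alpha(X, Y; \tau)$$

Positive $\tau$ means $X$ leads $Y$. Scanning $t \in [-200, 500]$ ms and
$\tau \in [-100, 200]$ ms gives a map $M(t, \tau)$ per ordered region
pair; max-normalized, threshold-gated ($c = 0.4$) and restricted to
conduction delays $5 \le |\tau| \le 20$ ms, its super-threshold
components become directed, latency-stamped links in an influence
diagram.

Around that core sit the supporting stages: quintic-spline
interpolation of current-density maps (8 mm grid to a 1 mm lattice) with
maxima localization; fully combinatorial Student-t contrasts between
trial-pooled CDV moduli intersected across all maps of a set at
corrected $P < 10^{-4}$; ROI selection by moving-window SNR (> 0.2
within 0–100 ms); and a synthetic-session generator that plants known
lagged couplings among 8 regions so every stage is testable without any
recording.

## Worked example

Derive intensities from the printed thresholds, synthesize a session
with the blind-like three-stage network, and recover a planted coupling:

```r
library(mipath)

derive_intensities(stimulus_thresholds(2.2, 5.3, "left"))
#>   Sub Supra Motor
#> 1.425 2.975 6.075

net <- blind_like_network()          # Thal -> S1/S2 -> BA40/BA7 -> V3 -> V5 -> V1
session <- generate_session(session_design(trials_per_run = 60L), net, seed = 42)
session
#> <synthetic_session> 12 runs, 8 ROIs, seed 42

run1 <- session_runs(session, "Motor", "left")[[1]]
m <- normalize_map(mi_map(run1$racs$BA7, run1$racs$V3,
                          t_range = c(-60, 110), tau_range = c(-30, 30),
                          t_step = 1.6, tau_step = 1.6))
extract_links(m, mi_threshold = 0.4)[1, c("source", "target", "delay_ms",
                                          "source_onset_ms", "strength")]
#>   source target delay_ms source_onset_ms strength
#> 1    BA7     V3      9.6            23.2        1
```

The planted BA7 → V3 lag is 10 ms; the extracted dominant delay of
9.6 ms is one lattice step away, with the source onset at 23.2 ms —
parietal activity feeding V3 around 33–66 ms, as the staged network
prescribes. Running the same pipeline on `sighted_like_network()` (no
couplings into visual areas) selects only the 5 somatosensory/parietal
ROIs and extracts **zero** links into V1/V3/V5.

The numbered drivers under `analysis/` run the whole study in order —
`01_simulate.R` … `06_influence_diagram.R` — writing tables (ROI SNR,
activation clusters, planted-vs-extracted delays, influence diagrams as
JSON) under `results/`. For example `05_mi_network.R` prints:

```
 source target planted_lag_ms extracted_delay_ms source_onset_ms strength
   Thal     S1              8                9.6             5.6     0.95
   Thal     S2             10                9.6             5.6     1.00
     S2    BA7              7                6.4            16.8     1.00
     S1   BA40             10                9.6            15.2     1.00
    BA7     V3             10                9.6            23.2     1.00
     V3     V5              6                6.4            34.4     1.00
     V5     V1              6                6.4            42.4     1.00
```

See `vignettes/pathway-tracing.Rmd` for the model, the estimator's
identifiability conditions, and every numerical convention.

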