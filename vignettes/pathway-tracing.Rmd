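---
title: "Tracing fast cortical pathways with time-delayed Renyi mutual information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing fast cortical pathways with time-delayed Renyi mutual information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipath)
```

## The analysis and its assumptions

`mipath` implements a source-space MEG analysis chain for tracing fast
inter-regional information transfer after median-nerve stimulation. The
chain assumes its *input* is already a tomographic source reconstruction:
per-trial current-density vectors (CDV) on a coarse 17 × 17 × 17
representation grid (8 mm spacing), or regional activation curves (RACs)
derived from them. Producing that reconstruction — forward modelling and
the nonlinear distributed inverse — is out of scope; the package starts
where the source estimates end.

The stages are:

1. **Stimulus arithmetic.** From the sensory threshold STH and motor
   threshold MTH (mA), three intensities are derived with
   $\Delta = \mathrm{MTH} - \mathrm{STH}$: Sub $= \mathrm{STH} - 0.25\Delta$,
   Supra $= \mathrm{STH} + 0.25\Delta$, Motor $= \mathrm{MTH} + 0.25\Delta$.
2. **Mapping.** CDV fields are interpolated from the coarse grid to a 1 mm
   lattice with tensor-product quintic splines; activity maxima are read
   off the fine lattice. A spatio-frequency representation is obtained by
   zero-padded FFT at 0.2 Hz bin spacing.
3. **Statistical parametric mapping.** Trial-pooled CDV moduli of two
   runs are contrasted pointwise with Student's t at every (grid point,
   latency or frequency). Contrasts are *fully combinatorial* across run
   repetitions (2 × 2 gives four maps; merging two baseline conditions
   first gives 2 × 4 = eight), and a point counts as active only when
   significant in *every* map of the set at the corrected threshold
   (default $P < 10^{-4}$).
4. **ROIs and RACs.** Spherical ROIs (8 mm radius) carry a principal
   direction — the magnitude-weighted resultant of the in-sphere CDVs —
   and a RAC: the per-timeslice sum of in-sphere projections on that
   direction. ROIs are kept when their moving-window SNR (6.4 ms window,
   0.8 ms step) exceeds 0.2 anywhere in 0–100 ms post-stimulus.
5. **Time-frequency.** 6-cycle complex Morlet scalograms of single-trial
   RACs, trial-averaged power.
6. **Connectivity.** Time-delayed mutual information between 24 ms
   windows of two trial-averaged RACs, with Rényi entropy of order
   $\alpha = 4$ over $n = 10$ uniform amplitude bins:
   $$I_\alpha(X,Y;\tau) = \frac{1}{1-\alpha}\,
     \ln\frac{\sum_i p_x^\alpha(i)\,\sum_j p_y^\alpha(j)}
             {\sum_{i,j} p_{x,y}^\alpha(i,j;\tau)}.$$
   $M(t,\tau)$ maps are max-normalized; multi-subject maps are averaged
   with a threshold gate (zero wherever any subject falls below
   $c = 0.4$). Links are extracted from super-threshold components inside
   the conduction band $5 \le |\tau| \le 20$ ms and $-50 \le t \le 100$
   ms, and assembled into an influence diagram.

MI linkage is *not* causal inference: a super-threshold region says two
windows are statistically dependent at that delay, which can equally
arise from common drive via a third region. The delay-band restriction
removes zero-lag common drive but not lagged indirect routes; diagrams
from densely coupled systems therefore contain indirect links by design.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| grid shape / spacing | 17³ / 8 | – / mm | representation grid |
| fine spacing | 1 | mm | interpolation target |
| sampling rate | 1250 | Hz | 0.8 ms timeslices |
| epoch | −200…500 | ms | trial window |
| corrected alpha | 1e−4 | – | activation threshold |
| ROI radius | 8 | mm | spherical ROIs |
| SNR threshold / window | 0.2 / 0–100 | – / ms | ROI selection |
| Morlet width | 6 | cycles | σ_t = 6/(2πf) |
| MI window | 24 | ms | 30 samples |
| Rényi order α | 4 | – | entropy order |
| amplitude bins n | 10 | – | histogram estimator |
| τ band | 5–20 | ms | conduction delays |
| link range | −50…100 | ms | analysed latencies |
| link threshold c | 0.4 | – | normalized MI gate |

The lattice steps of the $M(t,\tau)$ plane default to the 0.8 ms sample
period and are configurable coarser; the analyses in `analysis/` and the
recovery tests use 1.6 ms, which quarters the cell count at no cost to
delay resolution beyond one step.

## What the synthetic generator emulates — and what it does not

`generate_session()` emulates the study design: 12 runs (2 repetitions ×
3 intensities × 2 wrists), 80–120 trials per run, 700 ms epochs at
1250 Hz, intensity-scaled evoked components, gamma bursts, `1/f` + white
background noise, and directed couplings that deliver a source region's
waveform to a target delayed by a conduction lag (5–20 ms) and scaled by
a gain. Per-trial latency jitter (uniform ±3 ms) and per-trial random
burst phases make the gamma content time-unlocked, as reported for the
real data.

Four generator design choices matter for whether planted lags are
*identifiable* by windowed, binned MI, and were settled during
development by analysis of the estimator (not by tweaking until numbers
matched):

* **Binned MI is invariant under monotone amplitude maps.** Any
  injective relation between two 30-sample windows reaches the same MI
  as a perfect linear one. A narrowband carrier is therefore ambiguous
  with its *anti-phase* copy at half its period: 45–70 Hz bursts have
  half-periods of 7–11 ms, inside the 5–20 ms conduction band. The
  generator consequently keeps phase-locked narrowband content below
  ~25 Hz (half-period > 20 ms, outside the band) and makes the gamma
  bursts non-phase-locked, so they are visible in scalograms but cancel
  from the averaged RACs the MI stage consumes.
* **Broadband phase-locked texture.** Smooth waveforms produce long
  near-ceiling MI plateaus over τ (any short monotone segment maps
  injectively onto any other). Each driver region therefore carries a
  deterministic band-limited "texture" (random-phase atoms under one
  envelope) whose fast structure collapses misaligned windows into
  many-to-one bin mappings, sharpening the ridge at the true lag.
* **Relay dominance.** A lag is only recoverable when the transferred
  component dominates the target window (link SNR ≥ 1); downstream nodes
  therefore have weak or no intrinsic content. This matches the regime
  the recovery claims presuppose.
* **Coupling windows cover the source's activity.** Truncating a source
  mid-activity leaves near-cut content without a counterpart in the
  target and systematically degrades the aligned ridge; windows trim
  only tails.

What the generator does **not** emulate: volume conduction and source
leakage between ROIs, nonstationary noise, artifacts, subject-specific
anatomy, nonlinear coupling (the transfer is linear delayed addition),
and real inverse-solution errors. Passing the recovery tests therefore
shows the *estimator chain* is correct and calibrated under the stated
conditions — not that real MEG data meet those conditions.

## Numerical choices

* **0.2 Hz spectra from 700 ms epochs** require zero-padding to 5 s
  (6250 samples); series are demeaned first, no taper (plain rectangular
  window). Padding a constant record leaks (boxcar spectrum), which is
  why the DC check in the tests uses resolution matched to the record.
* **Quintic interpolation** is tensor-product degree-5 B-spline
  interpolation (clamped knots, interior knots at the middle data
  sites), exact at grid nodes and for polynomials up to degree 5, C⁴
  inside the grid. Interpolation is per Cartesian component; the scalar
  activity used for maxima is the Euclidean modulus of the interpolated
  vector. Maxima ties break to the first occurrence in column-major
  order and are flagged; near-constant fields are flagged degenerate.
* **Pooled-variance two-sided t** by default (Welch via
  `var_equal = FALSE`); cells with zero variance on both sides are
  degenerate (`t = NA`, `p = 1`, flagged). The stated $P < 10^{-4}$ is
  applied as the already-corrected pointwise threshold; a Bonferroni
  family divisor is available via `family_size`.
* **SNR estimator**: evoked power (trial-averaged RAC) over mean
  residual power per window. The original work cites an external
  estimator whose exact form is not reproduced; this ratio is the
  documented stand-in, and the 0.2 threshold is applied on the ratio
  scale.
* **MI conventions**: bins span each series' full-epoch range (fixed
  across windows; per-window binning via `binning = "window"`); empty
  bins contribute zero terms, so no `log(0)` arises; negative
  finite-sample estimates are floored at zero and counted; a window
  "centered" at *t* with 30 samples spans `t − 12 … t + 11.2` ms
  (left-heavy by one sample); the τ lattice is anchored at zero delay.
* **Link extraction**: components are 4-connected super-threshold
  regions (`value ≥ c`, matching the strict "less than c" zeroing rule
  of the subject average). The link delay is the component's *dominant*
  delay — the τ row with the largest summed MI mass — rather than the τ
  of the single peak cell, because near-ceiling plateaus make the peak
  cell fragile while a genuine coupling forms a ridge at its lag across
  the whole activation. Strength is the component maximum; the source
  onset is the earliest latency of the leading region's windows.

## Decisions on genuinely open points

* The normalization preceding cross-subject averaging is taken as
  division by the map's maximum over its valid region (idempotent,
  range [0, 1]).
* Spectra are computed per component with the modulus taken afterwards;
  the frequency-domain trial statistic is the vector norm of the
  per-component amplitude moduli.
* Whether Motor runs hold 80 or 120 trials is a per-design field
  (`motor_trials`); no rule decides it.
* Scalograms show the trial-mean of single-trial power (not the power
  of the trial mean), which is what preserves non-phase-locked bursts.
* The principal-direction fitting window defaults to 15–50 ms, the
  latency range of the dominant early response.

## Problem sizes in the shipped analyses and tests

The bundled analyses and the test suite run sessions of 24–120 trials
per run, $M(t,\tau)$ lattices at 1.6 ms steps over $t \in [-60, 110]$,
$\tau \in [-30, 30]$ ms, and 17³ grids with short (8-timeslice) epochs
for the grid-level contrast checks; the planted-pathway recovery check
uses 50 independently seeded sessions of the single Motor run it needs.
These sizes keep each stage in the seconds-to-minutes range on one core
while leaving every algorithmic path identical to a full-size run.

## Known limitations

* Influence diagrams from a *single* synthetic subject at `c = 0.4`
  contain indirect and reverse links (the normalization guarantees every
  pair's map has a unit maximum somewhere); the two-subject threshold
  gate or a higher threshold (the study used `c > 0.9` for single-subject
  maps) prunes them. The planted-coupling delays are nonetheless
  recovered as the dominant links.
* The histogram MI estimator at 30 samples × 100 joint bins is biased
  upward under independence; `mi_permutation_null()` quantifies that
  bias but no bias correction is applied, matching the original
  procedure.
* RAC extraction integrates over whole grid cells inside the sphere; no
  partial-volume weighting at the sphere boundary.
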