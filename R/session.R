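#' Session design for a median-nerve stimulation experiment
#'
#' Describes the run/trial layout of one MEG session: three constant-current
#' intensities (Sub, Supra, Motor) delivered to each wrist, each condition
#' repeated, trials epoched from -200 to 500 ms around stimulus onset at a
#' 1250 Hz sampling rate (0.8 ms timeslices). The defaults reproduce the
#' standard design: 2 repetitions x 3 intensities x 2 wrists = 12 runs of
#' 120 trials (Motor runs may hold 80).
#'
#' @param sampling_rate sampling rate in Hz.
#' @param epoch_window `c(start, end)` of the trial epoch in ms relative to
#'   stimulus onset; the epoch spans `[start, end)` so that
#'   `(end - start) * sampling_rate / 1000` samples tile it exactly.
#' @param isi mean and jitter of the inter-stimulus interval in ms
#'   (metadata; epochs are generated independently).
#' @param intensities ordered character vector of intensity conditions.
#' @param sides wrists stimulated.
#' @param repetitions runs per (intensity, side) condition.
#' @param trials_per_run trials in each Sub/Supra run.
#' @param motor_trials trials in each Motor run (80 or 120 in the original
#'   design; the choice is a per-design field because no rule fixes it).
#' @return An object of class `session_design`.
#' @export
session_design <- function(sampling_rate = 1250,
                           epoch_window = c(-200, 500),
                           isi = c(mean = 600, jitter = 100),
                           intensities = c("Sub", "Supra", "Motor"),
                           sides = c("left", "right"),
                           repetitions = 2L,
                           trials_per_run = 120L,
                           motor_trials = trials_per_run) {
  stopifnot(length(epoch_window) == 2L, epoch_window[1] < epoch_window[2])
  n_samp <- (epoch_window[2] - epoch_window[1]) * sampling_rate / 1000
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("epoch length times sampling rate must give an integer sample count")
  if (repetitions < 1L) stop("'repetitions' must be at least 1")
  structure(list(
    sampling_rate = sampling_rate,
    epoch_window = as.numeric(epoch_window),
    isi = isi,
    intensities = intensities,
    sides = sides,
    repetitions = as.integer(repetitions),
    trials_per_run = as.integer(trials_per_run),
    motor_trials = as.integer(motor_trials),
    n_samples = as.integer(round(n_samp))
  ), class = "session_design")
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design> %d runs (%d intensities x %d sides x %d reps), %d samples/trial @ %g Hz\n",
              length(x$intensities) * length(x$sides) * x$repetitions,
              length(x$intensities), length(x$sides), x$repetitions,
              x$n_samples, x$sampling_rate))
  invisible(x)
}

#' Epoch time axis of a session design
#'
#' @param design a [session_design()].
#' @return numeric vector of sample latencies in ms, `[start, end)`.
#' @export
design_times <- function(design) {
  design$epoch_window[1] + (seq_len(design$n_samples) - 1) * 1000 / design$sampling_rate
}

#' Ground-truth regional network for synthetic sessions
#'
#' Encodes what the generator plants: the set of regional nodes, their
#' intrinsic waveforms, the directed lagged couplings between them, and the
#' per-intensity amplitude gains. Couplings transfer the source node's
#' clean (noise-free) waveform to the target, delayed by `lag_ms`, scaled by
#' `gain`, and restricted to an optional source-latency `window`.
#'
#' @param nodes character vector of ROI labels.
#' @param couplings data frame with columns `source`, `target`, `lag_ms`
#'   (>= 0), `gain` (>= 0) and optional `window_on`/`window_off` (ms, NA for
#'   the whole epoch). Both endpoints must be declared nodes and the coupling
#'   graph must be acyclic.
#' @param intensity_gains named numeric vector of evoked-amplitude
#'   multipliers per intensity condition.
#' @param node_signals optional named list giving each node's intrinsic
#'   waveform as a data frame of Gabor atoms with columns `center_ms`,
#'   `sd_ms`, `freq_hz`, `amp`, `phase`. Nodes without an entry are driven
#'   only through couplings (plus background noise).
#' @return An object of class `gt_network`.
#' @seealso [blind_like_network()], [sighted_like_network()]
#' @export
gt_network <- function(nodes, couplings = NULL,
                       intensity_gains = c(Sub = 0.2, Supra = 0.55, Motor = 1),
                       node_signals = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node labels")
  if (is.null(couplings)) {
    couplings <- data.frame(source = character(), target = character(),
                            lag_ms = numeric(), gain = numeric(),
                            window_on = numeric(), window_off = numeric())
  }
  couplings <- as.data.frame(couplings)
  needed <- c("source", "target", "lag_ms", "gain")
  if (!all(needed %in% names(couplings)))
    stop("'couplings' needs columns source, target, lag_ms, gain")
  if (is.null(couplings$window_on)) couplings$window_on <- NA_real_
  if (is.null(couplings$window_off)) couplings$window_off <- NA_real_
  bad <- setdiff(unique(c(couplings$source, couplings$target)), nodes)
  if (length(bad)) stop("coupling endpoints not declared as nodes: ",
                        paste(bad, collapse = ", "))
  if (any(couplings$lag_ms < 0)) stop("coupling lags must be >= 0")
  if (any(couplings$gain < 0)) stop("coupling gains must be >= 0")
  if (any(intensity_gains < 0)) stop("intensity gains must be >= 0")
  if (!is.null(node_signals)) {
    bad <- setdiff(names(node_signals), nodes)
    if (length(bad)) stop("node_signals for undeclared nodes: ",
                          paste(bad, collapse = ", "))
  }
  net <- structure(list(nodes = nodes, couplings = couplings,
                        intensity_gains = intensity_gains,
                        node_signals = node_signals),
                   class = "gt_network")
  topo_order(net)   # errors on cycles
  net
}

#' @export
print.gt_network <- function(x, ...) {
  cat(sprintf("<gt_network> %d nodes, %d couplings\n",
              length(x$nodes), nrow(x$couplings)))
  invisible(x)
}

# Kahn topological sort of the coupling DAG.
topo_order <- function(network) {
  nodes <- network$nodes
  cp <- network$couplings
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (tg in cp$target) indeg[tg] <- indeg[tg] + 1L
  order <- character(0)
  ready <- names(indeg)[indeg == 0L]
  remaining <- cp
  while (length(ready)) {
    nd <- ready[1]; ready <- ready[-1]
    order <- c(order, nd)
    out <- remaining$source == nd
    for (tg in remaining$target[out]) {
      indeg[tg] <- indeg[tg] - 1L
      if (indeg[tg] == 0L) ready <- c(ready, tg)
    }
    remaining <- remaining[!out, , drop = FALSE]
  }
  if (length(order) != length(nodes))
    stop("coupling graph contains a cycle")
  order
}

# locked = FALSE marks bursts that are not phase-locked to the stimulus:
# they get a fresh uniform phase on every trial, so they survive in
# single-trial time-frequency power but cancel from trial-averaged RACs.
gabor_atoms <- function(center_ms, sd_ms, freq_hz, amp, phase = 0, locked = TRUE) {
  data.frame(center_ms = center_ms, sd_ms = sd_ms, freq_hz = freq_hz,
             amp = amp, phase = phase, locked = locked)
}

# Deterministic band-limited "texture": n random-frequency, random-phase
# atoms sharing one Gaussian envelope. Gives a node's waveform broadband,
# phase-locked structure so that lagged copies are identifiable (smooth
# narrowband waveforms are ambiguous under bin-invariant MI). A fixed
# seed makes the atoms a pure function of the arguments; the caller's
# RNG state is untouched.
texture_atoms <- function(center_ms, sd_ms, amp, n = 20, band = c(15, 95),
                          seed = 101) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  gabor_atoms(center_ms, sd_ms, stats::runif(n, band[1], band[2]),
              amp / sqrt(n), stats::runif(n, 0, 2 * pi))
}

#' Three-stage somatosensory-to-visual ground-truth network
#'
#' A plantable network reproducing, in synthetic form, the staged pathway
#' reported for the congenitally blind subject: thalamic drive reaches the
#' somatosensory cortices (S1, S2) at 15-35 ms, converges onto posterior
#' parietal areas BA40 and BA7 at 40-55 ms, and progresses to visual areas
#' V3, then V5, then V1 at 50-65 ms. All couplings carry lags in the 5-20 ms
#' conduction band so the mutual-information stage can recover them.
#'
#' The driver regions (Thal, S1, S2) carry intrinsic waveforms — an evoked
#' low-frequency component, gamma bursts (45-70 Hz at 20-50 ms, not
#' phase-locked across trials, so they appear in single-trial scalograms
#' but average out of the RACs the MI stage consumes) and a phase-locked
#' broadband texture. Downstream regions are relay-dominant: their
#' in-coupling delivers more power than any intrinsic content, the regime
#' in which a lagged linkage is identifiable from 24 ms windows. See the
#' package vignette for why each of these choices matters for lag
#' identifiability.
#'
#' @return A [gt_network()].
#' @export
blind_like_network <- function() {
  nodes <- c("Thal", "S1", "S2", "BA40", "BA7", "V3", "V5", "V1")
  # phase-locked narrowband content is kept below ~25 Hz: under
  # bin-invariant MI a carrier is ambiguous with its anti-phase copy at
  # half its period, and only carriers below ~25 Hz push that alias out of
  # the 5-20 ms conduction band
  sig <- list(
    Thal = rbind(gabor_atoms(16, 9, 18, 1.4),
                 gabor_atoms(16, 5, 62, 0.7, locked = FALSE),
                 gabor_atoms(19, 6, 47, 0.5, locked = FALSE),
                 texture_atoms(20, 9, 1.8, seed = 103)),
    S1   = rbind(gabor_atoms(21, 6, 22, 1.0),
                 gabor_atoms(30, 7, 55, 1.0, locked = FALSE),
                 gabor_atoms(35, 7, 68, 0.6, locked = FALSE),
                 texture_atoms(33, 10, 1.0, seed = 107)),
    S2   = rbind(gabor_atoms(24, 6, 19, 0.8),
                 gabor_atoms(32, 7, 48, 0.8, locked = FALSE),
                 gabor_atoms(35, 7, 59, 0.5, locked = FALSE),
                 texture_atoms(35, 10, 0.9, seed = 109))
  )
  # coupling windows cover the source region's active period (trimming
  # only tails): a window that truncates the source mid-activity leaves
  # near-cut content without a counterpart in the target, which degrades
  # the aligned MI ridge relative to chance alignments elsewhere
  cp <- rbind(
    data.frame(source = "Thal", target = "S1",   lag_ms = 8,  gain = 1.0, window_on = 4,  window_off = 44),
    data.frame(source = "Thal", target = "S2",   lag_ms = 10, gain = 0.9, window_on = 4,  window_off = 44),
    data.frame(source = "S2",   target = "BA7",  lag_ms = 7,  gain = 0.9, window_on = 8,  window_off = 62),
    data.frame(source = "S1",   target = "BA40", lag_ms = 10, gain = 0.9, window_on = 8,  window_off = 62),
    data.frame(source = "BA7",  target = "V3",   lag_ms = 10, gain = 0.9, window_on = 14, window_off = 72),
    data.frame(source = "V3",   target = "V5",   lag_ms = 6,  gain = 0.9, window_on = 22, window_off = 82),
    data.frame(source = "V5",   target = "V1",   lag_ms = 6,  gain = 0.9, window_on = 26, window_off = 90)
  )
  gt_network(nodes, cp, node_signals = sig)
}

#' Sighted-like ground-truth network (no parieto-occipital couplings)
#'
#' Same nodes and thalamo-cortical / cortico-parietal couplings as
#' [blind_like_network()], but with every coupling into the visual areas
#' removed: V1, V3 and V5 carry background noise only, so no
#' somatosensory-to-visual chain exists to be found.
#'
#' @return A [gt_network()].
#' @export
sighted_like_network <- function() {
  full <- blind_like_network()
  visual <- c("V1", "V3", "V5")
  cp <- full$couplings[!(full$couplings$target %in% visual), , drop = FALSE]
  gt_network(full$nodes, cp, intensity_gains = full$intensity_gains,
             node_signals = full$node_signals)
}

# Shift a vector by k samples (k >= 0 delays, zero-filled at the left edge).
shift_samples <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  if (k >= n) return(numeric(n))
  c(numeric(k), x[seq_len(n - k)])
}

# Evaluate a Gabor-atom table on a time axis (ms). Atoms with
# locked = FALSE receive a fresh random phase (per call = per trial).
eval_atoms <- function(atoms, times, randomize_unlocked = FALSE) {
  out <- numeric(length(times))
  if (is.null(atoms) || nrow(atoms) == 0L) return(out)
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    phase <- a$phase
    if (randomize_unlocked && !is.null(a$locked) && !isTRUE(a$locked))
      phase <- stats::runif(1, 0, 2 * pi)
    env <- exp(-((times - a$center_ms)^2) / (2 * a$sd_ms^2))
    out <- out + a$amp * env * cos(2 * pi * a$freq_hz * (times - a$center_ms) / 1000 + phase)
  }
  out
}

# Smooth 0/1 source-latency window with cosine tapers (taper_ms each side).
coupling_window <- function(times, on, off, taper_ms = 4) {
  if (is.na(on) && is.na(off)) return(rep(1, length(times)))
  if (is.na(on)) on <- -Inf
  if (is.na(off)) off <- Inf
  w <- as.numeric(times >= on & times <= off)
  if (is.finite(on)) {
    ramp <- times >= on - taper_ms & times < on
    w[ramp] <- 0.5 * (1 + cos(pi * (on - times[ramp]) / taper_ms))
  }
  if (is.finite(off)) {
    ramp <- times > off & times <= off + taper_ms
    w[ramp] <- 0.5 * (1 + cos(pi * (times[ramp] - off) / taper_ms))
  }
  w
}

# 1/f^alpha + white-floor background noise, standardized to sd = 1.
# floor_frac is the relative white amplitude floor added to the 1/f profile.
pink_noise <- function(n, dt_ms, alpha = 1, floor_frac = 0.25) {
  freqs <- seq(0, floor(n / 2)) / (n * dt_ms / 1000)  # Hz
  prof <- c(0, 1 / freqs[-1]^(alpha / 2)) + floor_frac
  nh <- length(freqs)
  spec <- complex(real = stats::rnorm(nh), imaginary = stats::rnorm(nh)) * prof
  spec[1] <- 0
  full <- c(spec, Conj(rev(spec[2:(n - nh + 1)])))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s
}

# Clean (noise-free) per-node traces for one trial, after applying per-node
# latency jitter to the intrinsic atoms and propagating couplings in
# topological order.
propagate_network <- function(network, times, dt_ms, intensity_gain, jitter_ms) {
  order <- topo_order(network)
  traces <- stats::setNames(
    rep(list(numeric(length(times))), length(network$nodes)), network$nodes)
  jit <- stats::setNames(
    if (jitter_ms > 0) stats::runif(length(network$nodes), -jitter_ms, jitter_ms)
    else numeric(length(network$nodes)),
    network$nodes)
  cp <- network$couplings
  for (nd in order) {
    atoms <- network$node_signals[[nd]]
    tr <- intensity_gain * eval_atoms(atoms, times - jit[[nd]],
                                      randomize_unlocked = TRUE)
    incoming <- cp[cp$target == nd, , drop = FALSE]
    for (i in seq_len(nrow(incoming))) {
      co <- incoming[i, ]
      lag_samp <- round(co$lag_ms / dt_ms)
      src <- traces[[co$source]] *
        coupling_window(times, co$window_on, co$window_off)
      tr <- tr + co$gain * shift_samples(src, lag_samp)
    }
    traces[[nd]] <- tr
  }
  traces
}

run_seed <- function(master_seed, run_index) {
  as.integer((as.numeric(master_seed) + 7919 * run_index) %% 2147483647)
}

#' Generate a full synthetic session with planted couplings
#'
#' Builds single-trial regional activation curves (RACs) for every node of a
#' ground-truth network across all runs of a session design. Each trial's
#' clean trace is the node's intrinsic Gabor-atom waveform (scaled by the
#' run's intensity gain and shifted by per-trial latency jitter) plus the
#' lagged, gain-scaled contributions of its in-couplings; `1/f`-plus-white
#' background noise is then added. Runs are seeded independently but
#' deterministically from the master seed, so any subset of runs is
#' reproducible in isolation.
#'
#' @param design a [session_design()].
#' @param network a [gt_network()].
#' @param seed master integer seed.
#' @param noise_sd standard deviation of the background noise in the
#'   (arbitrary) RAC amplitude units; the default 0.5 puts a unit-amplitude
#'   evoked component at a single-trial amplitude SNR of 2.
#' @param jitter_ms half-width of the uniform per-trial, per-node latency
#'   jitter (ms); 0 disables jitter. Lags of couplings exceeding the epoch
#'   length are a configuration error.
#' @return An object of class `synthetic_session`: a list with the design,
#'   network, seed and a list `runs`, each run holding `condition`, `side`,
#'   `rep`, `n_trials`, `seed` and `racs` (a named list of [rac_ensemble()]
#'   objects, one per node).
#' @export
generate_session <- function(design, network, seed,
                             noise_sd = 0.5, jitter_ms = 3) {
  stopifnot(inherits(design, "session_design"), inherits(network, "gt_network"))
  times <- design_times(design)
  dt <- 1000 / design$sampling_rate
  epoch_len <- design$epoch_window[2] - design$epoch_window[1]
  if (nrow(network$couplings) && any(network$couplings$lag_ms > epoch_len))
    stop("coupling lag exceeds the epoch length")

  conditions <- expand.grid(rep = seq_len(design$repetitions),
                            side = design$sides,
                            intensity = design$intensities,
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
  runs <- vector("list", nrow(conditions))
  for (r in seq_len(nrow(conditions))) {
    cond <- conditions$intensity[r]
    gain <- network$intensity_gains[[cond]]
    n_tr <- if (cond == "Motor") design$motor_trials else design$trials_per_run
    rs <- run_seed(seed, r)
    set.seed(rs)
    mats <- stats::setNames(
      rep(list(matrix(0, n_tr, length(times))), length(network$nodes)),
      network$nodes)
    for (tr in seq_len(n_tr)) {
      clean <- propagate_network(network, times, dt, gain, jitter_ms)
      for (nd in network$nodes) {
        noise <- if (noise_sd > 0) noise_sd * pink_noise(length(times), dt) else 0
        mats[[nd]][tr, ] <- clean[[nd]] + noise
      }
    }
    runs[[r]] <- list(
      condition = cond, side = conditions$side[r], rep = conditions$rep[r],
      n_trials = n_tr, seed = rs,
      racs = lapply(stats::setNames(network$nodes, network$nodes), function(nd)
        rac_ensemble(mats[[nd]], times, roi = nd))
    )
  }
  structure(list(design = design, network = network, seed = seed,
                 noise_sd = noise_sd, jitter_ms = jitter_ms, runs = runs),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %d runs, %d ROIs, seed %s\n",
              length(x$runs), length(x$network$nodes), format(x$seed)))
  invisible(x)
}

#' Pick runs of a synthetic session by condition
#'
#' @param session a [generate_session()] result.
#' @param condition intensity label, or NULL for all.
#' @param side wrist, or NULL for all.
#' @return list of run objects, in session order.
#' @export
session_runs <- function(session, condition = NULL, side = NULL) {
  keep <- vapply(session$runs, function(r) {
    (is.null(condition) || r$condition %in% condition) &&
      (is.null(side) || r$side %in% side)
  }, logical(1))
  session$runs[keep]
}

#' Generate grid-level CDV datasets with planted focal sources
#'
#' Fixture generator for the mapping and contrast stages: builds per-run
#' [cdv_map()] objects containing smooth focal activations (Gaussian spatial
#' profile times a Gaussian latency envelope, optionally oscillatory) plus
#' spatially unstructured Gaussian noise.
#'
#' @param design a [session_design()]; its epoch and sampling rate set the
#'   time axis, its `trials_per_run` the default trial count.
#' @param focal_sources list of sources, each a list with `position` (mm,
#'   inside the grid), `direction` (3-vector, normalized internally),
#'   `amplitude`, `window_ms` = c(on, off) latency window, optional
#'   `freq_hz` (oscillatory carrier) and `spatial_sd_mm` (default 12).
#' @param seed integer seed.
#' @param grid a [source_grid()].
#' @param run_scales named numeric vector: one run per entry, with the
#'   source amplitudes multiplied by the entry (condition-dependent
#'   scaling).
#' @param n_trials trials per run.
#' @param noise_sd sd of the iid noise added to every vector component.
#' @return Named list of [cdv_map()] objects, one per entry of `run_scales`.
#' @export
generate_cdv_dataset <- function(design, focal_sources, seed,
                                 grid = source_grid(),
                                 run_scales = c(run1 = 1),
                                 n_trials = design$trials_per_run,
                                 noise_sd = 1) {
  stopifnot(inherits(design, "session_design"), inherits(grid, "source_grid"))
  times <- design_times(design)
  coords <- grid_coords(grid)
  lo <- grid$origin
  hi <- grid$origin + (grid$shape - 1) * grid$spacing
  np <- n_points(grid)

  profiles <- lapply(focal_sources, function(src) {
    pos <- as.numeric(src$position)
    if (length(pos) != 3L || any(pos < lo) || any(pos > hi))
      stop("focal source position outside the grid")
    dir <- as.numeric(src$direction)
    dir <- dir / sqrt(sum(dir^2))
    ssd <- if (is.null(src$spatial_sd_mm)) 12 else src$spatial_sd_mm
    d2 <- (coords[, 1] - pos[1])^2 + (coords[, 2] - pos[2])^2 + (coords[, 3] - pos[3])^2
    spatial <- exp(-d2 / (2 * ssd^2))
    t0 <- mean(src$window_ms)
    tsd <- diff(src$window_ms) / 4
    env <- exp(-((times - t0)^2) / (2 * tsd^2))
    temporal <- if (!is.null(src$freq_hz))
      env * cos(2 * pi * src$freq_hz * (times - t0) / 1000) else env
    list(spatial = spatial, temporal = src$amplitude * temporal, dir = dir)
  })

  out <- vector("list", length(run_scales))
  names(out) <- names(run_scales)
  for (r in seq_along(run_scales)) {
    set.seed(run_seed(seed, r))
    data <- array(stats::rnorm(n_trials * length(times) * np * 3, sd = noise_sd),
                  dim = c(n_trials, length(times), np, 3))
    for (pr in profiles) {
      st <- outer(pr$temporal, pr$spatial) * run_scales[r]  # time x points
      for (k in 1:3) {
        add <- st * pr$dir[k]
        for (tr in seq_len(n_trials)) data[tr, , , k] <- data[tr, , , k] + add
      }
    }
    out[[r]] <- cdv_map(data, grid, times)
  }
  out
}
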