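# Small designs and fixtures shared across test files. Everything is
# generated in code; nothing is read from disk.

# short-epoch design for grid-level fixtures (keeps CDV arrays small)
short_design <- function(epoch = c(0, 6.4), trials = 8L) {
  session_design(epoch_window = epoch, trials_per_run = trials,
                 repetitions = 1L)
}

# wrap a plain vector as a single-trial RAC ensemble on the 0.8 ms lattice
as_rac <- function(x, roi = "X", t0 = 0) {
  rac_ensemble(matrix(x, nrow = 1), t0 + (seq_along(x) - 1) * 0.8, roi)
}

# deterministic multi-band probe signal: rich enough that windows occupy
# many amplitude bins
probe_signal <- function(n, dt_ms = 0.8, seed = 1) {
  withr::with_seed(seed, {
    t <- (seq_len(n) - 1) * dt_ms / 1000
    rowSums(sapply(c(7, 19, 31, 53), function(f)
      stats::runif(1, 0.5, 1) * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))))
  })
}

# independent Shannon MI oracle from binned windows (plain table counts);
# deliberately separate from the package's estimator
shannon_mi_oracle <- function(x, y, n_bins = 10) {
  brk <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(rep(1L, length(v)))
    pmin(pmax(1L + floor((v - r[1]) / (r[2] - r[1]) * n_bins), 1L), n_bins)
  }
  jt <- table(factor(brk(x), levels = 1:n_bins),
              factor(brk(y), levels = 1:n_bins)) / length(x)
  px <- rowSums(jt); py <- colSums(jt)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h(px) + h(py) - h(as.vector(jt))
}
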