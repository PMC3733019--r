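#' Morlet wavelet scalogram of a RAC ensemble
#'
#' Instantaneous power of single-trial regional activation curves from a
#' complex Morlet filterbank with `sigma_cycles` cycles (default 6): at
#' analysis frequency `f` the wavelet's temporal SD is
#' `sigma_t = sigma_cycles / (2 pi f)`. The transform is evaluated in the
#' frequency domain (Gaussian transfer function with the zero-mean
#' admissibility correction, which at 6 cycles is of order `exp(-18)` but
#' kept for exactness), with zero-padding of the signal; samples closer to
#' an epoch edge than one wavelet half-width (3 temporal SDs) are outside
#' the cone of influence and flagged invalid.
#'
#' @param rac a [rac_ensemble()] (or numeric matrix `trials x samples` with
#'   a `times` attribute supplied via `times`).
#' @param freqs analysis frequencies, Hz; must lie strictly inside
#'   `(0, Nyquist)`. Default 1-100 Hz in 1 Hz steps.
#' @param sigma_cycles wavelet width in cycles.
#' @param aggregate `"trial-mean"` (default): mean across trials of the
#'   single-trial power; `"single-trial"`: per-trial power array.
#' @param times sample latencies in ms, only needed for plain-matrix input.
#' @return An object of class `scalogram`: `power` (`freqs x time`, or
#'   `trials x freqs x time` for single-trial), `freqs`, `times`, `valid`
#'   (`freqs x time` cone-of-influence mask), `roi`, `aggregation`.
#' @export
morlet_power <- function(rac, freqs = 1:100, sigma_cycles = 6,
                         aggregate = c("trial-mean", "single-trial"),
                         times = NULL) {
  aggregate <- match.arg(aggregate)
  if (inherits(rac, "rac_ensemble")) {
    x <- rac$data; times <- rac$times; roi <- rac$roi
  } else {
    x <- rbind(rac); roi <- NA_character_
    if (is.null(times)) stop("'times' is required for plain-matrix input")
  }
  n <- ncol(x)
  dt <- (times[2] - times[1]) / 1000               # s
  nyquist <- 1 / (2 * dt)
  if (any(freqs <= 0) || any(freqs >= nyquist))
    stop(sprintf("frequencies must lie strictly inside (0, %g) Hz", nyquist))
  sigma_t <- sigma_cycles / (2 * pi * min(freqs))  # widest wavelet, s
  # rows whose wavelet half-width (3 SD) leaves no interior sample are
  # fully masked by the cone of influence; only a wholly degenerate
  # request deserves a warning
  if (all(6 * sigma_cycles / (2 * pi * freqs) > n * dt))
    warning("epoch is shorter than the widest wavelet at every requested ",
            "frequency; all samples are outside the cone of influence")

  pad <- stats::nextn(n + ceiling(min(6 * sigma_t, 2 * n * dt) / dt), 2)
  fax <- c(seq(0, pad / 2), seq(-pad / 2 + 1, -1)) / (pad * dt)  # Hz, FFT order
  X <- stats::mvfft(rbind(t(x), matrix(0, pad - n, nrow(x))))    # pad x trials

  ntr <- nrow(x)
  pw <- array(0, dim = c(ntr, length(freqs), n))
  valid <- matrix(TRUE, length(freqs), n)
  tsec <- (seq_len(n) - 1) * dt
  for (k in seq_along(freqs)) {
    f0 <- freqs[k]
    st <- sigma_cycles / (2 * pi * f0)
    kappa <- exp(-sigma_cycles^2 / 2)
    H <- exp(-2 * pi^2 * st^2 * (fax - f0)^2) -
      kappa * exp(-2 * pi^2 * st^2 * fax^2)
    coef <- stats::mvfft(X * H, inverse = TRUE)[seq_len(n), , drop = FALSE] / pad
    pw[, k, ] <- t(Mod(coef)^2)
    hw <- 3 * st
    valid[k, ] <- tsec >= hw & tsec <= (n - 1) * dt - hw
  }
  power <- if (aggregate == "trial-mean") {
    m <- apply(pw, c(2, 3), mean)
    dimnames(m) <- NULL
    m
  } else pw
  structure(list(power = power, freqs = as.numeric(freqs), times = times,
                 valid = valid, roi = roi, sigma_cycles = sigma_cycles,
                 aggregation = aggregate),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %s: %d freqs x %d samples (%s)\n",
              x$roi, length(x$freqs), length(x$times), x$aggregation))
  invisible(x)
}

#' Plot a scalogram
#'
#' @param x a [morlet_power()] result with trial-mean aggregation.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot.scalogram <- function(x, main = x$roi, ...) {
  stopifnot(x$aggregation == "trial-mean")
  graphics::image(x$times, x$freqs, t(x$power),
                  xlab = "time (ms)", ylab = "frequency (Hz)",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' Time-frequency location of a scalogram's power maximum
#'
#' @param scal a trial-mean [morlet_power()] result.
#' @param restrict_valid only search inside the cone of influence.
#' @return list with `freq` (Hz), `time` (ms) and `power` at the maximum.
#' @export
scalogram_peak <- function(scal, restrict_valid = TRUE) {
  stopifnot(inherits(scal, "scalogram"), scal$aggregation == "trial-mean")
  p <- scal$power
  if (restrict_valid) p[!scal$valid] <- -Inf
  idx <- arrayInd(which.max(p), dim(p))
  list(freq = scal$freqs[idx[1]], time = scal$times[idx[2]],
       power = scal$power[idx[1], idx[2]])
}
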