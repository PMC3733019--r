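#' Spatio-frequency transform of a CDV map
#'
#' Fourier transforms the full-epoch time course of every grid point and
#' Cartesian component of each trial, after demeaning and zero-padding the
#' series so the DFT bin spacing equals `resolution` (0.2 Hz requires a 5 s
#' padded window, i.e. 6250 samples at 1250 Hz). No taper is applied
#' (rectangular window). The amplitude modulus per component is retained.
#'
#' @param map a [cdv_map()].
#' @param trials trial indices to transform (default: all).
#' @param resolution frequency bin spacing, Hz.
#' @param freq_range `c(lo, hi)` in Hz; only bins inside the range are kept
#'   (default 0-100 Hz, the analysis band).
#' @param demean subtract each series' mean before padding (default TRUE;
#'   keeps the DC bin from dominating).
#' @return A [spatio_freq_map()] with amplitudes
#'   `trials x bins x points x 3`.
#' @export
to_spatio_frequency <- function(map, trials = NULL, resolution = 0.2,
                                freq_range = c(0, 100), demean = TRUE) {
  stopifnot(inherits(map, "cdv_map"))
  d <- dim(map$data)
  if (d[2] < 2L) stop("epoch must contain at least 2 samples")
  if (is.null(trials)) trials <- seq_len(d[1])
  dt <- (map$times[2] - map$times[1]) / 1000          # s
  fs <- 1 / dt
  nfft <- round(fs / resolution)
  if (nfft < d[2])
    stop("requested resolution is coarser than the epoch's native resolution")
  freqs <- (seq_len(nfft) - 1) * resolution
  keep <- which(freqs >= freq_range[1] & freqs <= freq_range[2])
  np <- d[3]
  amp <- array(0, dim = c(length(trials), length(keep), np, 3L))
  chunk <- max(1L, 1024L %/% 3L)
  for (ti in seq_along(trials)) {
    for (p0 in seq(1L, np, by = chunk)) {
      pts <- p0:min(np, p0 + chunk - 1L)
      x <- map$data[trials[ti], , pts, , drop = FALSE]     # 1 x time x pts x 3
      x <- matrix(x, nrow = d[2])                          # time x (pts*3)
      if (demean) x <- sweep(x, 2, colMeans(x))
      padded <- rbind(x, matrix(0, nfft - d[2], ncol(x)))
      sp <- Mod(stats::mvfft(padded))[keep, , drop = FALSE]
      amp[ti, , pts, ] <- array(sp, dim = c(length(keep), length(pts), 3L))
    }
  }
  spatio_freq_map(amp, map$grid, freqs[keep])
}
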