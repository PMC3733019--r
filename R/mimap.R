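#' Time-delayed MI map of an ordered ROI pair
#'
#' Computes `M(t, tau)`: the Renyi mutual information between a short
#' moving window of the first ROI's trial-averaged RAC centered at latency
#' `t` and the equally long window of the second ROI's averaged RAC
#' centered at `t + tau`, for every point of a `(t, tau)` lattice. Positive
#' tau means ROI1 leads ROI2. The window is 24 ms (30 samples at 1250 Hz)
#' and is left-heavy around its center: with sample period `dt` and window
#' length `w`, it spans `t - (w/2) dt ... t + (w/2 - 1) dt`.
#'
#' Amplitudes are binned into `n_bins` uniform bins spanning each series'
#' full-epoch range (fixed across windows; per-window binning via
#' `binning = "window"`). Lattice cells whose windows extend beyond the
#' epoch are invalid (`NA`). Negative finite-sample MI estimates are
#' floored at zero; the count of floored cells is recorded in `n_floored`.
#'
#' @param rac_a,rac_b [rac_ensemble()] objects (trial-averaged internally)
#'   or plain numeric vectors (already-averaged RACs; then `times` is
#'   required).
#' @param t_range,tau_range lattice extents in ms (defaults: the full
#'   epoch for `t`, -100..200 ms for `tau`).
#' @param t_step,tau_step lattice steps in ms; rounded to a whole number
#'   of samples (min 1).
#' @param window_ms moving-window length, ms.
#' @param alpha Renyi order.
#' @param n_bins amplitude bins.
#' @param binning `"series"` (bins fixed from the whole epoch, default) or
#'   `"window"` (bins from each window's own range).
#' @param times sample latencies (ms) for plain-vector input.
#' @param pair `c(roi1, roi2)` labels; taken from the ensembles when
#'   available.
#' @return An object of class `mi_map`: `values` (`t x tau` matrix, NA
#'   outside validity), `t`, `tau`, `pair`, `alpha`, `n_bins`,
#'   `window_ms`, `n_floored`, `normalized = FALSE`.
#' @export
mi_map <- function(rac_a, rac_b, t_range = NULL, tau_range = c(-100, 200),
                   t_step = 0.8, tau_step = 0.8, window_ms = 24,
                   alpha = 4, n_bins = 10,
                   binning = c("series", "window"),
                   times = NULL, pair = NULL) {
  binning <- match.arg(binning)
  get_series <- function(r, nm) {
    if (inherits(r, "rac_ensemble")) list(x = average_rac(r), times = r$times, roi = r$roi)
    else list(x = as.numeric(r), times = times, roi = nm)
  }
  a <- get_series(rac_a, "ROI1"); b <- get_series(rac_b, "ROI2")
  if (is.null(a$times)) stop("'times' is required for plain-vector input")
  if (length(a$x) != length(b$x)) stop("RACs must span the same epoch")
  tm <- a$times
  n <- length(tm)
  dt <- tm[2] - tm[1]
  w <- as.integer(round(window_ms / dt))
  if (w > n) stop("moving window is longer than the epoch")
  if (w < 2L) stop("moving window must contain at least 2 samples")
  left <- w %/% 2L
  right <- w - 1L - left
  if (is.null(t_range)) t_range <- range(tm)
  if (is.null(pair)) pair <- c(a$roi, b$roi)

  ts_samp <- max(1L, as.integer(round(t_step / dt)))
  tau_samp <- max(1L, as.integer(round(tau_step / dt)))
  it0 <- which.min(abs(tm - t_range[1]))
  t_idx <- seq(it0, which.min(abs(tm - t_range[2])), by = ts_samp)
  # anchor the tau lattice at zero delay
  lo <- as.integer(round(tau_range[1] / dt))
  hi <- as.integer(round(tau_range[2] / dt))
  tau_off <- sort(unique(c(seq(0L, lo, by = -tau_samp), seq(0L, hi, by = tau_samp))))
  tau_off <- tau_off[tau_off >= lo & tau_off <= hi]

  rx <- if (binning == "series") range(a$x) else NULL
  ry <- if (binning == "series") range(b$x) else NULL
  bx <- bin_indices(a$x, n_bins, rx)
  by <- bin_indices(b$x, n_bins, ry)

  # log sum(counts^alpha) of the marginal histogram for every window center
  lsum <- function(bi) {
    out <- rep(NA_real_, n)
    for (c in seq(left + 1L, n - right))
      out[c] <- log(sum(tabulate(bi[(c - left):(c + right)], n_bins)^alpha))
    out
  }
  # the fast counts-based identity needs alpha != 1; Shannon falls back to
  # the generic estimator with series-wide ranges
  series_mode <- binning == "series" && alpha != 1
  if (series_mode) {
    lsx <- lsum(bx)
    lsy <- lsum(by)
  }

  nt <- length(t_idx); ntau <- length(tau_off)
  vals <- matrix(NA_real_, nt, ntau)
  n_floored <- 0L
  alog_n <- alpha * log(w)
  inv <- 1 / (1 - alpha)
  for (i in seq_len(nt)) {
    it <- t_idx[i]
    if (it - left < 1L || it + right > n) next
    wx <- (it - left):(it + right)
    if (series_mode) {
      bxw <- bx[wx]
      jx <- n_bins * (bxw - 1L)
      lx <- lsx[it]
    }
    for (j in seq_len(ntau)) {
      iy <- it + tau_off[j]
      if (iy - left < 1L || iy + right > n) next
      wy <- (iy - left):(iy + right)
      if (series_mode) {
        cj <- tabulate(jx + by[wy], n_bins * n_bins)
        mi <- (lx + lsy[iy] - log(sum(cj^alpha)) - alog_n) * inv
      } else {
        mi <- delayed_mi(a$x[wx], b$x[wy], alpha = alpha, n_bins = n_bins,
                         range_x = rx, range_y = ry)
      }
      if (mi < 0) { mi <- 0; n_floored <- n_floored + 1L }
      vals[i, j] <- mi
    }
  }
  structure(list(values = vals, t = tm[t_idx], tau = tau_off * dt,
                 pair = pair, alpha = alpha, n_bins = n_bins,
                 window_ms = window_ms, n_floored = n_floored,
                 normalized = FALSE),
            class = "mi_map")
}

#' @export
print.mi_map <- function(x, ...) {
  cat(sprintf("<mi_map> %s -> %s: %d t x %d tau, max %.3g nats%s\n",
              x$pair[1], x$pair[2], length(x$t), length(x$tau),
              max(x$values, na.rm = TRUE),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Normalize an MI map to unit maximum
#'
#' Divides all values by the map's maximum over the valid region, giving a
#' `[0, 1]` map; this is the per-subject, per-pair normalization applied
#' before cross-subject averaging and link thresholding. An all-zero map
#' is returned unchanged with the `all_zero` flag set. Idempotent.
#'
#' @param map an [mi_map()].
#' @return the normalized `mi_map` (`normalized = TRUE`, with `scale` the
#'   maximum divided out and `all_zero` flag).
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "mi_map"))
  mx <- suppressWarnings(max(map$values, na.rm = TRUE))
  if (!is.finite(mx)) stop("map has no valid values")
  if (mx == 0) {
    map$all_zero <- TRUE
    map$scale <- if (isTRUE(map$normalized)) map$scale else 0
    map$normalized <- TRUE
    return(map)
  }
  map$values <- map$values / mx
  map$scale <- if (isTRUE(map$normalized)) map$scale * mx else mx
  map$all_zero <- FALSE
  map$normalized <- TRUE
  map
}

#' Threshold-gated average of per-subject normalized MI maps
#'
#' Cross-subject combination rule: at each `(t, tau)` cell the average map
#' is zero if any subject's normalized MI is less than the threshold `c`
#' (strictly), and otherwise the mean of the subjects' normalized values.
#'
#' @param maps list of normalized [mi_map()]s on identical lattices for
#'   the same ROI pair.
#' @param c threshold (default 0.4).
#' @return An `mi_map`-like object of class `c("avg_mi_map", "mi_map")`
#'   with the gated average in `values` and `threshold = c`.
#' @export
average_mi_maps <- function(maps, c = 0.4) {
  if (!length(maps)) stop("need at least one map")
  ref <- maps[[1]]
  for (m in maps) {
    stopifnot(inherits(m, "mi_map"))
    if (!isTRUE(m$normalized)) stop("maps must be normalized first")
    if (!isTRUE(all.equal(m$t, ref$t)) || !isTRUE(all.equal(m$tau, ref$tau)))
      stop("maps must share the (t, tau) lattice")
    if (!identical(m$pair, ref$pair)) stop("maps must refer to the same ROI pair")
  }
  arr <- simplify2array(lapply(maps, `[[`, "values"))  # t x tau x subj
  below <- apply(arr < c, c(1, 2), any)
  avg <- apply(arr, c(1, 2), mean)
  avg[below & !is.na(below)] <- 0
  out <- ref
  out$values <- avg
  out$threshold <- c
  out$n_subjects <- length(maps)
  class(out) <- c("avg_mi_map", "mi_map")
  out
}
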