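#' Spherical region of interest
#'
#' A ROI is a sphere in source space together with its principal direction,
#' the dominant orientation of the current-density vectors inside it.
#' Regional activation curves project in-sphere CDVs onto this direction.
#'
#' @param label ROI name, e.g. `"S1-L"`, `"BA7-R"`, `"V1-L"`.
#' @param center sphere center, mm (length-3).
#' @param radius sphere radius in mm (default 8, i.e. 0.8 cm).
#' @param principal_direction unit 3-vector; normalized internally.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(label, center, radius = 8, principal_direction) {
  stopifnot(length(center) == 3L, length(principal_direction) == 3L)
  if (radius <= 0) stop("'radius' must be positive (mm)")
  nrm <- sqrt(sum(principal_direction^2))
  if (nrm == 0) stop("principal direction cannot be the zero vector")
  structure(list(label = as.character(label), center = as.numeric(center),
                 radius = as.numeric(radius),
                 principal_direction = as.numeric(principal_direction) / nrm),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> %s: center (%g, %g, %g) mm, radius %g mm\n",
              x$label, x$center[1], x$center[2], x$center[3], x$radius))
  invisible(x)
}

#' Ensemble of single-trial regional activation curves
#'
#' The regional activation curve (RAC) of a ROI is the signed scalar time
#' course obtained by summing, per 0.8 ms timeslice, the projections of the
#' in-sphere current-density vectors onto the ROI's principal direction.
#' An ensemble holds all single-trial RACs of one ROI in one run.
#'
#' @param data `trials x samples` numeric matrix.
#' @param times sample latencies, ms.
#' @param roi ROI label (character) or a [roi_spec()].
#' @return An object of class `rac_ensemble`.
#' @export
rac_ensemble <- function(data, times, roi) {
  data <- as.matrix(data)
  if (ncol(data) != length(times))
    stop("'times' must have one entry per sample column")
  if (nrow(data) < 1L) stop("at least one trial is required")
  label <- if (inherits(roi, "roi_spec")) roi$label else as.character(roi)
  structure(list(data = data, times = as.numeric(times), roi = label,
                 spec = if (inherits(roi, "roi_spec")) roi else NULL),
            class = "rac_ensemble")
}

#' @export
print.rac_ensemble <- function(x, ...) {
  cat(sprintf("<rac_ensemble> %s: %d trials x %d samples (%.1f..%.1f ms)\n",
              x$roi, nrow(x$data), ncol(x$data), min(x$times), max(x$times)))
  invisible(x)
}

#' Trial-averaged RAC
#'
#' @param ensemble a [rac_ensemble()].
#' @return numeric vector, the mean curve across trials.
#' @export
average_rac <- function(ensemble) {
  stopifnot(inherits(ensemble, "rac_ensemble"))
  colMeans(ensemble$data)
}

#' Principal direction of a set of current-density vectors
#'
#' Directional-statistics mean orientation for vector data weighted by both
#' magnitude and direction: the normalized resultant (vector sum) of all CDV
#' samples. Since each sample is magnitude times unit direction, the plain
#' vector sum *is* the magnitude-weighted resultant of the directions.
#'
#' @param vectors `n x 3` matrix of CDV samples (rows may come from all
#'   timeslices of a fitting window and all in-sphere grid points).
#' @param tol degeneracy tolerance: the resultant length must exceed
#'   `tol` times the mean sample magnitude, otherwise the input is flagged
#'   as balanced/degenerate.
#' @return unit 3-vector with attribute `degenerate` (logical).
#' @export
principal_direction <- function(vectors, tol = 1e-8) {
  vectors <- rbind(vectors)
  stopifnot(ncol(vectors) == 3L)
  mags <- sqrt(rowSums(vectors^2))
  if (all(mags == 0)) stop("all CDV samples are zero; no direction defined")
  res <- colSums(vectors)
  rlen <- sqrt(sum(res^2))
  degen <- rlen <= tol * mean(mags) * nrow(vectors)
  if (degen) {
    warning("balanced opposing vectors: resultant is (numerically) zero")
    return(structure(c(NA_real_, NA_real_, NA_real_), degenerate = TRUE))
  }
  structure(res / rlen, degenerate = FALSE)
}

#' Fit a ROI's principal direction from a CDV map
#'
#' Pools the in-sphere CDV samples over a latency fitting window (default
#' 15-50 ms, the dominant early response) and over trials, and returns the
#' magnitude-weighted resultant direction.
#'
#' @param map a [cdv_map()].
#' @param center,radius sphere center (mm) and radius (mm).
#' @param window latency window (ms) over which directions are pooled.
#' @return unit 3-vector (see [principal_direction()]).
#' @export
fit_principal_direction <- function(map, center, radius = 8, window = c(15, 50)) {
  stopifnot(inherits(map, "cdv_map"))
  idx <- roi_point_index(map$grid, center, radius)
  tsel <- which(map$times >= window[1] & map$times <= window[2])
  if (!length(tsel)) stop("fitting window contains no timeslices")
  block <- map$data[, tsel, idx, , drop = FALSE]
  principal_direction(matrix(block, ncol = 3L))
}

roi_point_index <- function(grid, center, radius) {
  coords <- grid_coords(grid)
  d2 <- (coords[, 1] - center[1])^2 + (coords[, 2] - center[2])^2 +
    (coords[, 3] - center[3])^2
  idx <- which(d2 <= radius^2)
  if (!length(idx)) stop("no grid point falls inside the ROI sphere")
  idx
}

#' Regional activation curves from a CDV map
#'
#' For each requested trial and each timeslice, sums the projections
#' `CDV . principal_direction` over the grid points inside the ROI sphere
#' (integration over the ROI, up to the constant cell volume).
#'
#' @param map a [cdv_map()].
#' @param roi a [roi_spec()].
#' @param trials trial indices (default: all).
#' @return A [rac_ensemble()].
#' @export
compute_rac <- function(map, roi, trials = NULL) {
  stopifnot(inherits(map, "cdv_map"), inherits(roi, "roi_spec"))
  idx <- roi_point_index(map$grid, roi$center, roi$radius)
  if (is.null(trials)) trials <- seq_len(dim(map$data)[1])
  u <- roi$principal_direction
  proj <- map$data[trials, , idx, 1, drop = FALSE] * u[1] +
    map$data[trials, , idx, 2, drop = FALSE] * u[2] +
    map$data[trials, , idx, 3, drop = FALSE] * u[3]
  rac <- apply(proj[, , , 1, drop = FALSE], c(1, 2), sum)
  rac_ensemble(rac, map$times, roi)
}

#' Moving-window SNR of a single-trial RAC ensemble
#'
#' Evoked-to-residual power ratio in a short moving window: for each
#' window (default 6.4 ms = 8 samples, stepped by one 0.8 ms sample),
#' \deqn{SNR = P[\bar{x}] / \mathrm{mean}_k P[x_k - \bar{x}]}
#' where `P` is the mean squared amplitude inside the window, `x_k` the
#' k-th single-trial RAC and `x-bar` the trial average. Windows with zero
#' residual power (all trials identical) are flagged `Inf`.
#'
#' @param ensemble a [rac_ensemble()] with at least 2 trials.
#' @param window_ms window length in ms.
#' @param step_ms window step in ms.
#' @return An object of class `snr_series`: list with `snr`, `centers`
#'   (window-center latencies, ms) and `roi`.
#' @export
compute_snr <- function(ensemble, window_ms = 6.4, step_ms = 0.8) {
  stopifnot(inherits(ensemble, "rac_ensemble"))
  x <- ensemble$data
  if (nrow(x) < 2L) stop("SNR needs at least 2 trials")
  dt <- ensemble$times[2] - ensemble$times[1]
  w <- max(2L, as.integer(round(window_ms / dt)))
  step <- max(1L, as.integer(round(step_ms / dt)))
  n <- ncol(x)
  starts <- seq(1L, n - w + 1L, by = step)
  avg <- colMeans(x)
  resid2 <- sweep(x, 2, avg)^2
  mean_resid2 <- colMeans(resid2)  # per-sample residual power, mean over trials
  avg2 <- avg^2
  cum_a <- c(0, cumsum(avg2))
  cum_r <- c(0, cumsum(mean_resid2))
  sig_p <- (cum_a[starts + w] - cum_a[starts]) / w
  res_p <- (cum_r[starts + w] - cum_r[starts]) / w
  snr <- ifelse(res_p == 0, Inf, sig_p / res_p)
  centers <- vapply(starts, function(s) mean(ensemble$times[s:(s + w - 1L)]), numeric(1))
  structure(list(snr = snr, centers = centers, roi = ensemble$roi,
                 window_ms = window_ms, step_ms = step_ms),
            class = "snr_series")
}

#' @export
print.snr_series <- function(x, ...) {
  cat(sprintf("<snr_series> %s: %d windows, max SNR %.3g\n",
              x$roi, length(x$snr), max(x$snr)))
  invisible(x)
}

#' Select ROIs by early-window SNR
#'
#' Keeps the ROIs whose moving-window SNR strictly exceeds the threshold at
#' one or more window centers inside the post-stimulus selection window
#' (default 0-100 ms). This is the criterion that reduces the candidate ROI
#' set to the high-SNR subset entering the network analysis.
#'
#' @param snr_list named list of [compute_snr()] results (names are ROI
#'   labels; unnamed lists use each element's own `roi` label).
#' @param threshold selection threshold on the SNR ratio.
#' @param window post-stimulus latency window in ms.
#' @return character vector of selected ROI labels, in input order.
#' @export
select_rois <- function(snr_list, threshold = 0.2, window = c(0, 100)) {
  if (is.null(names(snr_list)))
    names(snr_list) <- vapply(snr_list, `[[`, character(1), "roi")
  keep <- vapply(snr_list, function(s) {
    sel <- s$centers >= window[1] & s$centers <= window[2]
    any(s$snr[sel] > threshold)
  }, logical(1))
  names(snr_list)[keep]
}
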