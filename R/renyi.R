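#' Renyi entropy of a discrete distribution
#'
#' Order-alpha Renyi entropy in nats,
#' \deqn{H_\alpha = \frac{1}{1-\alpha}\,\ln \sum_i p_i^\alpha,}
#' with the Shannon entropy `-sum p log p` returned at `alpha = 1` (its
#' continuous limit). Empty bins contribute zero terms.
#'
#' @param p numeric vector of bin probabilities; non-negative, summing to 1
#'   (within `1e-8`).
#' @param alpha entropy order, `> 0`. The connectivity analysis uses
#'   `alpha = 4`.
#' @return entropy in nats.
#' @examples
#' renyi_entropy(rep(0.1, 10), 4)  # ln 10 for any order
#' @export
renyi_entropy <- function(p, alpha = 4) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1")
  if (alpha <= 0) stop("'alpha' must be positive")
  if (alpha == 1) {
    nz <- p > 0
    return(-sum(p[nz] * log(p[nz])))
  }
  log(sum(p[p > 0]^alpha)) / (1 - alpha)
}

# Uniform-width bin assignment over 'range', clamped to [1, n_bins].
# Degenerate zero-width range puts everything in bin 1.
bin_indices <- function(x, n_bins, range = NULL) {
  if (is.null(range)) range <- base::range(x)
  width <- range[2] - range[1]
  if (width <= 0) return(rep(1L, length(x)))
  idx <- 1L + as.integer(floor((x - range[1]) / width * n_bins))
  pmin.int(pmax.int(idx, 1L), n_bins)
}

#' Time-delayed Renyi mutual information between two signal windows
#'
#' Histogram estimator of
#' \deqn{I_\alpha(X, Y; \tau) = \frac{1}{1-\alpha}\ln\frac{\sum_i
#'   p_x^\alpha(i)\,\sum_j p_y^\alpha(j)}{\sum_{i,j} p_{x,y}^\alpha(i,j;\tau)}
#'   = H_\alpha(X) + H_\alpha(Y) - H_\alpha(X, Y; \tau),}
#' where the marginal and joint probabilities come from binning the two
#' equal-length amplitude windows into `n_bins` uniform bins. The delay
#' enters through the caller: `y` is the window of the second series
#' shifted by tau relative to `x`. Bin edges default to each window's own
#' range; map-level code passes series-wide ranges so bins are fixed
#' across windows.
#'
#' @param x,y equal-length numeric windows.
#' @param alpha Renyi order (default 4).
#' @param n_bins number of amplitude bins (default 10).
#' @param range_x,range_y amplitude ranges defining the bin edges.
#' @return mutual information in nats (raw estimate; may be slightly
#'   negative for finite samples at `alpha != 1`).
#' @export
delayed_mi <- function(x, y, alpha = 4, n_bins = 10,
                       range_x = NULL, range_y = NULL) {
  if (length(x) != length(y)) stop("windows must have equal length")
  n <- length(x)
  bx <- bin_indices(x, n_bins, range_x)
  by <- bin_indices(y, n_bins, range_y)
  cx <- tabulate(bx, n_bins)
  cy <- tabulate(by, n_bins)
  cj <- tabulate(bx + n_bins * (by - 1L), n_bins * n_bins)
  if (alpha == 1) {
    hx <- renyi_entropy(cx / n, 1)
    hy <- renyi_entropy(cy / n, 1)
    hj <- renyi_entropy(cj / n, 1)
    return(hx + hy - hj)
  }
  # I = [ln sum(cx^a) + ln sum(cy^a) - ln sum(cj^a) - a ln n] / (1 - a)
  (log(sum(cx^alpha)) + log(sum(cy^alpha)) -
      log(sum(cj^alpha)) - alpha * log(n)) / (1 - alpha)
}

#' Permutation null distribution for the windowed MI estimator
#'
#' Destroys the temporal pairing between the two windows by randomly
#' permuting the samples of `y`, re-estimating the MI each time. The
#' resulting distribution characterizes the finite-sample bias of the
#' histogram estimator under independence and can calibrate link
#' thresholds.
#'
#' @inheritParams delayed_mi
#' @param n_perm number of permutations.
#' @return numeric vector of `n_perm` null MI values (nats).
#' @export
mi_permutation_null <- function(x, y, alpha = 4, n_bins = 10, n_perm = 1000,
                                range_x = NULL, range_y = NULL) {
  vapply(seq_len(n_perm), function(i)
    delayed_mi(x, sample(y), alpha = alpha, n_bins = n_bins,
               range_x = range_x, range_y = range_y),
    numeric(1))
}
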