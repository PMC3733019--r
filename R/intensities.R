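#' Sensory and motor stimulation thresholds
#'
#' The two per-wrist calibration currents from which the three
#' experimental stimulus intensities are derived: the sensory threshold
#' STH (minimal current the subject can just feel) and the motor threshold
#' MTH (minimal current producing a thumb twitch).
#'
#' @param sth sensory threshold, mA.
#' @param mth motor threshold, mA; must satisfy `0 < sth <= mth`.
#' @param side which wrist, `"left"` or `"right"`.
#' @return An object of class `stimulus_thresholds`.
#' @export
stimulus_thresholds <- function(sth, mth, side = c("left", "right")) {
  side <- match.arg(side)
  if (!is.numeric(sth) || !is.numeric(mth) || length(sth) != 1L || length(mth) != 1L)
    stop("'sth' and 'mth' must be single numbers (mA)")
  if (sth <= 0) stop("sensory threshold must be positive")
  if (mth < sth) stop("motor threshold cannot be below the sensory threshold")
  structure(list(sth = as.numeric(sth), mth = as.numeric(mth), side = side),
            class = "stimulus_thresholds")
}

#' Derive the three stimulus intensities from the thresholds
#'
#' With `delta = MTH - STH`, the three constant-current intensities are
#' fixed offsets of a quarter of the threshold gap:
#' \deqn{Sub = STH - 0.25\Delta,\quad Supra = STH + 0.25\Delta,\quad
#'       Motor = MTH + 0.25\Delta.}
#' Sub stimuli fall below perception, Supra stimuli are clearly felt, and
#' Motor stimuli produce a small thumb twitch. The ordering
#' `Sub < STH < Supra <= MTH < Motor` holds whenever `sth < mth`
#' (degenerate `delta = 0` collapses all three onto the common threshold).
#'
#' @param thresholds a [stimulus_thresholds()].
#' @return Named numeric vector `c(Sub =, Supra =, Motor =)`, mA.
#' @examples
#' derive_intensities(stimulus_thresholds(2.2, 5.3, "left"))
#' @export
derive_intensities <- function(thresholds) {
  stopifnot(inherits(thresholds, "stimulus_thresholds"))
  delta <- thresholds$mth - thresholds$sth
  c(Sub   = thresholds$sth - 0.25 * delta,
    Supra = thresholds$sth + 0.25 * delta,
    Motor = thresholds$mth + 0.25 * delta)
}
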