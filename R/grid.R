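#' Source-space representation grid
#'
#' A regular cubic lattice of representation points covering the source
#' space. Tomographic current-density estimates are stored at these points
#' only; finer maps are obtained by interpolation (see
#' [interpolate_fine()]). The default is a 17 x 17 x 17 grid with 8 mm
#' inter-point spacing, i.e. a cube of about 13 cm side covering the whole
#' brain.
#'
#' Grid indices are 1-based in R; physical positions are
#' `origin + (index - 1) * spacing`, in mm.
#'
#' @param shape integer vector of length 3, number of points per axis.
#' @param spacing inter-point distance in mm.
#' @param origin physical position (mm) of grid point (1, 1, 1).
#' @return An object of class `source_grid`.
#' @export
source_grid <- function(shape = c(17L, 17L, 17L), spacing = 8, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, length(origin) == 3L)
  if (any(shape < 2L)) stop("each grid axis needs at least 2 points")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("'spacing' must be a single positive number (mm)")
  structure(
    list(shape = shape, spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "source_grid"
  )
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %d x %d x %d points, %g mm spacing\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing))
  invisible(x)
}

n_points <- function(grid) prod(grid$shape)

#' Physical coordinates of all grid points
#'
#' @param grid a [source_grid()].
#' @return A `prod(shape) x 3` matrix of positions in mm, in column-major
#'   point order (first axis fastest), matching the point axis of
#'   [cdv_map()] data.
#' @export
grid_coords <- function(grid) {
  ax <- lapply(1:3, function(d) grid$origin[d] + (seq_len(grid$shape[d]) - 1) * grid$spacing)
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]], KEEP.OUT.ATTRS = FALSE))
}

#' Spatio-temporal current-density-vector map
#'
#' Container for single-trial current-density vectors (CDV) on the
#' representation grid: one 3-vector per trial, timeslice and grid point.
#' The time axis is in ms with the 0.8 ms step of the 1250 Hz acquisition.
#'
#' @param data numeric array `trials x timeslices x points x 3`.
#' @param grid a [source_grid()]; `prod(grid$shape)` must equal `dim(data)[3]`.
#' @param times numeric vector of timeslice latencies in ms.
#' @return An object of class `cdv_map`.
#' @export
cdv_map <- function(data, grid, times) {
  stopifnot(inherits(grid, "source_grid"))
  d <- dim(data)
  if (length(d) != 4L || d[4] != 3L)
    stop("'data' must be a trials x timeslices x points x 3 array")
  if (d[3] != n_points(grid))
    stop("point axis of 'data' does not match the grid")
  if (length(times) != d[2])
    stop("'times' must have one entry per timeslice")
  if (!all(is.finite(data))) stop("CDV data must be finite")
  structure(list(data = data, grid = grid, times = as.numeric(times)),
            class = "cdv_map")
}

#' @export
print.cdv_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cdv_map> %d trial(s), %d timeslices (%.1f..%.1f ms), %d grid points\n",
              d[1], d[2], min(x$times), max(x$times), d[3]))
  invisible(x)
}

#' Trial-wise CDV moduli
#'
#' Euclidean modulus of the current-density vector at every trial,
#' timeslice and grid point. These moduli, pooled across the trials of a
#' run at a fixed latency, are the samples entering the pointwise t
#' contrasts ([pointwise_t_map()]).
#'
#' @param map a [cdv_map()] or [spatio_freq_map()].
#' @return numeric array `trials x axis points x grid points`.
#' @export
cdv_moduli <- function(map) {
  stopifnot(inherits(map, c("cdv_map", "spatio_freq_map")))
  x <- if (inherits(map, "cdv_map")) map$data else map$amplitude
  sqrt(x[, , , 1, drop = FALSE]^2 + x[, , , 2, drop = FALSE]^2 +
         x[, , , 3, drop = FALSE]^2)[, , , 1]
}

#' Spatio-frequency current-density map
#'
#' Frequency-domain counterpart of [cdv_map()]: per trial, frequency bin,
#' grid point and Cartesian component, the amplitude modulus of the
#' discrete Fourier transform of the epoch time course. Produced by
#' [to_spatio_frequency()]; bin spacing is 0.2 Hz.
#'
#' @param amplitude numeric array `trials x frequency bins x points x 3`
#'   of non-negative amplitude moduli.
#' @param grid a [source_grid()].
#' @param freqs frequency-axis values in Hz.
#' @return An object of class `spatio_freq_map`.
#' @export
spatio_freq_map <- function(amplitude, grid, freqs) {
  stopifnot(inherits(grid, "source_grid"))
  d <- dim(amplitude)
  if (length(d) != 4L || d[4] != 3L)
    stop("'amplitude' must be a trials x bins x points x 3 array")
  if (d[3] != n_points(grid)) stop("point axis does not match the grid")
  if (length(freqs) != d[2]) stop("'freqs' must have one entry per bin")
  structure(list(amplitude = amplitude, grid = grid, freqs = as.numeric(freqs)),
            class = "spatio_freq_map")
}

#' @export
print.spatio_freq_map <- function(x, ...) {
  d <- dim(x$amplitude)
  cat(sprintf("<spatio_freq_map> %d trial(s), %d bins (%.1f..%.1f Hz), %d grid points\n",
              d[1], d[2], min(x$freqs), max(x$freqs), d[3]))
  invisible(x)
}
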