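#' @name interpolation
#' @title Quintic spline interpolation of grid fields
#' @description
#' Current-density maps are stored on a coarse representation grid (8 mm
#' spacing); high-resolution (1 mm) maps are derived from it by smooth
#' quintic polynomial interpolation, realized here as tensor-product
#' piecewise-quintic (degree-5 B-spline) interpolation per Cartesian
#' component. The interpolant reproduces the coarse-grid values exactly at
#' the nodes, reproduces polynomials up to degree 5, and is C^4-smooth
#' inside the grid.
NULL

# Degree-5 (order-6) B-spline interpolation operator for one axis:
# returns the fine-lattice evaluation matrix E %*% solve(B) so that
# fine = M %*% values. Falls back to lower order on very short axes.
spline_axis_operator <- function(sites, eval_at) {
  n <- length(sites)
  ord <- min(6L, n)
  if (n - ord > 0) {
    half <- floor(ord / 2)
    interior <- sites[(half + 1):(half + n - ord)]
  } else interior <- numeric(0)
  knots <- c(rep(sites[1], ord), interior, rep(sites[n], ord))
  B <- splines::splineDesign(knots, sites, ord = ord)
  E <- splines::splineDesign(knots, eval_at, ord = ord)
  E %*% solve(B)
}

# Contract matrix M (m x dim[axis]) against 'arr' along 'axis'.
apply_axis <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  x <- aperm(arr, perm)
  dim(x) <- c(d[axis], prod(d[-axis]))
  y <- M %*% x
  dim(y) <- c(nrow(M), d[-axis])
  aperm(y, order(perm))
}

#' Interpolate a scalar or vector grid field to a fine lattice
#'
#' @param field numeric array `n1 x n2 x n3` (scalar) or `n1 x n2 x n3 x 3`
#'   (vector field), sampled on a regular grid.
#' @param spacing coarse grid spacing, mm.
#' @param target_spacing fine lattice spacing, mm; must not exceed
#'   `spacing`.
#' @param origin physical position of the first grid point, mm.
#' @return An object of class `fine_field`: list with `values` (fine
#'   array, extra length-3 axis for vector fields), `axes` (per-axis
#'   physical coordinates, mm) and `spacing`.
#' @export
interp_quintic <- function(field, spacing, target_spacing = 1, origin = c(0, 0, 0)) {
  d <- dim(field)
  vector_field <- length(d) == 4L
  if (!(length(d) == 3L || (vector_field && d[4] == 3L)))
    stop("'field' must be n1 x n2 x n3 (x 3)")
  if (target_spacing > spacing) stop("'target_spacing' must not exceed the grid spacing")
  shp <- d[1:3]
  axes <- lapply(1:3, function(k) origin[k] + (seq_len(shp[k]) - 1) * spacing)
  fine_axes <- lapply(1:3, function(k) seq(axes[[k]][1], axes[[k]][shp[k]], by = target_spacing))
  ops <- lapply(1:3, function(k) spline_axis_operator(axes[[k]], fine_axes[[k]]))
  interp3 <- function(a) {
    for (k in 1:3) a <- apply_axis(a, ops[[k]], k)
    a
  }
  if (vector_field) {
    comps <- lapply(1:3, function(c) interp3(field[, , , c]))
    values <- array(unlist(comps, use.names = FALSE),
                    dim = c(vapply(fine_axes, length, integer(1)), 3L))
  } else {
    values <- interp3(field)
  }
  structure(list(values = values, axes = fine_axes,
                 spacing = target_spacing),
            class = "fine_field")
}

#' Fine interpolation of one trial/timeslice of a CDV map
#'
#' Convenience wrapper extracting a single spatial vector field from a
#' [cdv_map()] and interpolating it with [interp_quintic()].
#'
#' @param map a [cdv_map()].
#' @param trial,timeslice 1-based indices into the map.
#' @param target_spacing fine lattice spacing, mm (default 1).
#' @return A `fine_field` (vector-valued).
#' @export
interpolate_fine <- function(map, trial, timeslice, target_spacing = 1) {
  stopifnot(inherits(map, "cdv_map"))
  d <- dim(map$data)
  if (trial < 1 || trial > d[1]) stop("trial index out of range")
  if (timeslice < 1 || timeslice > d[2]) stop("timeslice index out of range")
  shp <- map$grid$shape
  field <- array(map$data[trial, timeslice, , ], dim = c(shp, 3L))
  interp_quintic(field, map$grid$spacing, target_spacing, map$grid$origin)
}

#' Locate the activity maximum of a fine field
#'
#' Finds the fine-lattice position with the largest activity, defined as
#' the Euclidean modulus of the interpolated 3-vector (or the value itself
#' for scalar fields). Ties are broken by the first occurrence in
#' column-major order (lowest index along the first axis varying fastest)
#' and flagged; constant fields are flagged degenerate.
#'
#' @param fine a `fine_field` from [interp_quintic()] /
#'   [interpolate_fine()].
#' @return list with `position` (mm), `value` (modulus at the maximum),
#'   `tie` and `degenerate` flags.
#' @export
locate_maximum <- function(fine) {
  stopifnot(inherits(fine, "fine_field"))
  v <- fine$values
  act <- if (length(dim(v)) == 4L)
    sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2) else v
  rng <- range(act)
  # constant up to floating jitter from the interpolation
  if (rng[2] - rng[1] <= 1e-12 * max(abs(rng[2]), 1)) {
    return(list(position = c(NA_real_, NA_real_, NA_real_), value = rng[2],
                tie = TRUE, degenerate = TRUE))
  }
  i <- which.max(act)
  tie <- sum(act == act[i]) > 1L
  idx <- arrayInd(i, dim(act))
  pos <- vapply(1:3, function(k) fine$axes[[k]][idx[k]], numeric(1))
  list(position = pos, value = act[i], tie = tie, degenerate = FALSE)
}
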