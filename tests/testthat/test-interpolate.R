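grid17 <- function() source_grid(c(17, 17, 17), spacing = 8)

sample_on_grid <- function(grid, f) {
  co <- grid_coords(grid)
  array(f(co), dim = grid$shape)
}

test_that("interpolation reproduces constants and polynomials up to its degree", {
  g <- source_grid(c(9, 9, 9), spacing = 8)
  const <- sample_on_grid(g, function(co) rep(3.5, nrow(co)))
  fine <- interp_quintic(const, 8, target_spacing = 2)
  expect_equal(range(fine$values), c(3.5, 3.5), tolerance = 1e-10)

  lin <- sample_on_grid(g, function(co) 0.3 * co[, 1] - 0.7 * co[, 2] + 2 * co[, 3] + 1)
  finel <- interp_quintic(lin, 8, target_spacing = 2)
  fx <- expand.grid(x = finel$axes[[1]], y = finel$axes[[2]], z = finel$axes[[3]])
  expect_equal(as.vector(finel$values),
               0.3 * fx$x - 0.7 * fx$y + 2 * fx$z + 1, tolerance = 1e-9)

  quint <- sample_on_grid(g, function(co) (co[, 1] / 10)^5 + (co[, 2] / 10)^4)
  fineq <- interp_quintic(quint, 8, target_spacing = 4)
  fq <- expand.grid(x = fineq$axes[[1]], y = fineq$axes[[2]], z = fineq$axes[[3]])
  expect_equal(as.vector(fineq$values), (fq$x / 10)^5 + (fq$y / 10)^4,
               tolerance = 1e-8)
})

test_that("the interpolant matches the data exactly at coarse nodes", {
  g <- source_grid(c(7, 7, 7), spacing = 8)
  set.seed(42)
  field <- array(rnorm(343), dim = g$shape)
  fine <- interp_quintic(field, 8, target_spacing = 1)
  node_idx <- seq(1, length(fine$axes[[1]]), by = 8)
  expect_equal(fine$values[node_idx, node_idx, node_idx], field, tolerance = 1e-9)
})

test_that("an off-grid quadratic maximum is located to about a millimetre", {
  g <- source_grid(c(9, 9, 9), spacing = 8)
  x0 <- c(34.3, 29.8, 36.9)             # between nodes
  f <- sample_on_grid(g, function(co)
    100 - ((co[, 1] - x0[1])^2 + (co[, 2] - x0[2])^2 + (co[, 3] - x0[3])^2) / 50)
  fine <- interp_quintic(f, 8, target_spacing = 1)
  mx <- locate_maximum(fine)
  expect_false(mx$degenerate)
  expect_lt(sqrt(sum((mx$position - x0)^2)), 1.01)
})

test_that("maxima ties and degenerate fields are flagged", {
  g <- source_grid(c(5, 5, 5), spacing = 8)
  flat <- interp_quintic(array(1, dim = g$shape), 8, target_spacing = 8)
  expect_true(locate_maximum(flat)$degenerate)

  two <- array(0, dim = c(5, 5, 5))
  two[2, 2, 2] <- two[4, 4, 4] <- 1
  # exact duplicate maxima on a hand-built fine field
  fine <- structure(list(values = two, axes = lapply(1:3, function(k) (0:4) * 8),
                         spacing = 8), class = "fine_field")
  mx <- locate_maximum(fine)
  expect_true(mx$tie)
  expect_equal(mx$position, c(8, 8, 8))  # first occurrence, column-major
})

test_that("interpolate_fine extracts the requested trial/timeslice and validates", {
  g <- source_grid(c(5, 5, 5), spacing = 8)
  arr <- array(rnorm(2 * 3 * 125 * 3), dim = c(2, 3, 125, 3))
  m <- cdv_map(arr, g, c(0, 0.8, 1.6))
  fine <- interpolate_fine(m, trial = 2, timeslice = 3, target_spacing = 8)
  expect_equal(as.vector(fine$values),
               as.vector(array(arr[2, 3, , ], dim = c(5, 5, 5, 3))),
               tolerance = 1e-9)
  expect_error(interpolate_fine(m, 3, 1), "trial index")
  expect_error(interpolate_fine(m, 1, 9), "timeslice index")
  expect_error(interp_quintic(array(0, c(5, 5, 5)), 8, target_spacing = 9),
               "must not exceed")
})

test_that("random smooth single-source fields are localized within a millimetre", {
  # the same measurement the acceptance stage reports, at reduced count
  set.seed(7)
  errs <- replicate(12, {
    g <- grid17()
    ctr <- runif(3, 40, 88)
    width <- runif(1, 10, 18)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    co <- grid_coords(g)
    d2 <- colSums((t(co) - ctr)^2)
    prof <- exp(-d2 / (2 * width^2))
    field <- array(outer(prof, dir), dim = c(g$shape, 3))
    mx <- locate_maximum(interp_quintic(field, 8, target_spacing = 1))
    sqrt(sum((mx$position - ctr)^2))
  })
  expect_lte(median(errs), 1)
})
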