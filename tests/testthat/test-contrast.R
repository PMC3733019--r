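rand_moduli <- function(trials, axis, points, seed, shift = 0, at = NULL) {
  set.seed(seed)
  arr <- array(abs(rnorm(trials * axis * points, mean = 2)), dim = c(trials, axis, points))
  if (!is.null(at)) arr[, at[1], at[2]] <- arr[, at[1], at[2]] + shift
  arr
}

test_that("contrasting a dataset with itself gives t = 0, p = 1 everywhere", {
  a <- rand_moduli(10, 4, 6, seed = 1)
  m <- pointwise_t_map(a, a, axis = 1:4)
  expect_true(all(m$t == 0))
  expect_true(all(m$p == 1))
})

test_that("a planted five-SD mean shift is detected far below 1e-4", {
  # closed form: with n = 100 per side and a 5-pooled-SD shift the
  # noncentrality is 5 / sqrt(2/100) ~ 35; the two-sided p is astronomically
  # small, so p < 1e-4 must hold with huge margin
  a <- rand_moduli(100, 3, 5, seed = 2, shift = 5, at = c(2, 3))
  b <- rand_moduli(100, 3, 5, seed = 3)
  m <- pointwise_t_map(a, b, axis = 1:3)
  expect_lt(m$p[2, 3], 1e-4)
  # every other cell is null: none should be astronomically significant
  p_null <- m$p
  p_null[2, 3] <- NA
  expect_gt(min(p_null, na.rm = TRUE), 1e-8)
})

test_that("the vectorised t map agrees with stats::t.test cell by cell", {
  a <- rand_moduli(7, 2, 3, seed = 4)
  b <- rand_moduli(9, 2, 3, seed = 5)
  m <- pointwise_t_map(a, b, axis = 1:2)
  mw <- pointwise_t_map(a, b, axis = 1:2, var_equal = FALSE)
  for (i in 1:2) for (j in 1:3) {
    tt <- t.test(a[, i, j], b[, i, j], var.equal = TRUE)
    expect_equal(m$t[i, j], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(m$p[i, j], tt$p.value, tolerance = 1e-12)
    tw <- t.test(a[, i, j], b[, i, j])
    expect_equal(mw$t[i, j], unname(tw$statistic), tolerance = 1e-12)
    expect_equal(mw$p[i, j], tw$p.value, tolerance = 1e-12)
  }
})

test_that("zero-variance cells are flagged degenerate with p = 1", {
  a <- rand_moduli(5, 2, 2, seed = 6)
  a[, 1, 1] <- 3
  b <- rand_moduli(5, 2, 2, seed = 7)
  b[, 1, 1] <- 3
  m <- pointwise_t_map(a, b, axis = 1:2)
  expect_true(m$degenerate[1, 1])
  expect_equal(m$p[1, 1], 1)
  expect_true(is.na(m$t[1, 1]))
})

test_that("combinatorial contrasts produce 4, 8 and 1 maps", {
  runs <- lapply(1:6, function(s) rand_moduli(6, 2, 4, seed = 10 + s))
  motor <- runs[1:2]; supra <- runs[3:4]; sub <- runs[5:6]
  expect_length(combinatorial_contrasts(motor, supra, axis = 1:2), 4L)
  expect_length(combinatorial_contrasts(motor, supra, axis = 1:2, merge = sub), 8L)
  expect_length(combinatorial_contrasts(motor[1], supra[1], axis = 1:2), 1L)
  expect_error(combinatorial_contrasts(list(), supra, axis = 1:2), "empty")
  # merged datasets hold the union of the trials
  maps8 <- combinatorial_contrasts(motor, supra, axis = 1:2, merge = sub)
  expect_equal(maps8[[1]]$n, c(6L, 12L))
})

test_that("intersection requires significance in every member map", {
  mk <- function(p) structure(list(p = matrix(p, 1, 1), t = matrix(1, 1, 1),
                                   degenerate = matrix(FALSE, 1, 1),
                                   axis = 1, domain = "time", label = "x",
                                   n = c(5L, 5L)), class = "spm_map")
  three_of_four <- list(mk(1e-6), mk(1e-6), mk(1e-6), mk(0.5))
  expect_equal(sum(intersect_activation(three_of_four, 1e-4)$active), 0L)
  four_of_four <- list(mk(1e-6), mk(1e-6), mk(1e-6), mk(1e-5))
  expect_equal(sum(intersect_activation(four_of_four, 1e-4)$active), 1L)
  freq <- mk(1e-6); freq$domain <- "frequency"
  expect_error(intersect_activation(list(mk(1e-6), freq)), "mixed domains")
})

test_that("shrinking alpha never adds active points, and the intersection is a subset", {
  runs_a <- lapply(1:2, function(s) rand_moduli(20, 3, 30, seed = 20 + s,
                                                shift = 2, at = c(2, 7)))
  runs_b <- lapply(1:2, function(s) rand_moduli(20, 3, 30, seed = 30 + s))
  maps <- combinatorial_contrasts(runs_a, runs_b, axis = 1:3)
  act_loose <- intersect_activation(maps, alpha = 0.01)
  act_tight <- intersect_activation(maps, alpha = 1e-4)
  expect_true(all(act_loose$active | !act_tight$active))
  for (m in maps) expect_true(all(m$p[act_tight$active] < 1e-4))
})
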