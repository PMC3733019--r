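test_that("a pure delayed copy puts the MI ridge at the planted delay", {
  n <- 500
  x <- probe_signal(n, seed = 2)
  y <- c(numeric(15), x[1:(n - 15)])          # 12 ms at 0.8 ms/sample
  # cross-correlation oracle confirms the construction
  cc <- ccf(y, x, lag.max = 30, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 15)
  m <- mi_map(x, y, times = (0:(n - 1)) * 0.8, t_range = c(40, 250),
              tau_range = c(-40, 40), t_step = 4, tau_step = 0.8)
  for (i in seq_along(m$t)) {
    prof <- m$values[i, ]
    if (all(is.na(prof))) next
    expect_lte(abs(m$tau[which.max(prof)] - 12), 0.81,
               label = sprintf("argmax tau at t = %g", m$t[i]))
  }
})

test_that("exchange symmetry M_AB(t, tau) = M_BA(t + tau, -tau) holds on the lattice", {
  n <- 400
  a <- probe_signal(n, seed = 5)
  b <- probe_signal(n, seed = 6)
  tm <- (0:(n - 1)) * 0.8
  mab <- mi_map(a, b, times = tm, t_range = c(40, 260), tau_range = c(-24, 24),
                t_step = 1.6, tau_step = 1.6)
  mba <- mi_map(b, a, times = tm, t_range = c(40, 300), tau_range = c(-24, 24),
                t_step = 1.6, tau_step = 1.6)
  checked <- 0L
  for (i in seq_along(mab$t)) for (j in seq_along(mab$tau)) {
    v <- mab$values[i, j]
    if (is.na(v)) next
    i2 <- which(abs(mba$t - (mab$t[i] + mab$tau[j])) < 1e-9)
    j2 <- which(abs(mba$tau + mab$tau[j]) < 1e-9)
    if (!length(i2) || !length(j2) || is.na(mba$values[i2, j2])) next
    expect_equal(v, mba$values[i2, j2], tolerance = 1e-12)
    checked <- checked + 1L
  }
  expect_gt(checked, 100)
})

test_that("self-MI at zero delay equals the windowed marginal entropy and caps the row", {
  n <- 300
  x <- probe_signal(n, seed = 8)
  tm <- (0:(n - 1)) * 0.8
  m <- mi_map(x, x, times = tm, t_range = c(40, 200), tau_range = c(-20, 20),
              t_step = 8, tau_step = 1.6)
  j0 <- which(m$tau == 0)
  bx <- mipath:::bin_indices(x, 10, range(x))
  for (i in seq_along(m$t)) {
    it <- which(abs(tm - m$t[i]) < 1e-9)
    win <- bx[(it - 15):(it + 14)]
    h <- renyi_entropy(tabulate(win, 10) / 30, 4)
    expect_equal(m$values[i, j0], h, tolerance = 1e-12)
    expect_true(all(m$values[i, ] <= m$values[i, j0] + 1e-12, na.rm = TRUE))
  }
})

test_that("windows beyond the epoch are invalid and window length is checked", {
  x <- probe_signal(100, seed = 9)
  tm <- (0:99) * 0.8
  m <- mi_map(x, x, times = tm, t_range = c(0, 79.2), tau_range = c(-16, 16),
              t_step = 0.8, tau_step = 8)
  expect_true(all(is.na(m$values[1:5, ])))   # left edge: x window incomplete
  expect_false(anyNA(m$values[30, which(m$tau == 0)]))
  expect_error(mi_map(x[1:20], x[1:20], times = tm[1:20]), "longer than the epoch")
})

test_that("normalization scales the maximum to 1 and is idempotent", {
  x <- probe_signal(200, seed = 10)
  y <- probe_signal(200, seed = 11)
  m <- mi_map(x, y, times = (0:199) * 0.8, t_range = c(30, 120),
              tau_range = c(-10, 10), t_step = 4, tau_step = 4)
  nm <- normalize_map(m)
  expect_equal(max(nm$values, na.rm = TRUE), 1)
  expect_equal(nm$scale, max(m$values, na.rm = TRUE))
  nn <- normalize_map(nm)
  expect_equal(nn$values, nm$values)
  expect_equal(nn$scale, nm$scale)

  z <- m; z$values[] <- 0
  nz <- normalize_map(z)
  expect_true(nz$all_zero)
  expect_true(all(nz$values == 0))
})

test_that("cross-subject averaging zeroes cells where any subject is below c", {
  base <- mi_map(probe_signal(200, seed = 12), probe_signal(200, seed = 13),
                 times = (0:199) * 0.8, t_range = c(30, 100),
                 tau_range = c(0, 8), t_step = 8, tau_step = 8)
  base <- normalize_map(base)
  m1 <- base; m2 <- base
  m1$values[] <- 0.5; m2$values[] <- 0.3
  expect_true(all(average_mi_maps(list(m1, m2), c = 0.4)$values == 0))
  m2$values[] <- 0.6
  expect_true(all(average_mi_maps(list(m1, m2), c = 0.4)$values == 0.55))
  # boundary: "less than c" is strict, so exactly c survives
  m1$values[] <- 0.4; m2$values[] <- 0.4
  expect_true(all(average_mi_maps(list(m1, m2), c = 0.4)$values == 0.4))

  other <- normalize_map(mi_map(probe_signal(120, seed = 14),
                                probe_signal(120, seed = 15),
                                times = (0:119) * 0.8, t_range = c(30, 60),
                                tau_range = c(0, 8), t_step = 8, tau_step = 8))
  expect_error(average_mi_maps(list(m1, other), 0.4), "lattice|pair")
  raw <- mi_map(probe_signal(200, seed = 16), probe_signal(200, seed = 17),
                times = (0:199) * 0.8, t_range = c(30, 100),
                tau_range = c(0, 8), t_step = 8, tau_step = 8)
  expect_error(average_mi_maps(list(m1, raw), 0.4), "normalized")
})
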