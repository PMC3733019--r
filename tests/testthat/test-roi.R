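test_that("the principal direction is the magnitude-weighted resultant", {
  expect_equal(as.numeric(principal_direction(rbind(c(0, 0, 1), c(0, 0, 1)))),
               c(0, 0, 1))
  expect_equal(as.numeric(principal_direction(rbind(c(1, 0, 0), c(0, 1, 0)))),
               c(1, 1, 0) / sqrt(2))
  expect_equal(as.numeric(principal_direction(rbind(c(2, 0, 0), c(0, 1, 0)))),
               c(2, 1, 0) / sqrt(5))
  expect_error(principal_direction(rbind(c(0, 0, 0))), "all CDV samples are zero")
  expect_warning(pd <- principal_direction(rbind(c(1, 0, 0), c(-1, 0, 0))),
                 "balanced")
  expect_true(attr(pd, "degenerate"))
})

one_point_map <- function(vecs_by_time, grid = source_grid(c(3, 3, 3), 8)) {
  # a single trial with the given per-timeslice CDV at the grid center,
  # zero elsewhere
  np <- n_points(grid)
  center <- (np + 1) %/% 2
  arr <- array(0, dim = c(1, nrow(vecs_by_time), np, 3))
  arr[1, , center, ] <- vecs_by_time
  cdv_map(arr, grid, (seq_len(nrow(vecs_by_time)) - 1) * 0.8)
}

test_that("RACs sum in-sphere projections onto the principal direction", {
  g <- source_grid(c(3, 3, 3), 8)
  dirz <- c(0, 0, 1)
  m <- one_point_map(rbind(5 * dirz, c(3, 0, 0)), g)
  roi <- roi_spec("S1", center = c(8, 8, 8), radius = 6, principal_direction = dirz)
  r <- compute_rac(m, roi)
  expect_equal(unname(r$data[1, ]), c(5, 0))  # orthogonal CDV contributes 0

  # two in-sphere points with projections 3 and -1 sum to 2
  arr <- array(0, dim = c(1, 1, 27, 3))
  arr[1, 1, 14, 3] <- 3
  arr[1, 1, 13, 3] <- -1
  m2 <- cdv_map(arr, g, 0)
  roi2 <- roi_spec("X", c(8, 8, 8), radius = 8.5, principal_direction = dirz)
  expect_equal(unname(compute_rac(m2, roi2)$data[1, 1]), 2)

  far <- roi_spec("far", c(8, 8, 8), radius = 1, principal_direction = dirz)
  g2 <- source_grid(c(3, 3, 3), 8, origin = c(100, 100, 100))
  m3 <- cdv_map(arr, g2, 0)
  expect_error(compute_rac(m3, far), "no grid point")
})

test_that("RAC is linear in the map and equivariant under joint rotation", {
  g <- source_grid(c(3, 3, 3), 8)
  set.seed(5)
  arr1 <- array(rnorm(1 * 4 * 27 * 3), dim = c(1, 4, 27, 3))
  arr2 <- array(rnorm(1 * 4 * 27 * 3), dim = c(1, 4, 27, 3))
  tm <- (0:3) * 0.8
  roi <- roi_spec("R", c(8, 8, 8), radius = 9,
                  principal_direction = c(1, 2, 2))
  r1 <- compute_rac(cdv_map(arr1, g, tm), roi)$data
  r2 <- compute_rac(cdv_map(arr2, g, tm), roi)$data
  r12 <- compute_rac(cdv_map(arr1 + arr2, g, tm), roi)$data
  expect_equal(r12, r1 + r2, tolerance = 1e-12)

  # rotate all CDVs and the principal direction by the same rotation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  arr_rot <- arr1
  for (t in 1:4) arr_rot[1, t, , ] <- arr1[1, t, , ] %*% t(R)
  roi_rot <- roi_spec("R", c(8, 8, 8), radius = 9,
                      principal_direction = as.numeric(R %*% roi$principal_direction))
  expect_equal(compute_rac(cdv_map(arr_rot, g, tm), roi_rot)$data, r1,
               tolerance = 1e-12)
})

test_that("identical trials give infinite SNR; pure noise gives about 1/n", {
  tm <- (0:99) * 0.8
  sig <- sin(2 * pi * 30 * tm / 1000)
  same <- rac_ensemble(rbind(sig, sig, sig), tm, "A")
  s <- compute_snr(same)
  expect_true(all(is.infinite(s$snr)))

  # Monte-Carlo oracle: for n iid zero-mean trials the expected ratio of
  # average power to mean residual power is 1/(n-1) ~ 1/n at n = 100
  set.seed(11)
  n <- 100
  vals <- replicate(30, {
    e <- rac_ensemble(matrix(rnorm(n * 40), n, 40), (0:39) * 0.8, "N")
    mean(compute_snr(e)$snr)
  })
  expect_lt(abs(mean(vals) - 1 / (n - 1)), 0.0015)
  expect_error(compute_snr(rac_ensemble(matrix(1, 1, 10), (0:9) * 0.8, "X")),
               "at least 2")
})

test_that("SNR grows with planted evoked amplitude", {
  tm <- (0:249) * 0.8
  shape <- exp(-((tm - 100)^2) / (2 * 15^2))
  snr_at <- function(amp) {
    set.seed(17)
    e <- rac_ensemble(t(replicate(40, amp * shape + rnorm(250))), tm, "A")
    max(compute_snr(e)$snr)
  }
  v <- vapply(c(0.5, 1, 2), snr_at, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("ROI selection applies the strict threshold inside the window only", {
  mk <- function(roi, snr, centers) structure(
    list(snr = snr, centers = centers, roi = roi, window_ms = 6.4, step_ms = 0.8),
    class = "snr_series")
  lst <- list(
    mk("just_below", rep(0.19, 5), seq(10, 50, by = 10)),
    mk("one_peak", c(0.05, 0.5, 0.05), c(10, 20, 30)),
    mk("pre_stimulus_only", c(5, 0.1, 0.1), c(-50, 20, 80)),
    mk("boundary", rep(0.2, 3), c(10, 20, 30))
  )
  expect_equal(select_rois(lst), "one_peak")
  expect_equal(select_rois(lst, threshold = 0.1), c("just_below", "one_peak", "boundary"))
})
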