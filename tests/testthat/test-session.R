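test_that("the default design yields 12 runs with the right epoch geometry", {
  des <- session_design()
  expect_equal(des$n_samples, 875L)  # 700 ms at 1250 Hz
  tm <- design_times(des)
  expect_equal(tm[1], -200)
  expect_equal(tm[2] - tm[1], 0.8)
  expect_equal(length(tm), 875L)

  net <- gt_network("A", node_signals = list(A = mipath:::gabor_atoms(20, 5, 40, 1)))
  s <- generate_session(session_design(trials_per_run = 3L), net, seed = 1,
                        noise_sd = 0.1, jitter_ms = 0)
  expect_equal(length(s$runs), 12L)  # 3 intensities x 2 sides x 2 reps
  conds <- table(vapply(s$runs, `[[`, character(1), "condition"))
  expect_equal(unname(conds[c("Sub", "Supra", "Motor")]), rep(4L, 3), ignore_attr = TRUE)
})

test_that("Sub runs hold trials_per_run trials of the full epoch", {
  net <- gt_network("A", node_signals = list(A = mipath:::gabor_atoms(20, 5, 40, 1)))
  des <- session_design(trials_per_run = 120L)
  s <- generate_session(des, net, seed = 3, noise_sd = 0.05)
  sub_run <- session_runs(s, "Sub")[[1]]
  expect_equal(dim(sub_run$racs$A$data), c(120L, 875L))
})

test_that("epoch geometry and run-count validation fire", {
  expect_error(session_design(epoch_window = c(0, 10.1)), "integer sample count")
  expect_error(session_design(repetitions = 0), "at least 1")
  net <- gt_network(c("A", "B"),
                    data.frame(source = "A", target = "B", lag_ms = 900, gain = 1),
                    node_signals = list(A = mipath:::gabor_atoms(20, 5, 40, 1)))
  expect_error(generate_session(session_design(), net, 1), "exceeds the epoch")
})

test_that("a noiseless coupling is an exact sample-shifted copy", {
  # 12 ms at 1250 Hz = 15 samples
  net <- gt_network(c("S1", "BA7"),
                    data.frame(source = "S1", target = "BA7", lag_ms = 12, gain = 0.7),
                    node_signals = list(S1 = mipath:::gabor_atoms(25, 6, 40, 1.2)))
  des <- session_design(trials_per_run = 2L, intensities = "Motor",
                        sides = "left", repetitions = 1L)
  s <- generate_session(des, net, seed = 5, noise_sd = 0, jitter_ms = 0)
  s1 <- s$runs[[1]]$racs$S1$data[1, ]
  ba7 <- s$runs[[1]]$racs$BA7$data[1, ]
  expect_equal(ba7[16:875], 0.7 * s1[1:860], tolerance = 1e-12)
  expect_equal(ba7[1:15], rep(0, 15))
})

test_that("planted lags are recovered by cross-correlation to the nearest sample", {
  net <- blind_like_network()
  des <- session_design(trials_per_run = 2L, intensities = "Motor",
                        sides = "left", repetitions = 1L)
  s <- generate_session(des, net, seed = 11, noise_sd = 0, jitter_ms = 0)
  racs <- s$runs[[1]]$racs
  for (k in seq_len(nrow(net$couplings))) {
    cp <- net$couplings[k, ]
    a <- racs[[cp$source]]$data[1, ]
    b <- racs[[cp$target]]$data[1, ]
    cc <- stats::ccf(b, a, lag.max = 40, plot = FALSE)
    lag_hat <- cc$lag[which.max(cc$acf)] * 0.8
    expect_equal(lag_hat, cp$lag_ms, tolerance = 0.81,
                 label = sprintf("ccf lag for %s->%s", cp$source, cp$target))
  }
})

test_that("identical seed and config reproduce the dataset bit for bit", {
  net <- blind_like_network()
  des <- session_design(trials_per_run = 4L)
  s1 <- generate_session(des, net, seed = 21)
  s2 <- generate_session(des, net, seed = 21)
  expect_identical(s1$runs[[7]]$racs$V1$data, s2$runs[[7]]$racs$V1$data)
  s3 <- generate_session(des, net, seed = 22)
  expect_false(identical(s1$runs[[7]]$racs$V1$data, s3$runs[[7]]$racs$V1$data))
})

test_that("evoked amplitude is ordered Motor > Supra > Sub", {
  net <- blind_like_network()
  des <- session_design(trials_per_run = 12L)
  s <- generate_session(des, net, seed = 31, noise_sd = 0.3)
  mean_amp <- function(cond) {
    runs <- session_runs(s, cond, "left")
    mean(vapply(runs, function(r) {
      avg <- average_rac(r$racs$S1)
      sel <- r$racs$S1$times >= 0 & r$racs$S1$times <= 100
      sqrt(mean(avg[sel]^2))
    }, numeric(1)))
  }
  expect_true(mean_amp("Motor") > mean_amp("Supra"))
  expect_true(mean_amp("Supra") > mean_amp("Sub"))
})

test_that("the sighted-like variant removes every coupling into visual areas", {
  b <- blind_like_network()
  sgt <- sighted_like_network()
  expect_setequal(sgt$nodes, b$nodes)
  expect_false(any(sgt$couplings$target %in% c("V1", "V3", "V5")))
  expect_true(all(c("S1", "S2") %in% sgt$couplings$target))
  expect_error(gt_network(c("A", "B"), data.frame(
    source = c("A", "B"), target = c("B", "A"), lag_ms = c(5, 5), gain = c(1, 1))),
    "cycle")
})
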