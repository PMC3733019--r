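# hand-built normalized map with a rectangular super-threshold component
fake_map <- function(t, tau, hot, pair = c("S1", "BA7"), value = 0.9,
                     peak = NULL) {
  v <- matrix(0.05, length(t), length(tau))
  v[hot] <- value
  if (!is.null(peak)) v[peak] <- 1
  structure(list(values = v, t = t, tau = tau, pair = pair, alpha = 4,
                 n_bins = 10, window_ms = 24, n_floored = 0L,
                 normalized = TRUE, scale = 1),
            class = "mi_map")
}

test_that("a rectangular component yields one correctly stamped link", {
  t <- seq(0, 60, by = 4); tau <- seq(-20, 20, by = 2)
  hot <- as.matrix(expand.grid(i = which(t >= 28 & t <= 36),
                               j = which(tau >= 10 & tau <= 14)))
  pk <- matrix(c(which(t == 32), which(tau == 12)), 1)
  lk <- extract_links(fake_map(t, tau, hot, peak = pk), mi_threshold = 0.4)
  expect_equal(nrow(lk), 1L)
  expect_equal(lk$source, "S1")
  expect_equal(lk$target, "BA7")
  expect_equal(lk$source_onset_ms, 28)
  expect_equal(lk$delay_ms, 12)                       # dominant tau row
  expect_equal(c(lk$target_on_ms, lk$target_off_ms), c(38, 50))
  expect_equal(lk$strength, 1)
})

test_that("delays outside the conduction band and latencies outside the range are excluded", {
  t <- seq(0, 60, by = 4); tau <- seq(-20, 20, by = 1)
  near_zero <- as.matrix(expand.grid(i = which(t >= 20 & t <= 28),
                                     j = which(tau == 3)))
  expect_equal(nrow(extract_links(fake_map(t, tau, near_zero), 0.4)), 0L)
  too_late <- as.matrix(expand.grid(i = which(t >= 120), j = which(tau == 10)))
  expect_equal(nrow(extract_links(fake_map(t, tau, too_late), 0.4)), 0L)
})

test_that("negative delays reverse the link direction", {
  t <- seq(0, 60, by = 4); tau <- seq(-20, 20, by = 2)
  hot <- as.matrix(expand.grid(i = which(t >= 40 & t <= 48),
                               j = which(tau == -12)))
  lk <- extract_links(fake_map(t, tau, hot, pair = c("A", "B")), 0.4)
  expect_equal(lk$source, "B")
  expect_equal(lk$target, "A")
  expect_equal(lk$delay_ms, 12)
  expect_equal(lk$source_onset_ms, 40 - 12)           # leading region is B
  expect_equal(c(lk$target_on_ms, lk$target_off_ms), c(40, 48))
})

test_that("separate components yield separate links; raw maps are rejected", {
  t <- seq(0, 60, by = 4); tau <- seq(-20, 20, by = 2)
  hot1 <- as.matrix(expand.grid(i = which(t >= 8 & t <= 16), j = which(tau == 8)))
  hot2 <- as.matrix(expand.grid(i = which(t >= 40 & t <= 48), j = which(tau == 16)))
  m <- fake_map(t, tau, rbind(hot1, hot2))
  lk <- extract_links(m, 0.4)
  expect_equal(nrow(lk), 2L)
  expect_equal(lk$source_onset_ms, c(8, 40))          # sorted by onset
  raw <- m; raw$normalized <- FALSE
  expect_error(extract_links(raw, 0.4), "normalized")
})

test_that("influence diagrams assemble, validate and serialize", {
  lk <- extract_links(fake_map(seq(0, 60, by = 4), seq(-20, 20, by = 2),
                               as.matrix(expand.grid(i = 8:10, j = 17:18))), 0.4)
  d <- build_influence_diagram(list(lk), c("Thal", "S1", "BA7", "V1"))
  expect_s3_class(d, "influence_diagram")
  expect_equal(nrow(d$links), 1L)
  expect_error(build_influence_diagram(list(lk), c("Thal", "V1")), "unknown ROIs")

  empty <- build_influence_diagram(list(), c("A", "B"))
  expect_equal(nrow(empty$links), 0L)
  expect_output(print(empty), "no links extracted")

  path <- tempfile(fileext = ".json")
  diagram_to_json(d, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$rois, c("Thal", "S1", "BA7", "V1"))
  expect_equal(back$links$source, d$links$source)
  expect_equal(back$links$delay_ms, d$links$delay_ms)
})

test_that("component labelling respects 4-connectivity", {
  mask <- matrix(FALSE, 4, 4)
  mask[1, 1] <- mask[1, 2] <- TRUE   # one component
  mask[3, 3] <- TRUE                 # diagonal neighbour of [4, 4]
  mask[4, 4] <- TRUE                 # -> separate component
  lab <- mipath:::label_components(mask)
  expect_equal(lab[1, 1], lab[1, 2])
  expect_false(lab[3, 3] == lab[4, 4])
  expect_equal(max(lab, na.rm = TRUE), 3L)
})
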