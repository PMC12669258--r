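test_that("gfp matches the spatial-SD definition", {
  tpl <- tiny_templates()
  # constant sample -> 0
  expect_equal(gfp(matrix(5, 1, 16))[1], 0)
  # unit-norm zero-mean map scaled by a -> a / sqrt(C)
  a <- 7.3
  expect_equal(gfp(matrix(a * tpl$maps[1, ], 1))[1], a / sqrt(16),
               tolerance = 1e-12)
  # random sample -> brute-force population SD across channels
  set.seed(1)
  x <- matrix(rnorm(3 * 16), 3, 16)
  brute <- apply(x, 1, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(gfp(x), brute, tolerance = 1e-12)
})

test_that("backfit assigns by absolute spatial correlation", {
  tpl <- tiny_templates()
  lay <- tpl$layout
  d_idx <- which(tpl$state_names == "D")
  x <- rbind(
    3 * tpl$maps[d_idx, ],                       # +map_D
    -5 * tpl$maps[d_idx, ],                      # -map_D: polarity ignored
    2 * tpl$maps[1, ] + rnorm(16, sd = 1e-3),    # near map_A
    rep(1, 16)                                   # zero variance after centering
  )
  rec <- eeg_recording(x, 100, lay)
  lab <- suppressMessages(backfit(rec, tpl))
  expect_equal(lab$labels[1:3], c(d_idx, d_idx, 1L))
  expect_true(is.na(lab$labels[4]))
})

test_that("backfit is invariant to sign and positive scaling per sample", {
  tpl <- tiny_templates()
  set.seed(2)
  x <- matrix(rnorm(50 * 16), 50, 16)
  rec1 <- eeg_recording(x, 100, tpl$layout)
  scale <- sample(c(-3, -1, 0.5, 2), 50, replace = TRUE)
  rec2 <- eeg_recording(x * scale, 100, tpl$layout)
  expect_identical(backfit(rec1, tpl)$labels, backfit(rec2, tpl)$labels)
})

test_that("smoothing: identity at factor 0, majority fixes lone flips", {
  tpl <- tiny_templates()
  m <- tiny_model()
  lab <- sample_labels(m, 300, 125, seed = 3)
  rec <- render_eeg(lab, tpl, noise_sigma = 7.5, seed = 4)
  bf <- backfit(rec, tpl)
  expect_identical(smooth_labels(rec, tpl, bf, factor = 0)$labels, bf$labels)
  # a single-sample flip inside a long uniform run is removed
  lab2 <- rep(2L, 101)
  lab2[51] <- 4L
  rec2 <- render_clean(ms_labels(lab2, 125, n_states = 5), tpl)
  sm <- smooth_labels(rec2, tpl, ms_labels(rep(c(2L, 4L, 2L), c(50, 1, 50)),
                                           125, n_states = 5))
  expect_true(all(sm$labels == 2L))
})


test_that("smoothing equals the brute-force reference on random sequences", {
  tpl <- tiny_templates()
  m <- tiny_model()
  for (seed in c(11, 12, 13)) {
    lab <- sample_labels(m, 200, 125, seed = seed)
    rec <- render_eeg(lab, tpl, noise_sigma = 12, seed = seed + 100)
    bf <- backfit(rec, tpl)
    got <- smooth_labels(rec, tpl, bf)
    expect_identical(got$labels, brute_smooth(rec, tpl, bf))
  }
})

test_that("smoothing never invents labels missing from the window", {
  tpl <- tiny_templates()
  lab <- sample_labels(tiny_model(), 400, 125, seed = 21)
  rec <- render_eeg(lab, tpl, noise_sigma = 10, seed = 22)
  bf <- backfit(rec, tpl)
  sm <- smooth_labels(rec, tpl, bf)
  half <- 12
  n <- length(sm$labels)
  ok <- vapply(seq_len(n), function(t) {
    w <- sm$labels[setdiff(max(1, t - half):min(n, t + half), t)]
    sm$labels[t] %in% w || sm$labels[t] == bf$labels[t]
  }, logical(1))
  # every final label is supported by its window or is the sample's own best fit
  expect_true(all(ok))
})

test_that("short segments are relabeled from their neighbors", {
  tpl <- tiny_templates()
  # both neighbors identical: the short run is absorbed
  lab <- ms_labels(c(4, 4, 4, 1, 4, 4, 4), 125, n_states = 5)
  rec <- render_clean(lab, tpl)
  out <- reject_short_segments(rec, tpl, lab, min_samples = 3)
  expect_true(all(out$labels == 4L))
  # no run below the minimum: unchanged
  lab2 <- ms_labels(rep(c(1L, 2L), c(5, 5)), 125, n_states = 5)
  rec2 <- render_clean(lab2, tpl)
  expect_identical(reject_short_segments(rec2, tpl, lab2)$labels, lab2$labels)
  # single run: nothing to relabel
  lab3 <- ms_labels(rep(3L, 2), 125, n_states = 5)
  rec3 <- render_clean(lab3, tpl)
  expect_identical(
    suppressMessages(reject_short_segments(rec3, tpl, lab3, min_samples = 3))$labels,
    lab3$labels)
})

test_that("an odd middle sample joins the better-correlated neighbor", {
  tpl <- tiny_templates()
  # A A A B C C C with the B sample rendered from map_C: it must join C
  lab_true <- c(1L, 1L, 1L, 3L, 3L, 3L, 3L)
  rec <- render_clean(ms_labels(lab_true, 125, n_states = 5), tpl)
  lab_in <- ms_labels(c(1L, 1L, 1L, 2L, 3L, 3L, 3L), 125, n_states = 5)
  out <- reject_short_segments(rec, tpl, lab_in, min_samples = 3)
  # oracle: direct correlation comparison for sample 4
  xc <- rec$data[4, ] - mean(rec$data[4, ])
  cors <- abs(c(cor(xc, tpl$maps[1, ]), cor(xc, tpl$maps[3, ])))
  expect_equal(out$labels[4], c(1L, 3L)[which.max(cors)])
  expect_identical(out$labels, lab_true)
})

test_that("metrics match hand counting", {
  tpl <- tiny_templates()
  # coverage by counting: 5 of 8 samples are D
  lab <- ms_labels(c(1, 1, 2, 4, 4, 4, 4, 4), 125, n_states = 5)
  rec <- render_clean(lab, tpl)
  met <- compute_metrics(rec, lab, tpl)
  expect_equal(met$time_coverage[met$state == "D"], 0.625)
  # mean duration: D runs of 2 and 4 samples at 500 Hz -> 6 ms
  lab2 <- ms_labels(c(4, 4, 1, 4, 4, 4, 4, 2), 500, n_states = 5)
  rec2 <- render_clean(lab2, tpl)
  met2 <- compute_metrics(rec2, lab2, tpl)
  expect_equal(met2$mean_duration_ms[met2$state == "D"], 6.0)
  expect_equal(met2$n_segments[met2$state == "D"], 2L)
})

test_that("coverage sums to 1 and gev stays within [0, 1] under noise", {
  tpl <- tiny_templates()
  lab <- sample_labels(tiny_model(), 1000, 125, seed = 31)
  for (sigma in c(0, 7.5, 30)) {
    rec <- render_eeg(lab, tpl, noise_sigma = sigma, seed = 32)
    bf <- backfit(rec, tpl)
    met <- compute_metrics(rec, bf, tpl)
    expect_equal(sum(met$time_coverage), 1, tolerance = 1e-12)
    expect_gte(sum(met$gev), 0)
    expect_lte(sum(met$gev), 1 + 1e-12)
  }
})

test_that("backfit accuracy degrades monotonically with noise", {
  tpl <- tiny_templates()
  lab <- sample_labels(tiny_model(), 4000, 125, seed = 41)
  acc <- vapply(c(0, 15, 60, 240), function(sigma) {
    rec <- render_eeg(lab, tpl, noise_sigma = sigma, seed = 42)
    mean(backfit(rec, tpl)$labels == lab$labels)
  }, numeric(1))
  expect_gte(acc[1], 0.99)
  expect_true(all(diff(acc) < 0))
})

test_that("labels and recording length mismatches are caught", {
  tpl <- tiny_templates()
  lab <- ms_labels(rep(1L, 10), 125, n_states = 5)
  rec <- render_clean(ms_labels(rep(1L, 9), 125, n_states = 5), tpl)
  expect_error(compute_metrics(rec, lab, tpl), class = "msnf_metrics")
})
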