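make_rec <- function(x, sfreq = 250, n_ch = NULL) {
  if (is.null(dim(x))) x <- matrix(x, ncol = n_ch %||% 1,
                                   nrow = length(x) / (n_ch %||% 1))
  colnames(x) <- NULL
  eeg_recording(x, sfreq)
}

test_that("bandpass keeps the passband and removes drift and DC", {
  sfreq <- 250
  t <- (0:(10 * sfreq - 1)) / sfreq
  rec <- make_rec(cbind(sin(2 * pi * 10 * t), sin(2 * pi * 0.1 * t) + 5), sfreq)
  out <- bandpass(rec, 1, 30)
  core <- (2 * sfreq):(8 * sfreq)  # trim filter edges
  amp10 <- max(abs(out$data[core, 1]))
  expect_equal(amp10, 1, tolerance = 0.01)
  expect_lt(max(abs(out$data[core, 2])), 0.05)  # >= 95% attenuation
  expect_error(bandpass(rec, 1, 200), class = "msnf_filter")
})

test_that("white-noise spectrum matches the designed two-pass response", {
  sfreq <- 250
  set.seed(42)
  n <- 2^15
  rec <- make_rec(rnorm(n), sfreq)
  out <- bandpass(rec, 1, 30, order = 8)
  # analytic oracle: |H_hp|^2 * |H_lp|^2 (two passes of each section)
  hp <- signal::butter(8, 1 / (sfreq / 2), type = "high")
  lp <- signal::butter(8, 30 / (sfreq / 2), type = "low")
  f <- seq(2, 100, by = 2)
  H <- abs(signal::freqz(hp$b, hp$a, f, Fs = sfreq)$h)^2 *
    abs(signal::freqz(lp$b, lp$a, f, Fs = sfreq)$h)^2
  spec_in <- Mod(fft(rec$data[, 1]))^2
  spec_out <- Mod(fft(out$data[, 1]))^2
  bins <- round(f * n / sfreq) + 1
  # average the empirical gain over neighborhoods to tame periodogram noise
  gain <- vapply(seq_along(bins), function(i) {
    idx <- pmax(2, bins[i] + (-8:8))
    mean(spec_out[idx]) / mean(spec_in[idx])
  }, numeric(1))
  keep <- H > 0.05  # compare in the passband where the ratio is well-posed
  expect_equal(gain[keep], H[keep], tolerance = 0.15)
  expect_lt(max(gain[H < 1e-4]), 0.01)
})

test_that("filters are zero-phase: a symmetric pulse stays symmetric", {
  sfreq <- 250
  n <- 2001
  pulse <- exp(-((seq_len(n) - 1001) / 40)^2)
  out <- bandpass(make_rec(pulse, sfreq), 1, 30)$data[, 1]
  expect_lt(max(abs(out - rev(out))), 1e-6)
  outn <- notch(make_rec(pulse, sfreq), 49, 51, method = "iir")$data[, 1]
  expect_lt(max(abs(outn - rev(outn))), 1e-6)
})

test_that("notch attenuates line noise in both dialects", {
  sfreq <- 250
  t <- (0:(12 * sfreq - 1)) / sfreq
  x <- sin(2 * pi * 50 * t) + sin(2 * pi * 10 * t)
  core <- (4 * sfreq):(8 * sfreq)
  for (meth in c("iir", "fir")) {
    out <- notch(make_rec(x, sfreq), 49, 51, method = meth)
    resid <- out$data[core, 1] - sin(2 * pi * 10 * t[core])
    expect_lt(sqrt(mean(resid^2)), 0.1)
  }
  out <- notch(make_rec(x, sfreq), method = "fir", transition_hz = 0.5)
  expect_equal(attr(out, "filter_length"), 1651)  # 3.3 * 250 / 0.5, odd
})

test_that("bridged pairs are detected by electrical distance", {
  sfreq <- 250
  set.seed(1)
  n <- 3 * sfreq
  base <- matrix(rnorm(n * 8, sd = 10), n, 8)
  # duplicate channel 3 into channel 7 with 0.01 uV noise
  base[, 7] <- base[, 3] + rnorm(n, sd = 0.01)
  rec <- make_rec(base, sfreq)
  hit <- detect_bridges(rec)
  expect_equal(nrow(hit), 1L)
  expect_setequal(c(hit$ch1, hit$ch2), c("E3", "E7"))

  clean <- make_rec(matrix(rnorm(n * 8, sd = 10), n, 8), sfreq)
  expect_equal(nrow(detect_bridges(clean)), 0L)
})

test_that("exactly the near-identical pair is flagged among 3 channels", {
  sfreq <- 250
  set.seed(2)
  n <- 3 * sfreq
  a <- rnorm(n, sd = 10)
  x <- cbind(a, a + rnorm(n, sd = 0.02), rnorm(n, sd = 10))
  rec <- make_rec(x, sfreq, n_ch = 3)
  # oracle: exhaustive pairwise variance ranking
  ed <- c(var(x[, 1] - x[, 2]), var(x[, 1] - x[, 3]), var(x[, 2] - x[, 3]))
  expect_equal(which.min(ed), 1L)
  hit <- detect_bridges(rec)
  expect_equal(nrow(hit), 1L)
  expect_setequal(c(hit$ch1, hit$ch2), c("E1", "E2"))
})

test_that("virtual midpoint sits on the sphere, equidistant from parents", {
  lay <- tiny_layout(16)
  # symmetric pair about x = 0
  pos <- lay$positions
  pos[1, ] <- c(0.6, 0.64, 0.48); pos[1, ] <- pos[1, ] / sqrt(sum(pos[1, ]^2))
  pos[2, ] <- c(-pos[1, 1], pos[1, 2], pos[1, 3])
  lay2 <- channel_layout(lay$names, pos)
  out <- virtual_midpoint(lay2, c("E1", "E2"))
  mid <- out$positions[nrow(out$positions), ]
  expect_equal(unname(mid[1]), 0, tolerance = 1e-12)
  expect_equal(sum(mid^2), 1, tolerance = 1e-12)
  expect_setequal(out$bads, c("E1", "E2"))
  # arbitrary pair: unit norm and equal angular distance to both parents
  out2 <- virtual_midpoint(lay, c("E3", "E9"))
  mid2 <- out2$positions[nrow(out2$positions), ]
  expect_equal(sum(mid2^2), 1, tolerance = 1e-12)
  a1 <- acos(sum(mid2 * lay$positions["E3", ]))
  a2 <- acos(sum(mid2 * lay$positions["E9", ]))
  expect_equal(a1, a2, tolerance = 1e-9)
  # antipodal pair has no defined midpoint
  pos[2, ] <- -pos[1, ]
  lay3 <- channel_layout(lay$names, pos)
  expect_error(virtual_midpoint(lay3, c("E1", "E2")), class = "msnf_layout")
})

test_that("spherical spline reproduces constants and smooth fields", {
  lay <- default_layout(62)
  lay_bad <- channel_layout(lay$names, lay$positions, bads = "Cz")
  # constant topography
  rec <- eeg_recording(matrix(3.7, 5, 62), 100, lay_bad)
  out <- interpolate_bads(rec)
  expect_equal(out$data[, "Cz"], rep(3.7, 5), tolerance = 1e-6)
  # weights of the interpolation operator sum to 1 (constants reproduced)
  W <- interpolation_matrix(lay_bad)
  expect_equal(unname(rowSums(W)), rep(1, nrow(W)), tolerance = 1e-6)
  # leave-one-out on a smooth dipolar field
  field <- lay$positions %*% c(0.5, 1, 0.25)
  rng <- diff(range(field))
  for (ch in c("Cz", "F3", "O2")) {
    lb <- channel_layout(lay$names, lay$positions, bads = ch)
    r <- eeg_recording(matrix(field, 1), 100, lb)
    got <- interpolate_bads(r)$data[1, ch]
    expect_lt(abs(got - field[lay$names == ch, 1]), 0.05 * rng)
  }
  # idempotence: good channels untouched, re-running changes nothing
  rec2 <- eeg_recording(matrix(rnorm(62 * 10), 10, 62), 100, lay_bad)
  once <- interpolate_bads(rec2, bads = "Cz")
  twice <- interpolate_bads(once, bads = "Cz")
  expect_equal(once$data, twice$data, tolerance = 1e-12)
  good <- setdiff(lay$names, "Cz")
  expect_identical(once$data[, good], rec2$data[, good])
  all_bad <- channel_layout(lay$names, lay$positions, bads = lay$names)
  expect_error(interpolate_bads(eeg_recording(matrix(0, 2, 62), 100, all_bad)),
               class = "msnf_interp")
})

test_that("stored ICA solutions reconstruct from retained components", {
  set.seed(3)
  n_ch <- 8; n_comp <- 8; n <- 1000
  A <- qr.Q(qr(matrix(rnorm(n_ch * n_comp), n_ch)))  # orthonormal mixing
  U <- t(A)
  t_ax <- (0:(n - 1)) / 250
  S <- matrix(rnorm(n * n_comp, sd = 0.5), n, n_comp)
  S[, 4] <- 20 * sin(2 * pi * 7 * t_ax)  # injected sinusoidal artifact
  X <- S %*% t(A)
  rec <- eeg_recording(X, 250)
  # no rejection: identity
  same <- apply_ica(rec, ica_solution(A, U, integer()))
  expect_equal(unname(same$data), X, tolerance = 1e-9)
  # rejecting the artifact component removes >= 99% of its power
  cleaned <- apply_ica(rec, ica_solution(A, U, 4L))
  art <- S[, 4] %o% A[, 4]
  expect_lt(sum((cleaned$data - (X - art))^2), 1e-12 * sum(X^2))
  expect_lt(sum((U[4, ] %*% t(cleaned$data))^2) / sum(S[, 4]^2), 0.01)
  # rejecting everything zeroes the modeled subspace
  none <- apply_ica(rec, ica_solution(A, U, 1:8))
  expect_lt(max(abs(none$data)), 1e-9)
  # inconsistent matrices are rejected
  expect_error(ica_solution(A, U * 1.01), class = "msnf_ica")
})

test_that("epoching yields the documented window counts and samples", {
  sfreq <- 250
  rec <- make_rec(seq_len(180 * sfreq), sfreq)
  eps <- epoch_windows(rec, 3, 0.5)
  expect_length(eps, 71)  # floor((180 - 3) / 2.5) + 1
  expect_true(all(vapply(eps, function(e) nrow(e$data), numeric(1)) == 750))
  # windows reconstruct the source samples at their offsets
  for (i in c(1, 36, 71)) {
    onset <- attr(eps[[i]], "onset_s")
    src <- rec$data[(onset * sfreq + 1):(onset * sfreq + 750), 1]
    expect_identical(eps[[i]]$data[, 1], src)
  }
  expect_length(epoch_windows(make_rec(1:100, sfreq), 3, 0.5), 0)
  expect_length(epoch_windows(rec, 3, 0), 60)
  expect_error(epoch_windows(rec, 3, 3), class = "msnf_epoch")
})

test_that("epochs overlapping annotated bad segments are dropped", {
  sfreq <- 100
  ann <- tibble::tibble(onset_s = 4, duration_s = 1, label = "bad")
  rec <- eeg_recording(matrix(rnorm(20 * sfreq * 2), ncol = 2), sfreq,
                       annotations = ann)
  eps_all <- suppressMessages(epoch_windows(rec, 3, 0.5, drop_annotated = FALSE))
  eps <- suppressMessages(epoch_windows(rec, 3, 0.5))
  expect_lt(length(eps), length(eps_all))
  onsets <- vapply(eps, attr, numeric(1), which = "onset_s")
  expect_false(any(onsets < 5 & onsets + 3 > 4))
})

test_that("average reference removes the channel mean of every sample", {
  rec <- make_rec(matrix(rnorm(500) + 3, 100, 5), 100, n_ch = 5)
  out <- average_reference(rec)
  expect_lt(max(abs(rowMeans(out$data))), 1e-12)
})
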