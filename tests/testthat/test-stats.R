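test_that("paired Cohen's d matches its definition", {
  x <- c(3, 5, 2, 8, 6)
  expect_equal(paired_cohens_d(x, x), 0)
  # pure shift: d = shift / common SD
  expect_equal(paired_cohens_d(x, x + 2), 2 / sd(x), tolerance = 1e-12)
  set.seed(1)
  a <- rnorm(12); b <- rnorm(12, 0.4)
  expect_equal(paired_cohens_d(a, b), mean(b - a) / ((sd(a) + sd(b)) / 2),
               tolerance = 1e-12)
  expect_equal(paired_cohens_d(a, b, variant = "d_z"),
               mean(b - a) / sd(b - a), tolerance = 1e-12)
  expect_error(paired_cohens_d(1:3, 1:4), class = "msnf_stats")
})

test_that("BCa interval equals a step-by-step textbook computation at n=5", {
  dat <- c(1.2, 3.4, 2.2, 5.9, 4.1)
  n_boot <- 2000
  got <- bca_ci(dat, mean, n_boot = n_boot, seed = 99)
  # independent re-computation from the definitions, sharing the resamples
  boots <- withr::with_seed(99L, {
    idx <- matrix(sample.int(5, 5 * n_boot, replace = TRUE), 5, n_boot)
    apply(idx, 2, function(i) mean(dat[i]))
  })
  z0 <- qnorm(sum(boots < mean(dat)) / n_boot)
  jack <- vapply(1:5, function(i) mean(dat[-i]), numeric(1))
  u <- mean(jack) - jack
  a <- sum(u^3) / (6 * sum(u^2)^1.5)
  alphas <- pnorm(z0 + (z0 + qnorm(c(0.025, 0.975))) / (1 - a * (z0 + qnorm(c(0.025, 0.975)))))
  expected <- quantile(boots, alphas, names = FALSE, type = 6)
  expect_equal(as.numeric(got), expected, tolerance = 1e-12)
  expect_equal(attr(got, "method"), "bca")
})

test_that("BCa endpoints agree with boot::boot.ci within Monte-Carlo error", {
  skip_if_not_installed("boot")
  set.seed(2)
  dat <- rnorm(25)
  ours <- bca_ci(dat, mean, n_boot = 4000, seed = 7)
  bt <- boot::boot(dat, function(d, i) mean(d[i]), R = 4000)
  ref <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  # independent resamples: allow Monte-Carlo error on the tail quantiles
  expect_lt(abs(ours[["low"]] - ref[1]), 0.04)
  expect_lt(abs(ours[["high"]] - ref[2]), 0.04)
})

test_that("BCa is equivariant under monotone linear transforms", {
  set.seed(3)
  dat <- rexp(15)
  ci <- bca_ci(dat, mean, n_boot = 1000, seed = 5)
  ci2 <- bca_ci(3 * dat + 1, mean, n_boot = 1000, seed = 5)
  expect_equal(as.numeric(ci2), 3 * as.numeric(ci) + 1, tolerance = 1e-10)
})

test_that("degenerate bootstrap distributions fall back to percentile", {
  # bootstrap minima are never below the observed minimum: infinite bias
  dat <- c(1, 2, 3, 4, 5)
  expect_warning(ci <- bca_ci(dat, min, n_boot = 50, seed = 1),
                 "percentile")
  expect_equal(attr(ci, "method"), "percentile")
})

test_that("permutation test matches exhaustive enumeration at n=3", {
  x <- c(1.0, 2.0, 3.0)
  y <- c(2.5, 2.1, 4.4)
  res <- permutation_ttest(x, y, n_perm = 5000, sides = "two")
  expect_true(res$exhaustive)
  expect_equal(res$n_perm_used, 8L)
  # oracle: enumerate all 2^3 sign assignments directly
  d <- y - x
  stats <- apply(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)), 1, function(s) {
    a <- ifelse(s > 0, x, y); b <- ifelse(s > 0, y, x)
    mean(b - a) / ((sd(a) + sd(b)) / 2)
  })
  expected_p <- mean(abs(stats) >= abs(res$observed) - 1e-12)
  expect_equal(res$p, expected_p, tolerance = 1e-12)
  # all-zero differences: nothing is ever more extreme than everything
  expect_equal(permutation_ttest(x, x, n_perm = 100)$p, 1)
})

test_that("permutation p is invariant to condition relabeling (two-sided)", {
  set.seed(4)
  x <- rnorm(9); y <- rnorm(9, 0.5)
  p1 <- permutation_ttest(x, y, n_perm = 600, sides = "two")$p
  p2 <- permutation_ttest(y, x, n_perm = 600, sides = "two")$p
  expect_equal(p1, p2, tolerance = 1e-12)
  # one-sided reflects
  pg <- permutation_ttest(x, y, n_perm = 600, sides = "greater")$p
  pl <- permutation_ttest(y, x, n_perm = 600, sides = "less")$p
  expect_equal(pg, pl, tolerance = 1e-12)
})

test_that("Monte-Carlo and exhaustive permutation modes agree in expectation", {
  set.seed(5)
  x <- rnorm(12); y <- rnorm(12, 0.4)
  exact <- permutation_ttest(x, y, n_perm = 4096)  # 2^12 -> exhaustive
  expect_true(exact$exhaustive)
  mc <- permutation_ttest(x, y, n_perm = 2000, seed = 6)
  expect_false(mc$exhaustive)
  se <- sqrt(exact$p * (1 - exact$p) / 2000)
  expect_lt(abs(mc$p - exact$p), 3 * se + 1 / 2000)
})

test_that("rm_corr equals the subject-factor ANCOVA decomposition", {
  # perfect within-subject line: r = 1
  d <- tibble::tibble(
    s = rep(1:4, each = 5), x = rep(1:5, 4),
    y = rep(1:5, 4) + rep(c(0, 10, -3, 5), each = 5)
  )
  expect_equal(rm_corr(d, s, x, y)$r, 1, tolerance = 1e-12)
  # noisy data: cross-check r, df, p against aov sequential sums of squares
  set.seed(7)
  d2 <- tibble::tibble(
    s = factor(rep(1:6, each = 8)),
    x = rnorm(48),
    y = rnorm(48, sd = 2) + rep(rnorm(6, sd = 3), each = 8)
  )
  d2$y <- d2$y + 0.7 * d2$x
  got <- rm_corr(d2, s, x, y)
  av <- summary(stats::aov(y ~ s + x, data = d2))[[1]]
  ss_x <- av["x", "Sum Sq"]; ss_err <- av["Residuals", "Sum Sq"]
  slope <- coef(lm(y ~ s + x, data = d2))[["x"]]
  expect_equal(got$r, sign(slope) * sqrt(ss_x / (ss_x + ss_err)),
               tolerance = 1e-10)
  expect_equal(got$df, 48 - 6 - 1)
  expect_equal(got$p, av["x", "Pr(>F)"], tolerance = 1e-10)
})

test_that("rm_corr is near zero when y is unrelated to x within subjects", {
  set.seed(8)
  rs <- replicate(40, {
    d <- tibble::tibble(s = rep(1:5, each = 6), x = rnorm(30), y = rnorm(30))
    rm_corr(d, s, x, y)$r
  })
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(40))
})

test_that("noncentral-t power matches its definition and limits", {
  # no effect: power equals alpha
  expect_equal(ttest_power(0, 15), 0.05, tolerance = 1e-9)
  expect_equal(ttest_power(0, 15, sides = "two"), 0.05, tolerance = 1e-9)
  # large-n limit: normal approximation power Phi(d*sqrt(n) - z_{1-alpha})
  n <- 5000; d <- 0.05
  approx <- pnorm(d * sqrt(n) - qnorm(0.95))
  expect_equal(ttest_power(d, n), approx, tolerance = 1e-3)
  # strictly increasing in n and |d|
  pw_n <- vapply(c(5, 10, 20, 40, 80), function(n) ttest_power(0.4, n), numeric(1))
  expect_true(all(diff(pw_n) > 0))
  pw_d <- vapply(c(0.1, 0.3, 0.5, 0.9), function(d) ttest_power(d, 12), numeric(1))
  expect_true(all(diff(pw_d) > 0))
})

test_that("required_n inverts ttest_power under both conventions", {
  # huge effects need only the minimum df
  expect_equal(required_n(50), 2L)
  # ceiling convention: smallest n whose exact power clears the target
  for (d in c(0.3, 0.56, 0.9)) {
    n <- required_n(d, 0.80, 0.05, "one")
    expect_gte(ttest_power(d, n), 0.80)
    expect_lt(ttest_power(d, n - 1), 0.80)
  }
  # nearest convention rounds the continuous root
  n56 <- required_n(0.56, rounding = "nearest")
  expect_equal(n56, 21L)
  expect_lte(abs(ttest_power(0.56, n56) - 0.80), 0.01)
  # non-increasing in |d|
  ns <- vapply(c(0.2, 0.4, 0.6, 1), function(d) required_n(d), integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("paired_estimation bundles d, BCa CI, and permutation p", {
  set.seed(9)
  dat <- tibble::tibble(rs0 = rnorm(14, 20, 4), tr9 = rnorm(14, 23, 4))
  est <- paired_estimation(dat, rs0, tr9, n_boot = 800, n_perm = 800, seed = 10)
  expect_s3_class(est, "msnf_estimation")
  expect_equal(est$d, paired_cohens_d(dat$rs0, dat$tr9), tolerance = 1e-12)
  expect_true(est$ci_low <= est$d && est$d <= est$ci_high)
  expect_true(est$p > 0 && est$p <= 1)
  out <- tidy(est)
  expect_named(out, c("d", "ci_low", "ci_high", "p", "n", "n_boot", "n_perm",
                      "sides", "variant"))
  expect_equal(out$n, 14)
})
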