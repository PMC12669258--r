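#' Paired Cohen's d
#'
#' Standardized paired effect size. The default `"average"` variant divides
#' the mean paired difference by the average of the two condition standard
#' deviations, the convention of estimation-statistics software for paired
#' designs; `"d_z"` divides by the standard deviation of the differences.
#'
#' @param x,y Aligned numeric vectors (condition 1 and condition 2); pairs
#'   with a missing value are dropped listwise (with a message).
#' @param variant `"average"` (default) or `"d_z"`.
#' @return The effect size (positive when `y` exceeds `x`).
#' @export
paired_cohens_d <- function(x, y, variant = c("average", "d_z")) {
  variant <- match.arg(variant)
  p <- complete_pairs(x, y)
  d <- p$y - p$x
  denom <- switch(variant,
    average = (sd(p$x) + sd(p$y)) / 2,
    d_z = sd(d)
  )
  if (!is.finite(denom) || denom == 0) {
    if (all(d == 0)) return(0)
    stop_msnf("zero variance: effect size undefined", "stats")
  }
  mean(d) / denom
}

complete_pairs <- function(x, y) {
  if (length(x) != length(y))
    stop_msnf("paired samples must have equal length", "stats")
  ok <- stats::complete.cases(x, y)
  if (!all(ok))
    rlang::inform(sprintf("dropping %d incomplete pair(s)", sum(!ok)))
  if (sum(ok) < 2L) stop_msnf("need at least 2 complete pairs", "stats")
  list(x = x[ok], y = y[ok])
}

#' Bias-corrected and accelerated bootstrap confidence interval
#'
#' Nonparametric BCa interval for `statistic(data)`. Rows (or elements) of
#' `data` are resampled with replacement `n_boot` times; the bias-correction
#' constant is `z0 = qnorm(#[theta* < theta_hat] / n_boot)` and the
#' acceleration is the jackknife skewness
#' `a = sum(u^3) / (6 sum(u^2)^{3/2})` with `u = mean(theta_jack) -
#' theta_jack`. When the bias constant is infinite (all bootstrap replicates
#' on one side of the estimate) the plain percentile interval is returned
#' with a warning.
#'
#' @param data Numeric vector, matrix, or data frame (rows are the
#'   resampling unit).
#' @param statistic Function of one argument (a resampled `data`) returning a
#'   scalar.
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed for the resampling.
#' @return Named numeric vector `c(low, high)` with attributes `z0`, `a`,
#'   `estimate`, and `method` (`"bca"` or `"percentile"`).
#' @export
bca_ci <- function(data, statistic, n_boot = 5000, level = 0.95, seed = NULL) {
  take <- if (is.null(dim(data))) function(i) data[i]
          else function(i) data[i, , drop = FALSE]
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  if (n < 2L) stop_msnf("need at least 2 observations", "stats")
  t0 <- statistic(data)
  boots <- with_seed_if(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    vapply(seq_len(n_boot), function(b) statistic(take(idx[, b])), numeric(1))
  })
  alpha <- (1 - level) / 2
  prop <- sum(boots < t0) / n_boot
  if (prop == 0 || prop == 1) {
    rlang::warn("infinite BCa bias constant; falling back to percentile interval")
    ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 6)
    return(structure(c(low = ci[1], high = ci[2]), z0 = NA_real_, a = NA_real_,
                     estimate = t0, method = "percentile"))
  }
  z0 <- qnorm(prop)
  jack <- vapply(seq_len(n), function(i) statistic(take(-i)), numeric(1))
  u <- mean(jack) - jack
  denom <- sum(u^2)^1.5
  a <- if (denom > 0) sum(u^3) / (6 * denom) else 0
  zq <- qnorm(c(alpha, 1 - alpha))
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  ci <- stats::quantile(boots, adj, names = FALSE, type = 6)
  structure(c(low = ci[1], high = ci[2]), z0 = z0, a = a, estimate = t0,
            method = "bca")
}

#' Sign-flip permutation test for paired data
#'
#' Permutes the condition labels within pairs (equivalently, flips the signs
#' of the paired differences) and compares the observed paired effect size to
#' its permutation distribution. When the number of exhaustive sign patterns
#' `2^n` does not exceed `n_perm`, all patterns are enumerated and the exact
#' p-value is returned (the identity pattern makes p strictly positive);
#' otherwise `n_perm` random flips are drawn and the add-one-corrected
#' Monte-Carlo p-value `(1 + #[extreme]) / (1 + n_perm)` is returned.
#'
#' @inheritParams paired_cohens_d
#' @param n_perm Number of random reshuffles (default 5000).
#' @param sides `"two"` (default), `"greater"` (y > x), or `"less"`.
#' @param statistic `"d"` (paired Cohen's d, default), `"d_z"`, or
#'   `"mean_diff"`.
#' @param seed RNG seed for Monte-Carlo mode.
#' @return A list with `p`, `observed`, `n_perm_used`, `exhaustive`.
#' @export
permutation_ttest <- function(x, y, n_perm = 5000,
                              sides = c("two", "greater", "less"),
                              statistic = c("d", "d_z", "mean_diff"),
                              seed = NULL) {
  sides <- match.arg(sides)
  statistic <- match.arg(statistic)
  p <- complete_pairs(x, y)
  n <- length(p$x)
  stat_fun <- switch(statistic,
    d = function(a, b) paired_stat_d(a, b),
    d_z = function(a, b) {
      d <- b - a
      s <- sd(d)
      if (s == 0) 0 else mean(d) / s
    },
    mean_diff = function(a, b) mean(b - a)
  )
  obs <- stat_fun(p$x, p$y)
  exhaustive <- 2^n <= n_perm
  flips <- if (exhaustive) {
    m <- matrix(FALSE, n, 2^n)
    for (i in seq_len(n))
      m[i, ] <- rep(rep(c(FALSE, TRUE), each = 2^(i - 1)), length.out = 2^n)
    m
  } else {
    with_seed_if(seed, matrix(sample(c(FALSE, TRUE), n * n_perm, replace = TRUE),
                              n, n_perm))
  }
  stats_perm <- perm_stats(p$x, p$y, flips, statistic)
  extreme <- switch(sides,
    two = abs(stats_perm) >= abs(obs) - 1e-12,
    greater = stats_perm >= obs - 1e-12,
    less = stats_perm <= obs + 1e-12
  )
  pval <- if (exhaustive) mean(extreme)
          else (1 + sum(extreme)) / (1 + ncol(flips))
  list(p = pval, observed = obs, n_perm_used = ncol(flips),
       exhaustive = exhaustive)
}

paired_stat_d <- function(a, b) {
  d <- b - a
  denom <- (sd(a) + sd(b)) / 2
  if (denom == 0) return(0)
  mean(d) / denom
}

# vectorized permutation statistics over a n x P logical flip matrix
# (TRUE = swap the pair's condition labels)
perm_stats <- function(x, y, flips, statistic) {
  n <- nrow(flips)
  P <- ncol(flips)
  X <- matrix(x, n, P)
  Y <- matrix(y, n, P)
  Xs <- ifelse(flips, Y, X)
  Ys <- ifelse(flips, X, Y)
  md <- colMeans(Ys - Xs)
  if (statistic == "mean_diff") return(md)
  col_sd <- function(M) {
    mu <- colMeans(M)
    sqrt(pmax(colSums(M^2) - n * mu^2, 0) / (n - 1))
  }
  denom <- switch(statistic,
    d = (col_sd(Xs) + col_sd(Ys)) / 2,
    d_z = col_sd(Ys - Xs)
  )
  out <- ifelse(denom == 0, 0, md / denom)
  out
}

#' Paired estimation summary
#'
#' The estimation-statistics bundle for one paired contrast: the paired
#' Cohen's d, its 95% BCa bootstrap confidence interval, and the sign-flip
#' permutation p-value. Data-frame-first: supply a tibble and two condition
#' columns.
#'
#' @param data A data frame with one row per subject.
#' @param cond1,cond2 Column names (tidy-eval) of the two conditions.
#' @param n_boot,n_perm Resampling sizes (defaults 5000 each).
#' @param sides Sidedness of the permutation test (default `"two"`).
#' @param variant Effect-size variant (see [paired_cohens_d()]).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed.
#' @return An object of class `msnf_estimation`; `tidy()`/`glance()` return
#'   a one-row tibble with `d`, `ci_low`, `ci_high`, `p`, `n`, `n_boot`,
#'   `n_perm`, `sides`.
#' @export
paired_estimation <- function(data, cond1, cond2, n_boot = 5000, n_perm = 5000,
                              sides = "two", variant = "average", level = 0.95,
                              seed = NULL) {
  x <- dplyr::pull(data, {{ cond1 }})
  y <- dplyr::pull(data, {{ cond2 }})
  p <- complete_pairs(x, y)
  d <- paired_cohens_d(p$x, p$y, variant = variant)
  ci <- bca_ci(cbind(p$x, p$y),
               function(m) paired_cohens_d(m[, 1], m[, 2], variant = variant),
               n_boot = n_boot, level = level, seed = seed)
  perm <- permutation_ttest(p$x, p$y, n_perm = n_perm, sides = sides,
                            statistic = if (variant == "average") "d" else "d_z",
                            seed = seed)
  structure(
    list(d = d, ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
         p = perm$p, n = length(p$x), n_boot = n_boot,
         n_perm = perm$n_perm_used, sides = sides, variant = variant,
         level = level, seed = seed, ci_method = attr(ci, "method"),
         data = tibble::tibble(x = p$x, y = p$y)),
    class = "msnf_estimation"
  )
}

#' @export
print.msnf_estimation <- function(x, ...) {
  cat(sprintf(
    "<msnf_estimation> paired d = %.3f, %d%% CI [%.3f, %.3f], p = %.4g (%s-sided, n = %d)\n",
    x$d, round(100 * x$level), x$ci_low, x$ci_high, x$p, x$sides, x$n))
  invisible(x)
}

#' @export
tidy.msnf_estimation <- function(x, ...) {
  tibble::tibble(d = x$d, ci_low = x$ci_low, ci_high = x$ci_high, p = x$p,
                 n = x$n, n_boot = x$n_boot, n_perm = x$n_perm,
                 sides = x$sides, variant = x$variant)
}

#' @export
glance.msnf_estimation <- tidy.msnf_estimation

#' Repeated-measures correlation
#'
#' The common within-subject association between two repeated measures,
#' estimated by analysis of covariance with subject as a factor. After
#' centering both variables within subject, the coefficient is the Pearson
#' correlation of the centered variables with sign taken from the common
#' slope; the degrees of freedom are `n_obs - n_subjects - 1` and the p-value
#' comes from the t distribution on those df. (The centered-correlation form
#' is algebraically identical to the ANCOVA sums-of-squares definition.)
#'
#' @param data A data frame in long format.
#' @param subject,x,y Columns (tidy-eval): subject identifier and the two
#'   measures.
#' @return A one-row tibble of class `msnf_rmcorr`: `r`, `df`, `p`,
#'   `n_obs`, `n_subjects`.
#' @export
rm_corr <- function(data, subject, x, y) {
  s <- as.factor(dplyr::pull(data, {{ subject }}))
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- stats::complete.cases(s, xv, yv)
  s <- droplevels(s[ok]); xv <- xv[ok]; yv <- yv[ok]
  n_obs <- length(xv)
  n_sub <- nlevels(s)
  df <- n_obs - n_sub - 1L
  if (df < 1L) stop_msnf("not enough observations for rm_corr", "stats")
  xc <- xv - stats::ave(xv, s)
  yc <- yv - stats::ave(yv, s)
  if (sd(xc) == 0 || sd(yc) == 0)
    stop_msnf("a variable is constant within subjects", "stats")
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  out <- tibble::tibble(r = r, df = df, p = p, n_obs = n_obs,
                        n_subjects = n_sub)
  class(out) <- c("msnf_rmcorr", class(out))
  out
}

#' Power of a one-sample / paired t test
#'
#' Exact power from the noncentral t distribution: with standardized effect
#' `d` and `n` pairs, the noncentrality parameter is `d * sqrt(n)` and
#' `power = P(T'_{n-1, ncp} > t_{1-alpha, n-1})` for a one-sided test (the
#' two-sided version adds the opposite tail at `alpha/2`).
#'
#' @param d Standardized effect size.
#' @param n Sample size (pairs); may be non-integer when used as a continuous
#'   solve target.
#' @param alpha Significance level (default 0.05).
#' @param sides `"one"` (default) or `"two"`.
#' @return Power in `(0, 1)`.
#' @export
ttest_power <- function(d, n, alpha = 0.05, sides = c("one", "two")) {
  sides <- match.arg(sides)
  stopifnot(n > 1, alpha > 0, alpha < 1)
  ncp <- d * sqrt(n)
  df <- n - 1
  if (sides == "one") {
    1 - pt(qt(1 - alpha, df), df, ncp = ncp)
  } else {
    tc <- qt(1 - alpha / 2, df)
    (1 - pt(tc, df, ncp = ncp)) + pt(-tc, df, ncp = ncp)
  }
}

#' Required sample size for a target power
#'
#' Smallest sample size at which [ttest_power()] reaches `power`. Two
#' integer conventions are offered: `"ceiling"` (default) returns the
#' smallest integer n whose exact power meets the target — the conservative
#' planning convention; `"nearest"` solves the continuous noncentral-t power
#' equation for n and rounds to the nearest integer — the convention of
#' common power-analysis software reports, whose rounded n can fall one
#' participant short of the target at full precision.
#'
#' @inheritParams ttest_power
#' @param power Target power (default 0.80).
#' @param rounding `"ceiling"` or `"nearest"`.
#' @param n_max Search cap (default 1e6).
#' @return Integer sample size (>= 2).
#' @export
required_n <- function(d, power = 0.80, alpha = 0.05,
                       sides = c("one", "two"),
                       rounding = c("ceiling", "nearest"), n_max = 1e6) {
  sides <- match.arg(sides)
  rounding <- match.arg(rounding)
  stopifnot(d != 0, power > 0, power < 1)
  d <- abs(d)
  if (ttest_power(d, 2, alpha, sides) >= power) return(2L)
  if (rounding == "ceiling") {
    lo <- 2; hi <- 4
    while (ttest_power(d, hi, alpha, sides) < power) {
      lo <- hi; hi <- hi * 2
      if (hi > n_max) stop_msnf("required n exceeds n_max", "stats")
    }
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2
      if (ttest_power(d, mid, alpha, sides) >= power) hi <- mid else lo <- mid
    }
    as.integer(hi)
  } else {
    hi <- 4
    while (ttest_power(d, hi, alpha, sides) < power) {
      hi <- hi * 2
      if (hi > n_max) stop_msnf("required n exceeds n_max", "stats")
    }
    root <- stats::uniroot(function(n) ttest_power(d, n, alpha, sides) - power,
                           lower = 2, upper = hi, tol = 1e-9)$root
    max(2L, as.integer(round(root)))
  }
}
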