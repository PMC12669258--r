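#' Markov microstate models
#'
#' The synthetic generator models the microstate label sequence as a
#' first-order Markov chain over K states. Each state k dwells for a
#' geometrically distributed number of samples with mean
#' `1 / (1 - transition_matrix[k, k])`, so at sampling rate `f` the expected
#' dwell time is `1 / ((1 - p_kk) * f)` seconds. The chain's stationary
#' distribution is the analytic ground truth for time coverage.
#'
#' @param transition_matrix K x K row-stochastic matrix (rows sum to 1 within
#'   1e-12, entries non-negative).
#' @param gfp_mean Mean global field power amplitude of a segment (microvolts,
#'   default 15).
#' @param gfp_cv Coefficient of variation of per-segment amplitude (default 0.3).
#' @param noise_sigma Per-channel Gaussian sensor noise SD (microvolts,
#'   default 7.5, i.e. a 4:1 template-to-noise power ratio at the default
#'   amplitude).
#' @param seed Optional RNG seed carried with the model.
#' @return An object of class `msnf_markov_model`.
#' @export
markov_model <- function(transition_matrix, gfp_mean = 15, gfp_cv = 0.3,
                         noise_sigma = 7.5, seed = NULL) {
  P <- as.matrix(transition_matrix)
  if (nrow(P) != ncol(P)) stop_msnf("transition matrix must be square", "markov")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12))
    stop_msnf("transition matrix must be row-stochastic (rows sum to 1)", "markov")
  structure(
    list(n_states = nrow(P), transition_matrix = P, gfp_mean = gfp_mean,
         gfp_cv = gfp_cv, noise_sigma = noise_sigma, seed = seed),
    class = "msnf_markov_model"
  )
}

#' @export
print.msnf_markov_model <- function(x, ...) {
  cat(sprintf("<msnf_markov_model> K=%d, gfp %.3g uV (cv %.2f), noise %.3g uV\n",
              x$n_states, x$gfp_mean, x$gfp_cv, x$noise_sigma))
  invisible(x)
}

#' Build a transition matrix from mean dwell times
#'
#' Self-transition probabilities are set to `1 - 1/(dwell_s * sampling_rate)`
#' and the remaining mass is spread over the other states in proportion to
#' `pi_weights` (uniform by default).
#'
#' @param dwell_s Per-state expected dwell times in seconds.
#' @param sampling_rate Rendering rate in Hz.
#' @param pi_weights Optional relative weights steering off-diagonal mass.
#' @return A row-stochastic matrix.
#' @export
transition_from_dwell <- function(dwell_s, sampling_rate, pi_weights = NULL) {
  k <- length(dwell_s)
  stopifnot(k >= 1, all(dwell_s * sampling_rate >= 1))
  w <- pi_weights %||% rep(1, k)
  P <- matrix(0, k, k)
  for (i in seq_len(k)) {
    p_leave <- 1 / (dwell_s[i] * sampling_rate)
    off <- w
    off[i] <- 0
    if (k > 1L) P[i, ] <- p_leave * off / sum(off)
    P[i, i] <- 1 - p_leave
  }
  P
}

#' Expected dwell times of a model at a sampling rate
#' @param model An `msnf_markov_model`.
#' @param sampling_rate Hz.
#' @return Numeric vector of seconds.
#' @export
expected_dwell_s <- function(model, sampling_rate) {
  p_stay <- diag(model$transition_matrix)
  1 / ((1 - p_stay) * sampling_rate)
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of the row-stochastic matrix for eigenvalue 1, normalized
#' to sum to one. This is the analytic ground truth against which empirical
#' time coverage of generated label sequences is checked.
#'
#' @param P Row-stochastic matrix (or an `msnf_markov_model`).
#' @return Numeric probability vector.
#' @export
stationary_distribution <- function(P) {
  if (inherits(P, "msnf_markov_model")) P <- P$transition_matrix
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Sample a microstate label sequence from a Markov model
#'
#' @param model An `msnf_markov_model` (or a row-stochastic matrix).
#' @param n_samples Number of samples to draw.
#' @param sampling_rate Sampling rate attached to the label sequence (Hz).
#' @param seed RNG seed (falls back to the model's own seed).
#' @param init Initial state: an index, or `"stationary"` (default) to draw
#'   it from the stationary distribution.
#' @return An [ms_labels()] sequence of length `n_samples`.
#' @export
sample_labels <- function(model, n_samples, sampling_rate, seed = NULL,
                          init = "stationary") {
  if (!inherits(model, "msnf_markov_model")) model <- markov_model(model)
  if (n_samples <= 0) stop_msnf("n_samples must be positive", "markov")
  P <- model$transition_matrix
  k <- nrow(P)
  cum <- t(apply(P, 1, cumsum))
  seed <- seed %||% model$seed
  lab <- with_seed_if(seed, {
    u <- runif(n_samples)
    out <- integer(n_samples)
    s <- if (identical(init, "stationary")) {
      pi0 <- stationary_distribution(P)
      findInterval(u[1], cumsum(pi0)) + 1L
    } else as.integer(init)
    out[1] <- s
    for (t in seq_len(n_samples - 1L)) {
      s <- findInterval(u[t + 1L], cum[s, ]) + 1L
      if (s > k) s <- k  # guard against cumsum rounding at 1
      out[t + 1L] <- s
    }
    out
  })
  ms_labels(lab, sampling_rate, n_states = k)
}

#' Render a label sequence into synthetic EEG
#'
#' Each sample is the active state's template scaled by a per-segment
#' amplitude, plus white sensor noise:
#' `x(t) = s(t) * a(seg(t)) * sqrt(C) * map[L(t), ] + noise`.
#' Segment amplitudes are log-normal with mean `gfp_mean` and coefficient of
#' variation `gfp_cv`, constant within a segment; the `sqrt(C)` factor makes
#' the noiseless global field power of a sample equal to its segment
#' amplitude. With `polarity_flips` the sign `s` is drawn once per segment,
#' exercising the polarity invariance of absolute-correlation backfitting.
#'
#' @param labels An [ms_labels()] sequence (no unassigned samples).
#' @param templates An `msnf_templates`; `max(labels)` must not exceed its
#'   state count.
#' @param gfp_mean,gfp_cv,noise_sigma Amplitude and noise parameters
#'   (microvolts); defaults as in [markov_model()].
#' @param polarity_flips Draw a random sign per segment (default TRUE).
#' @param seed RNG seed.
#' @return An `eeg_recording` with the templates' layout.
#' @export
render_eeg <- function(labels, templates, gfp_mean = 15, gfp_cv = 0.3,
                       noise_sigma = 7.5, polarity_flips = TRUE, seed = NULL) {
  stopifnot(inherits(labels, "ms_labels"), inherits(templates, "msnf_templates"))
  lab <- labels$labels
  if (anyNA(lab)) stop_msnf("labels must be fully assigned for rendering", "render")
  if (max(lab) > n_states(templates))
    stop_msnf("label index outside template range", "render")
  C <- ncol(templates$maps)
  runs <- label_runs(lab)
  sdlog <- sqrt(log(1 + gfp_cv^2))
  meanlog <- log(gfp_mean) - sdlog^2 / 2
  data <- with_seed_if(seed, {
    amp <- rlnorm(nrow(runs), meanlog, sdlog)
    sgn <- if (polarity_flips) sample(c(-1, 1), nrow(runs), replace = TRUE)
           else rep(1, nrow(runs))
    a_t <- rep(amp * sgn, runs$length)
    x <- templates$maps[lab, , drop = FALSE] * (a_t * sqrt(C))
    if (noise_sigma > 0)
      x <- x + matrix(rnorm(length(lab) * C, sd = noise_sigma), length(lab), C)
    x
  })
  eeg_recording(data, labels$sampling_rate, templates$layout)
}

#' Feedback-responsive virtual subject
#'
#' Wraps a base Markov model with a coupling from the feedback value to the
#' target state's self-transition probability, emulating a participant who
#' learns to regulate the target microstate. After each feedback emission
#' `fb`, the self-transition probability of the target state moves in the
#' trained direction at a reward-gated rate,
#' `p + learning_gain * (1 + fb) / 2` for up-regulation (`-` for down),
#' clamped to `(p_floor, p_ceiling)`; the off-diagonal row mass is rescaled
#' to keep the row stochastic. Gating by gauge fill rather than signed
#' feedback reflects how feedback training works: a full gauge reinforces the
#' current strategy, an empty gauge stalls progress but does not reverse it.
#'
#' @param base_model An `msnf_markov_model`.
#' @param target_state Index (or name resolved later against templates) of
#'   the regulated state.
#' @param learning_gain Dimensionless coupling from feedback to probability
#'   (0 = sham/non-learner). The update is applied at every feedback emission
#'   (default cadence 250 ms), so gains of order 1e-4 produce gradual
#'   learning over a session; large gains saturate within the first block.
#' @param direction `"up"` or `"down"`.
#' @param p_floor,p_ceiling Clamp bounds for the self-transition probability.
#'   The ceiling of 0.98 caps the mean dwell at 50 samples, keeping the
#'   regulated chain in a physiologically sensible dwell range.
#' @return An object of class `msnf_subject`.
#' @export
responsive_subject <- function(base_model, target_state, learning_gain,
                               direction = c("up", "down"),
                               p_floor = 0.5, p_ceiling = 0.98) {
  direction <- match.arg(direction)
  stopifnot(inherits(base_model, "msnf_markov_model"),
            p_floor > 0, p_ceiling < 1, p_floor < p_ceiling)
  structure(
    list(base_model = base_model, target_state = target_state,
         learning_gain = learning_gain, direction = direction,
         p_floor = p_floor, p_ceiling = p_ceiling),
    class = "msnf_subject"
  )
}

# apply one feedback update to a transition matrix, returning the new matrix
update_transition <- function(P, target, delta, p_floor, p_ceiling) {
  p_old <- P[target, target]
  p_new <- min(max(p_old + delta, p_floor), p_ceiling)
  row <- P[target, ]
  off <- row
  off[target] <- 0
  s <- sum(off)
  if (s > 0) {
    row <- off * (1 - p_new) / s
  } else {
    row[] <- (1 - p_new) / (length(row) - 1)
  }
  row[target] <- p_new
  P[target, ] <- row
  P
}
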