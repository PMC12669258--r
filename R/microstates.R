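#' Microstate label sequences
#'
#' A per-sample assignment of EEG samples to template states, stored as
#' integers in `1..K` with `NA` for unassigned samples (zero-variance
#' samples that have no defined spatial correlation).
#'
#' @param labels Integer vector (NA = unassigned).
#' @param sampling_rate Hz.
#' @param n_states Number of states K the labels index into (default
#'   `max(labels)`).
#' @return An object of class `ms_labels`.
#' @export
ms_labels <- function(labels, sampling_rate, n_states = NULL) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop_msnf("labels must be non-empty", "labels")
  n_states <- as.integer(n_states %||% max(labels, na.rm = TRUE))
  if (any(labels < 1L | labels > n_states, na.rm = TRUE))
    stop_msnf("labels out of range", "labels")
  structure(list(labels = labels, sampling_rate = sampling_rate,
                 n_states = n_states),
            class = "ms_labels")
}

#' @export
print.ms_labels <- function(x, ...) {
  cat(sprintf("<ms_labels> %d samples @ %g Hz, K=%d (%d unassigned)\n",
              length(x$labels), x$sampling_rate, x$n_states,
              sum(is.na(x$labels))))
  invisible(x)
}

#' @export
length.ms_labels <- function(x) length(x$labels)

#' @export
as.integer.ms_labels <- function(x, ...) x$labels

#' Global field power
#'
#' GFP(t) is the spatial standard deviation of the average-referenced sample
#' across channels (population convention, divide by the channel count), the
#' standard instantaneous measure of EEG field strength.
#'
#' @param recording An `eeg_recording` (or a samples x channels matrix).
#' @return Non-negative numeric vector, one value per sample.
#' @export
gfp <- function(recording) {
  x <- if (inherits(recording, "eeg_recording")) recording$data else as.matrix(recording)
  xc <- x - rowMeans(x)
  sqrt(rowSums(xc^2) / ncol(x))
}

# spatial correlation of every sample with every template map:
# Pearson across channels of average-referenced vectors. Because maps are
# zero-mean unit-norm, corr(t, k) = <xc_t, map_k> / ||xc_t||.
spatial_corr <- function(x, templates) {
  xc <- x - rowMeans(x)
  nrm <- sqrt(rowSums(xc^2))
  a <- xc %*% t(templates$maps)
  list(corr = a / ifelse(nrm > 0, nrm, NA_real_), norm = nrm)
}

#' Backfit template maps to a recording
#'
#' Assigns each sample to the template with which it shares the highest
#' absolute spatial correlation (Pearson correlation across channels of the
#' average-referenced vectors). The absolute value makes the assignment
#' invariant to the polarity reversals inherent to oscillatory EEG topographies.
#' Ties go to the lowest state index; zero-variance samples are unassigned.
#'
#' @param recording An `eeg_recording`.
#' @param templates An `msnf_templates` with matching channels.
#' @return An [ms_labels()] sequence.
#' @export
backfit <- function(recording, templates) {
  check_channels(recording, templates)
  sc <- spatial_corr(recording$data, templates)
  ac <- abs(sc$corr)
  lab <- max.col(replace(ac, is.na(ac), -Inf), ties.method = "first")
  zero_var <- sc$norm <= 0
  lab[zero_var] <- NA_integer_
  if (any(zero_var))
    rlang::inform(sprintf("%d zero-variance sample(s) left unassigned",
                          sum(zero_var)))
  ms_labels(lab, recording$sfreq, n_states = n_states(templates))
}

check_channels <- function(recording, templates) {
  if (ncol(recording$data) != ncol(templates$maps))
    stop_msnf("recording and templates have different channel counts", "channels")
  rn <- colnames(recording$data)
  tn <- colnames(templates$maps)
  if (!is.null(rn) && !is.null(tn) && !identical(rn, tn))
    stop_msnf("recording and template channels are not aligned", "channels")
  invisible(TRUE)
}

#' Smooth a label sequence by windowed relabeling
#'
#' Iterative segmentation smoothing: each sample's fit criterion for state k
#' (its squared spatial correlation with map k) is boosted by
#' `factor * n_k / window_samples`, where `n_k` counts same-labeled neighbors
#' within a centered window of `window_samples` samples, and the sample is
#' relabeled to the best boosted state. Samples are updated in place in a
#' deterministic left-to-right sweep (so each update sees its left
#' neighbors' new labels, which makes the iteration convergent rather than
#' oscillatory); sweeps repeat until the labeling is stable or `max_iter` is
#' reached (then the last iterate is returned with a warning). `factor = 0`
#' returns the input unchanged. Unassigned samples are left untouched and do
#' not count as neighbors.
#'
#' @param recording An `eeg_recording`.
#' @param templates An `msnf_templates`.
#' @param labels An [ms_labels()] (typically from [backfit()]).
#' @param window_samples Effective window length in samples (default 24; the
#'   window spans `floor(window_samples/2)` samples on each side).
#' @param factor Smoothing strength (default 10).
#' @param max_iter Iteration cap (default 1000).
#' @return A smoothed [ms_labels()].
#' @export
smooth_labels <- function(recording, templates, labels, window_samples = 24,
                          factor = 10, max_iter = 1000) {
  stopifnot(inherits(labels, "ms_labels"), factor >= 0)
  if (factor == 0) return(labels)
  check_channels(recording, templates)
  sc <- spatial_corr(recording$data, templates)
  c2 <- sc$corr^2
  c2[is.na(c2)] <- -Inf        # unassigned samples never win, stay NA below
  half <- max(1L, window_samples %/% 2L)
  k <- n_states(templates)
  n <- length(labels$labels)
  lab <- labels$labels
  boost <- factor / window_samples
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (t in seq_len(n)) {
      if (is.na(lab[t])) next
      lo <- max(1L, t - half)
      hi <- min(n, t + half)
      w <- lab[lo:hi]
      cnt <- tabulate(w[!is.na(w)], nbins = k)
      cnt[lab[t]] <- cnt[lab[t]] - 1L  # exclude the sample itself
      new <- which.max(c2[t, ] + boost * cnt)
      if (new != lab[t]) {
        lab[t] <- new
        changed <- TRUE
      }
    }
    if (!changed)
      return(ms_labels(lab, labels$sampling_rate, n_states = k))
  }
  rlang::warn("label smoothing did not converge; returning last iterate")
  ms_labels(lab, labels$sampling_rate, n_states = k)
}

#' Reject short microstate segments
#'
#' Runs of identical labels shorter than `min_samples` are split at their
#' midpoint: the left part takes the left neighbor's label, the right part
#' the right neighbor's, and the middle sample of an odd-length run joins the
#' side whose template correlates more strongly (in absolute value) with that
#' sample. The pass repeats until no short interior run remains. Runs touching
#' a sequence boundary keep their boundary side (no neighbor exists there),
#' and a sequence that is one single run is returned unchanged.
#'
#' @inheritParams smooth_labels
#' @param min_samples Minimum run length to keep (default 3).
#' @return An [ms_labels()] with no interior run shorter than `min_samples`.
#' @export
reject_short_segments <- function(recording, templates, labels, min_samples = 3) {
  stopifnot(inherits(labels, "ms_labels"))
  check_channels(recording, templates)
  sc <- spatial_corr(recording$data, templates)
  ac <- abs(sc$corr)
  lab <- labels$labels
  repeat {
    runs <- label_runs(lab)
    nr <- nrow(runs)
    if (nr <= 1L) {
      if (nr == 1L && runs$length[1] < min_samples)
        rlang::inform("single short run has no neighbors; left unchanged")
      break
    }
    short <- which(runs$length < min_samples & !is.na(runs$label) &
                   seq_len(nr) > 1L & seq_len(nr) < nr)
    short <- short[!is.na(runs$label[pmax(short - 1L, 1L)]) &
                   !is.na(runs$label[pmin(short + 1L, nr)])]
    if (length(short) == 0L) break
    i <- short[1]
    s <- runs$start[i]; e <- runs$end[i]; L <- runs$length[i]
    left_lab <- runs$label[i - 1L]
    right_lab <- runs$label[i + 1L]
    h <- L %/% 2L
    if (h > 0L) {
      lab[s:(s + h - 1L)] <- left_lab
      lab[(e - h + 1L):e] <- right_lab
    }
    if (L %% 2L == 1L) {
      m <- s + h
      lab[m] <- if (ac[m, left_lab] >= ac[m, right_lab]) left_lab else right_lab
    }
  }
  ms_labels(lab, labels$sampling_rate, n_states = labels$n_states)
}

#' Spatio-temporal microstate metrics
#'
#' Computes, per state, the three standard microstate statistics:
#' * global explained variance (GEV): the share of total GFP-squared-weighted
#'   variance explained by the assigned template,
#'   `gev_k = sum over t with L(t)=k of GFP(t)^2 corr(x_t, map_k)^2 /
#'    sum over all t of GFP(t)^2`;
#' * time coverage: the fraction of samples assigned to the state (by default
#'   among assigned samples; `coverage_denominator = "all"` divides by the
#'   full sample count instead);
#' * mean duration: the average uninterrupted run length, in milliseconds.
#'
#' @inheritParams smooth_labels
#' @param coverage_denominator `"assigned"` (default) or `"all"`.
#' @return A tibble of class `msnf_metrics` with columns `state`, `gev`,
#'   `time_coverage`, `mean_duration_ms`, `n_segments`.
#' @export
compute_metrics <- function(recording, labels, templates,
                            coverage_denominator = c("assigned", "all")) {
  coverage_denominator <- match.arg(coverage_denominator)
  stopifnot(inherits(labels, "ms_labels"))
  check_channels(recording, templates)
  lab <- labels$labels
  if (length(lab) != nrow(recording$data))
    stop_msnf("labels and recording have different lengths", "metrics")
  k <- n_states(templates)
  g <- gfp(recording)
  sc <- spatial_corr(recording$data, templates)
  g2 <- g^2
  denom_gev <- sum(g2)
  n_assigned <- sum(!is.na(lab))
  denom_cov <- if (coverage_denominator == "assigned") n_assigned else length(lab)
  runs <- label_runs(lab)
  per_state <- lapply(seq_len(k), function(s) {
    idx <- which(!is.na(lab) & lab == s)
    gev <- if (denom_gev > 0) sum(g2[idx] * sc$corr[idx, s]^2) / denom_gev else 0
    rr <- runs$length[!is.na(runs$label) & runs$label == s]
    tibble::tibble(
      state = templates$state_names[s],
      gev = gev,
      time_coverage = length(idx) / denom_cov,
      mean_duration_ms = if (length(rr)) mean(rr) * 1000 / labels$sampling_rate
                         else NA_real_,
      n_segments = length(rr)
    )
  })
  out <- dplyr::bind_rows(per_state)
  class(out) <- c("msnf_metrics", class(out))
  out
}

#' Time coverage of one state
#'
#' Convenience accessor used by calibration and the feedback loop: the
#' fraction of (assigned) samples labeled with `state`.
#'
#' @param labels An [ms_labels()].
#' @param state State index.
#' @param denominator `"assigned"` or `"all"`.
#' @return A fraction in `[0, 1]`.
#' @export
time_coverage <- function(labels, state, denominator = c("assigned", "all")) {
  denominator <- match.arg(denominator)
  lab <- labels$labels
  d <- if (denominator == "assigned") sum(!is.na(lab)) else length(lab)
  if (d == 0L) return(NA_real_)
  sum(lab == state, na.rm = TRUE) / d
}

#' Full offline segmentation pipeline
#'
#' Backfit, smooth, and reject short segments in one call — the offline
#' analysis path. The online (calibration/feedback) path uses [backfit()]
#' alone, with no smoothing and no short-segment rejection.
#'
#' @inheritParams smooth_labels
#' @param min_samples Minimum segment length (default 3).
#' @return An [ms_labels()].
#' @export
segment <- function(recording, templates, window_samples = 24, factor = 10,
                    min_samples = 3) {
  lab <- backfit(recording, templates)
  lab <- smooth_labels(recording, templates, lab,
                       window_samples = window_samples, factor = factor)
  reject_short_segments(recording, templates, lab, min_samples = min_samples)
}
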