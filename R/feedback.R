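#' Feedback engine configuration
#'
#' Bundles the real-time loop parameters: a 3 s analysis window re-scored
#' every 250 ms, the last 10 raw coverages averaged with linear time weights,
#' and a session of 10 blocks of 3 min training separated by 20 s breaks.
#' The defaults are the protocol's printed parameters.
#'
#' @param window_s Analysis window length (s), default 3.
#' @param step_s Iteration cadence (s), default 0.25.
#' @param n_smooth Number of raw coverages entering the weighted score,
#'   default 10.
#' @param target_state Regulated state name or index, default `"D"`.
#' @param direction `"up"` or `"down"`. The direction never changes the
#'   computed feedback value — only how the display interprets it — matching
#'   a double-blind protocol.
#' @param n_blocks,block_s,break_s Session block structure, defaults 10
#'   blocks x 180 s with 20 s breaks.
#' @param clip Clip feedback to `[-1, 1]` (default TRUE).
#' @return An object of class `msnf_engine_config`.
#' @export
engine_config <- function(window_s = 3.0, step_s = 0.25, n_smooth = 10,
                          target_state = "D", direction = c("up", "down"),
                          n_blocks = 10, block_s = 180, break_s = 20,
                          clip = TRUE) {
  direction <- match.arg(direction)
  stopifnot(window_s > 0, step_s > 0, n_smooth >= 1, n_blocks >= 1,
            block_s >= window_s, break_s >= 0)
  structure(
    list(window_s = window_s, step_s = step_s, n_smooth = n_smooth,
         target_state = target_state, direction = direction,
         n_blocks = n_blocks, block_s = block_s, break_s = break_s,
         clip = clip),
    class = "msnf_engine_config"
  )
}

#' Score one analysis window
#'
#' Time coverage of the target state in the window, from plain backfitting —
#' no label smoothing and no short-segment rejection, as in the online loop.
#'
#' @param window An `eeg_recording` (one analysis window).
#' @param templates An `msnf_templates`.
#' @param target_state State name or index.
#' @return Coverage fraction in `[0, 1]`.
#' @export
score_window <- function(window, templates, target_state) {
  tgt <- state_index(templates, target_state)
  time_coverage(backfit(window, templates), tgt)
}

#' Linearly time-weighted score smoothing
#'
#' Weighted mean of the most recent raw coverages with weights `1..m`
#' (`m = min(length(history), n_smooth)`, the newest value carrying the
#' largest weight), normalized by their sum. With a full default history the
#' newest value has weight `10/55`.
#'
#' @param history Numeric vector of raw coverages, oldest first.
#' @param n_smooth Maximum number of values used (default 10).
#' @return The smoothed score.
#' @export
smooth_score <- function(history, n_smooth = 10) {
  if (!length(history)) stop_msnf("history must be non-empty", "feedback")
  h <- tail(history, n_smooth)
  w <- seq_along(h)
  sum(w * h) / sum(w)
}

#' Scale a score to a feedback value
#'
#' The linear gauge mapping
#' `feedback = 1 - 2 * (max - score) / (max - min)`,
#' which is -1 at the calibration minimum, +1 at the maximum, and 0 at the
#' midpoint; clipped to `[-1, 1]` when `clip` is on (a gauge cannot
#' over-fill).
#'
#' @param score Smoothed coverage score.
#' @param calib An `msnf_calibration`, or any list with `min_threshold` and
#'   `max_threshold`.
#' @param clip Clip to `[-1, 1]` (default TRUE).
#' @return The feedback value.
#' @export
feedback_value <- function(score, calib, clip = TRUE) {
  mx <- calib$max_threshold
  mn <- calib$min_threshold
  if (!is_scalar_number(mx) || !is_scalar_number(mn) || mx <= mn)
    stop_msnf("degenerate calibration: max_threshold must exceed min_threshold",
              "feedback")
  fb <- 1 - 2 * (mx - score) / (mx - mn)
  if (clip) fb <- pmin(pmax(fb, -1), 1)
  fb
}

# ---- streams ---------------------------------------------------------------

#' Sample streams for the feedback loop
#'
#' A stream is a pull-based source the engine draws samples from. It is a
#' list with fields `pull(n)` (returns the next n samples as a matrix, or
#' fewer/NULL when exhausted), `sfreq`, `layout`, and optionally
#' `set_feedback(fb)`, which closed-loop sources use to couple the subject to
#' the feedback. `replay_stream()` replays a recorded file deterministically;
#' `subject_stream()` renders a [responsive_subject()] on the fly, advancing
#' its Markov chain under the current (feedback-modulated) transition matrix
#' and collecting the ground-truth labels.
#'
#' @param recording An `eeg_recording` to replay.
#' @return A stream object (class `msnf_stream`).
#' @export
replay_stream <- function(recording) {
  pos <- 0L
  n <- nrow(recording$data)
  structure(list(
    pull = function(ns) {
      if (pos >= n) return(NULL)
      take <- min(ns, n - pos)
      out <- recording$data[(pos + 1L):(pos + take), , drop = FALSE]
      pos <<- pos + take
      out
    },
    sfreq = recording$sfreq,
    layout = recording$layout,
    set_feedback = NULL
  ), class = "msnf_stream")
}

#' @rdname replay_stream
#' @param subject A [responsive_subject()].
#' @param templates An `msnf_templates` used for rendering.
#' @param sfreq Rendering rate (Hz).
#' @param seed RNG seed; the stream keeps a private RNG state so pulls are
#'   reproducible regardless of the caller's RNG use.
#' @param keep_data Accumulate the rendered samples so the full recording can
#'   be retrieved afterwards (default FALSE; a full session is large).
#' @export
subject_stream <- function(subject, templates, sfreq, seed = NULL,
                           keep_data = FALSE) {
  stopifnot(inherits(subject, "msnf_subject"))
  P <- subject$base_model$transition_matrix
  tgt <- state_index(templates, subject$target_state)
  mdl <- subject$base_model
  state <- NULL
  labels_acc <- integer()
  data_acc <- list()
  p_hist <- numeric()
  rng <- NULL  # private RNG state
  sign_dir <- if (subject$direction == "up") 1 else -1
  pull_fun <- function(ns) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    if (is.null(rng)) set.seed(seed %||% 1L) else assign(".Random.seed", rng, globalenv())
    if (is.null(state)) {
      pi0 <- stationary_distribution(P)
      state <<- findInterval(runif(1), cumsum(pi0)) + 1L
      state <<- min(state, nrow(P))
    }
    m <- markov_model(P, mdl$gfp_mean, mdl$gfp_cv, mdl$noise_sigma)
    lab <- sample_labels(m, ns, sfreq, seed = NULL, init = state)
    state <<- lab$labels[ns]
    x <- render_eeg(lab, templates, mdl$gfp_mean, mdl$gfp_cv, mdl$noise_sigma,
                    polarity_flips = TRUE, seed = NULL)
    rng <<- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    labels_acc <<- c(labels_acc, lab$labels)
    if (keep_data) data_acc[[length(data_acc) + 1L]] <<- x$data
    x$data
  }
  structure(list(
    pull = pull_fun,
    sfreq = sfreq,
    layout = templates$layout,
    set_feedback = function(fb) {
      # reward-gated learning: progress in the trained direction at a rate
      # scaled by gauge fill ((1+fb)/2 in [0,1]); a participant does not
      # unlearn when the gauge is empty, they just stop improving
      delta <- sign_dir * subject$learning_gain * (1 + fb) / 2
      P <<- update_transition(P, tgt, delta,
                              subject$p_floor, subject$p_ceiling)
      p_hist <<- c(p_hist, P[tgt, tgt])
      invisible(P)
    },
    ground_truth = function() ms_labels(labels_acc, sfreq, n_states = n_states(templates)),
    recording = function() {
      if (!keep_data) stop_msnf("stream was created with keep_data = FALSE", "stream")
      eeg_recording(do.call(rbind, data_acc), sfreq, templates$layout)
    },
    p_stay_history = function() p_hist
  ), class = "msnf_stream")
}

#' Run a neurofeedback session
#'
#' The real-time loop over a pull-based stream: every `step_s` the engine
#' takes the last `window_s` of data, applies the per-window preprocessing
#' (if any), scores the target state's coverage by plain backfitting, smooths
#' the last `n_smooth` raw scores with linear time weights, scales to a
#' feedback value with the calibration thresholds, and (for closed-loop
#' streams) feeds the value back to the source. Scores are only emitted once
#' a full window exists (warm-up); the smoothing history is reset at each
#' block start so no pre-break data leaks across blocks; breaks advance the
#' stream without scoring. The loop runs on simulated time, so a session is
#' deterministic given a deterministic stream.
#'
#' @param stream A stream from [replay_stream()] or [subject_stream()].
#' @param calib An `msnf_calibration` (or list with thresholds).
#' @param config An [engine_config()].
#' @param templates An `msnf_templates`.
#' @param preprocess Optional `function(eeg_recording) -> eeg_recording`
#'   applied to each window before scoring (see [online_preprocess()]).
#' @return A tibble of class `msnf_trace` with columns `t`, `block`,
#'   `iteration`, `raw_coverage`, `smoothed_score`, `feedback`.
#' @export
run_session <- function(stream, calib, config, templates, preprocess = NULL) {
  stopifnot(inherits(config, "msnf_engine_config"))
  sfreq <- stream$sfreq
  win <- round(config$window_s * sfreq)
  step <- round(config$step_s * sfreq)
  tgt <- state_index(templates, config$target_state)
  rows <- vector("list", 0L)
  t_now <- 0
  iter <- 0L
  for (blk in seq_len(config$n_blocks)) {
    buffer <- NULL
    history <- numeric()  # reset smoothing at block start
    n_steps <- floor(config$block_s / config$step_s)
    for (s in seq_len(n_steps)) {
      chunk <- stream$pull(step)
      t_now <- t_now + config$step_s
      if (is.null(chunk) || nrow(chunk) < step) {
        rlang::inform("stream exhausted; ending session early")
        out <- dplyr::bind_rows(rows)
        class(out) <- c("msnf_trace", class(out))
        return(out)
      }
      buffer <- rbind(buffer, chunk)
      if (nrow(buffer) > win)
        buffer <- buffer[(nrow(buffer) - win + 1L):nrow(buffer), , drop = FALSE]
      if (nrow(buffer) < win) next  # warm-up: no full window yet
      window <- eeg_recording(buffer, sfreq, stream$layout)
      if (!is.null(preprocess)) window <- preprocess(window)
      raw <- score_window(window, templates, tgt)
      history <- tail(c(history, raw), config$n_smooth)
      score <- smooth_score(history, config$n_smooth)
      fb <- feedback_value(score, calib, clip = config$clip)
      if (!is.null(stream$set_feedback)) stream$set_feedback(fb)
      iter <- iter + 1L
      rows[[iter]] <- tibble::tibble(
        t = t_now, block = blk, iteration = iter,
        raw_coverage = raw, smoothed_score = score, feedback = fb
      )
    }
    if (blk < config$n_blocks && config$break_s > 0) {
      stream$pull(round(config$break_s * sfreq))  # break: no scoring
      t_now <- t_now + config$break_s
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("msnf_trace", class(out))
  out
}

#' Per-window online preprocessing
#'
#' Builds the cleaning function the online loop applies to each window:
#' drop mastoids by name, band-pass and notch filter, apply a stored ICA
#' solution, interpolate bad channels, and re-reference to average. Each
#' window is filtered independently (stateless across iterations). Any stage
#' can be disabled by passing `NULL`.
#'
#' @param bandpass_hz Length-2 band edges or NULL (default `c(1, 30)`).
#' @param notch_hz Length-2 stop-band edges or NULL (default `c(49, 51)`).
#' @param ica An [ica_solution()] or NULL.
#' @param interpolate Interpolate channels flagged bad in the window's layout
#'   (default TRUE).
#' @param drop Channel names to drop (default `c("M1", "M2")`).
#' @return A `function(eeg_recording) -> eeg_recording`.
#' @export
online_preprocess <- function(bandpass_hz = c(1, 30), notch_hz = c(49, 51),
                              ica = NULL, interpolate = TRUE,
                              drop = c("M1", "M2")) {
  function(window) {
    w <- drop_channels(window, drop)
    if (!is.null(bandpass_hz)) w <- bandpass(w, bandpass_hz[1], bandpass_hz[2])
    if (!is.null(notch_hz) && notch_hz[2] < w$sfreq / 2)
      w <- notch(w, notch_hz[1], notch_hz[2], method = "iir")
    if (!is.null(ica)) w <- apply_ica(w, ica)
    if (interpolate && length(w$layout$bads)) w <- interpolate_bads(w)
    average_reference(w)
  }
}

#' Simulate a closed-loop session with a virtual subject
#'
#' Runs [run_session()] with a [subject_stream()]: after every feedback
#' emission the subject's target-state self-transition probability is nudged
#' by `learning_gain * feedback` (sign set by the regulation direction), so a
#' positive-gain subject "learns" to up-regulate. Returns the trace together
#' with the ground-truth labels actually generated, per-block ground-truth
#' coverage of the target state, and the self-transition history.
#'
#' @param subject A [responsive_subject()].
#' @param calib An `msnf_calibration` (or list with thresholds).
#' @param config An [engine_config()].
#' @param templates An `msnf_templates`.
#' @param sfreq Rendering rate (Hz).
#' @param seed RNG seed for the subject's EEG.
#' @param keep_recording Also return the rendered EEG (default FALSE; the
#'   full-session recording is large).
#' @return A list of class `msnf_session`: `trace` (msnf_trace),
#'   `block_coverage` (tibble `block`, `coverage` from ground-truth labels),
#'   `labels`, `p_stay`, and optionally `recording`.
#' @export
run_virtual_subject <- function(subject, calib, config, templates, sfreq,
                                seed = NULL, keep_recording = FALSE) {
  stream <- subject_stream(subject, templates, sfreq, seed = seed,
                           keep_data = keep_recording)
  trace <- run_session(stream, calib, config, templates)
  gt <- stream$ground_truth()
  tgt <- state_index(templates, subject$target_state)
  # map ground-truth samples to blocks; the stream advances by exactly
  # floor(block_s / step_s) steps per block, then the break
  step <- round(config$step_s * sfreq)
  blk_len <- floor(config$block_s / config$step_s) * step
  brk_len <- round(config$break_s * sfreq)
  idx <- seq_along(gt$labels) - 1L
  cyc <- blk_len + brk_len
  blk <- idx %/% cyc + 1L
  in_block <- (idx %% cyc) < blk_len
  bc <- tibble::tibble(block = blk[in_block], lab = gt$labels[in_block]) |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(coverage = mean(.data$lab == tgt), .groups = "drop")
  out <- list(trace = trace, block_coverage = bc, labels = gt,
              p_stay = stream$p_stay_history())
  if (keep_recording) out$recording <- stream$recording()
  structure(out, class = "msnf_session")
}

#' @export
print.msnf_session <- function(x, ...) {
  cat(sprintf("<msnf_session> %d feedback iterations, %d blocks\n",
              nrow(x$trace), max(x$trace$block %||% 0)))
  invisible(x)
}

#' Write a feedback trace as CSV
#' @param trace An `msnf_trace`.
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
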