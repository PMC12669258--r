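#' Simulate a full crossover neurofeedback study
#'
#' Generates a cohort of virtual subjects and runs each through the full
#' protocol: a resting calibration recording, then an up-regulation and a
#' down-regulation closed-loop session in alternating crossover order
#' (odd-numbered subjects start with up). Per-subject calibration JSON,
#' session traces, and block-coverage tables are written under `out_dir`,
#' together with a study-level summary including the crossover contrast
#' (up last-block-minus-baseline versus down last-block-minus-baseline).
#'
#' @param out_dir Output directory (created if missing).
#' @param n_subjects Number of virtual subjects.
#' @param seed Study-level RNG seed; each subject derives its own seeds.
#' @param templates An `msnf_templates` (default: 5 synthetic maps on the
#'   62-channel idealized layout).
#' @param config An [engine_config()]; defaults are the full protocol
#'   (10 blocks x 180 s). Pass a scaled config for quick experiments.
#' @param sfreq Rendering rate in Hz (default 250).
#' @param calibration_s Length of the resting calibration recording
#'   (default 180 s).
#' @param dwell_s Baseline per-state mean dwell times in seconds (default
#'   0.06 for 5 states, typical resting microstate durations).
#' @param learning_gain Coupling of the virtual subjects (default 5e-5, a
#'   gradual learner over a full 10 x 180 s protocol; 0 gives sham
#'   non-learners).
#' @param gfp_mean,gfp_cv,noise_sigma Generator amplitude/noise parameters.
#' @return A tibble (one row per subject x direction) with calibration
#'   thresholds, first/last block coverage, and the session contrast;
#'   attribute `"crossover"` holds the per-subject crossover contrasts.
#' @export
simulate_study <- function(out_dir, n_subjects, seed = 1,
                           templates = NULL, config = engine_config(),
                           sfreq = 250, calibration_s = 180,
                           dwell_s = NULL, learning_gain = 5e-5,
                           gfp_mean = 15, gfp_cv = 0.3, noise_sigma = 7.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  templates <- templates %||% synth_templates(default_layout(62))
  k <- n_states(templates)
  dwell_s <- dwell_s %||% rep(0.06, k)
  P <- transition_from_dwell(dwell_s, sfreq)
  model <- markov_model(P, gfp_mean, gfp_cv, noise_sigma)
  rows <- list()
  crossover <- numeric(n_subjects)
  for (subj in seq_len(n_subjects)) {
    subj_seed <- (seed * 1000L + subj) %% .Machine$integer.max
    subj_dir <- file.path(out_dir, sprintf("subject_%02d", subj))
    dir.create(subj_dir, showWarnings = FALSE)
    # resting calibration
    lab0 <- sample_labels(model, round(calibration_s * sfreq), sfreq,
                          seed = subj_seed)
    rest <- render_eeg(lab0, templates, gfp_mean, gfp_cv, noise_sigma,
                       seed = subj_seed + 1L)
    calib <- calibrate(rest, templates, config$target_state)
    write_calibration(calib, file.path(subj_dir, "calibration.json"))
    rs0 <- calib$mu  # baseline coverage estimate
    # crossover order alternates: odd subjects start with up
    dirs <- if (subj %% 2L == 1L) c("up", "down") else c("down", "up")
    contrast <- c(up = NA_real_, down = NA_real_)
    for (di in seq_along(dirs)) {
      dr <- dirs[di]
      cfg <- config
      cfg$direction <- dr
      subject <- responsive_subject(model, config$target_state,
                                    learning_gain, direction = dr)
      sess <- run_virtual_subject(subject, calib, cfg, templates, sfreq,
                                  seed = subj_seed + 10L * di)
      write_trace(sess$trace, file.path(subj_dir, sprintf("trace_%s.csv", dr)))
      utils::write.csv(as.data.frame(sess$block_coverage),
                       file.path(subj_dir, sprintf("blocks_%s.csv", dr)),
                       row.names = FALSE)
      bc <- sess$block_coverage
      last_cov <- bc$coverage[which.max(bc$block)]
      contrast[dr] <- last_cov - rs0
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = subj, direction = dr, order = di,
        mu = calib$mu, sigma = calib$sigma,
        first_block = bc$coverage[which.min(bc$block)],
        last_block = last_cov, contrast = contrast[[dr]]
      )
    }
    crossover[subj] <- contrast[["up"]] - contrast[["down"]]
  }
  out <- dplyr::bind_rows(rows)
  utils::write.csv(as.data.frame(out), file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(subject = seq_len(n_subjects),
                              crossover = crossover),
                   file.path(out_dir, "crossover.csv"), row.names = FALSE)
  attr(out, "crossover") <- crossover
  out
}

#' End-to-end offline analysis of one recording
#'
#' Glue over the module functions: calibrate on the recording, replay it
#' through the feedback engine, and compute offline microstate metrics from
#' the full segmentation pipeline.
#'
#' @param recording An `eeg_recording` (already preprocessed, or pass
#'   `preprocess = online_preprocess(...)` applied up front).
#' @param templates An `msnf_templates`.
#' @param config An [engine_config()].
#' @param preprocess Optional function applied to the recording before
#'   analysis.
#' @return A list with `calibration`, `trace`, and `metrics`.
#' @export
end_to_end <- function(recording, templates, config = engine_config(),
                       preprocess = NULL) {
  if (!is.null(preprocess)) recording <- preprocess(recording)
  calib <- calibrate(recording, templates, config$target_state)
  n_avail <- floor(nrow(recording$data) / recording$sfreq)
  cfg <- config
  cfg$n_blocks <- 1L
  cfg$block_s <- min(config$block_s, n_avail)
  trace <- run_session(replay_stream(recording), calib, cfg, templates)
  labels <- segment(recording, templates)
  metrics <- compute_metrics(recording, labels, templates)
  list(calibration = calib, trace = trace, metrics = metrics)
}
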