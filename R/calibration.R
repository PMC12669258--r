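#' Calibrate feedback thresholds from a resting recording
#'
#' Splits a preprocessed resting-state recording into overlapping epochs
#' (3 s / 0.5 s overlap by default, mimicking the online loop's windows),
#' backfits the templates to each epoch *without* smoothing or short-segment
#' rejection, and computes the target state's time coverage per epoch. The
#' feedback gauge range is then set to one standard deviation around the mean
#' of that distribution:
#' `min = mu - sigma`, `max = mu + sigma`.
#'
#' @param recording A preprocessed `eeg_recording` (filtered, ICA-applied,
#'   average-referenced).
#' @param templates An `msnf_templates`.
#' @param target_state Target state name or index (e.g. `"D"`).
#' @param epoch_length_s,overlap_s Epoching parameters (defaults 3 and 0.5 s).
#' @param sd_type `"population"` (divide by N, default) or `"sample"`.
#' @return An object of class `msnf_calibration` with fields `coverages`
#'   (tibble `epoch`, `onset_s`, `coverage`), `mu`, `sigma`, `min_threshold`,
#'   `max_threshold`, `target_state`, `epoch_length_s`, `overlap_s`.
#' @export
calibrate <- function(recording, templates, target_state = "D",
                      epoch_length_s = 3.0, overlap_s = 0.5,
                      sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  tgt <- state_index(templates, target_state)
  eps <- epoch_windows(recording, epoch_length_s, overlap_s)
  if (length(eps) < 2L)
    stop_msnf("calibration needs at least 2 epochs (sigma undefined)", "calibration")
  cov <- vapply(eps, function(e) {
    time_coverage(backfit(e, templates), tgt)
  }, numeric(1))
  mu <- mean(cov)
  sigma <- if (sd_type == "population") sqrt(mean((cov - mu)^2)) else sd(cov)
  if (sigma == 0)
    stop_msnf("degenerate calibration: all epochs have identical coverage",
              "calibration")
  structure(
    list(
      coverages = tibble::tibble(
        epoch = seq_along(cov),
        onset_s = vapply(eps, attr, numeric(1), which = "onset_s"),
        coverage = cov
      ),
      mu = mu, sigma = sigma,
      min_threshold = mu - sigma, max_threshold = mu + sigma,
      target_state = templates$state_names[tgt],
      epoch_length_s = epoch_length_s, overlap_s = overlap_s,
      sd_type = sd_type
    ),
    class = "msnf_calibration"
  )
}

#' @export
print.msnf_calibration <- function(x, ...) {
  cat(sprintf(
    "<msnf_calibration> state %s: mu=%.4f sigma=%.4f -> [%.4f, %.4f] (%d epochs)\n",
    x$target_state, x$mu, x$sigma, x$min_threshold, x$max_threshold,
    nrow(x$coverages)))
  invisible(x)
}

#' @export
tidy.msnf_calibration <- function(x, ...) x$coverages

#' @export
glance.msnf_calibration <- function(x, ...) {
  tibble::tibble(
    target_state = x$target_state, n_epochs = nrow(x$coverages),
    mu = x$mu, sigma = x$sigma,
    min_threshold = x$min_threshold, max_threshold = x$max_threshold
  )
}

#' Serialize calibration results to JSON
#' @param calib An `msnf_calibration`.
#' @param path File path.
#' @export
write_calibration <- function(calib, path) {
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coverages <- tibble::as_tibble(x$coverages)
  structure(x, class = "msnf_calibration")
}
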