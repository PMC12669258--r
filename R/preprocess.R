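#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel forward and backward (zero-phase, non-causal) with a
#' Butterworth design. The band-pass is realized as a cascade of an order-`order`
#' high-pass and an order-`order` low-pass, each applied two-pass; a direct
#' high-order band-pass in transfer-function form is numerically unstable at a
#' 1 Hz edge relative to EEG sampling rates, while the cascade is stable and
#' has the same effective order (2x the design order after forward-backward).
#' The DC component is removed by the high-pass.
#'
#' @param recording An `eeg_recording`.
#' @param low_hz,high_hz Band edges in Hz (defaults 1 and 30).
#' @param order Design order per pass and per section (default 8, i.e.
#'   effective order 16 after the two passes).
#' @return A filtered `eeg_recording` of the same shape.
#' @export
bandpass <- function(recording, low_hz = 1, high_hz = 30, order = 8) {
  nyq <- recording$sfreq / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop_msnf("band edges must satisfy 0 < low < high < Nyquist", "filter")
  hp <- butter_sos(order, low_hz / nyq, type = "high")
  lp <- butter_sos(order, high_hz / nyq, type = "low")
  pad <- round(3 * recording$sfreq / low_hz)  # three periods of the low edge
  x <- apply(recording$data, 2, function(ch) {
    sos_filtfilt(lp, sos_filtfilt(hp, ch, pad), pad)
  })
  eeg_recording(x, recording$sfreq, recording$layout, recording$annotations)
}

# Butterworth low/high-pass as second-order sections, built analytically from
# the prototype poles and the bilinear transform. The cascaded biquads are
# numerically well-conditioned where the expanded transfer-function polynomial
# of the same filter is unstable (poles clustered near z = 1 at EEG band
# edges).
butter_sos <- function(order, W, type = c("low", "high")) {
  type <- match.arg(type)
  wc <- tan(pi * W / 2)  # prewarped analog cutoff (s = (1 - z^-1)/(1 + z^-1))
  k <- seq_len(floor(order / 2))
  theta <- pi * (2 * k - 1) / (2 * order)
  secs <- lapply(theta, function(th) {
    re <- -sin(th)  # prototype pole pair -sin(th) +/- i cos(th), |p| = 1
    if (type == "low") {
      num <- c(0, 0, wc^2)           # wc^2 / (s^2 - 2 re wc s + wc^2)
      den <- c(1, -2 * re * wc, wc^2)
    } else {
      num <- c(1, 0, 0)              # s^2 / (s^2 - 2 re wc s + wc^2)
      den <- c(1, -2 * re * wc, wc^2)
    }
    bilinear_quad(num, den)
  })
  if (order %% 2 == 1) {
    # single real prototype pole at s = -1
    if (type == "low") { num <- c(0, wc); den <- c(1, wc) }
    else { num <- c(1, 0); den <- c(1, wc) }
    secs <- c(secs, list(bilinear_lin(num, den)))
  }
  secs
}

# bilinear transform of (n2 s^2 + n1 s + n0)/(s^2 + d1 s + d0), s=(1-z)/(1+z)
bilinear_quad <- function(num, den) {
  n2 <- num[1]; n1 <- num[2]; n0 <- num[3]
  d2 <- den[1]; d1 <- den[2]; d0 <- den[3]
  b <- c(n2 + n1 + n0, 2 * (n0 - n2), n2 - n1 + n0)
  a <- c(d2 + d1 + d0, 2 * (d0 - d2), d2 - d1 + d0)
  list(b = b / a[1], a = a / a[1])
}

bilinear_lin <- function(num, den) {
  b <- c(num[1] + num[2], num[2] - num[1])
  a <- c(den[1] + den[2], den[2] - den[1])
  list(b = b / a[1], a = a / a[1])
}

# one causal pass of b/a with steady-state initial conditions for a constant
# input level x0 (suppresses start-up transients)
iir_pass <- function(b, a, x, x0) {
  dc <- sum(b) / sum(a)
  y0 <- if (is.finite(dc)) dc * x0 else 0
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x0, max(length(b) - 1, 0)),
                            init.y = rep(y0, max(length(a) - 1, 0))))
}

# forward-backward filtering of a section cascade with odd-reflection padding
# at both ends: the filter transient decays inside the padding, so symmetric
# inputs stay symmetric (zero phase)
sos_filtfilt <- function(sos, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  ext <- if (pad > 0) {
    c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  } else x
  for (s in sos) {
    ext <- iir_pass(s$b, s$a, ext, ext[1])
    ext <- rev(iir_pass(s$b, s$a, rev(ext), ext[length(ext)]))
  }
  if (pad > 0) ext[(pad + 1):(pad + n)] else ext
}

# IIR band-stop in transfer-function form (well-conditioned away from z = 1),
# applied with the same padded two-pass scheme
pad_filtfilt <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  ext <- if (pad > 0) {
    c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  } else x
  ext <- iir_pass(filt$b, filt$a, ext, ext[1])
  ext <- rev(iir_pass(filt$b, filt$a, rev(ext), ext[length(ext)]))
  if (pad > 0) ext[(pad + 1):(pad + n)] else ext
}

#' Band-stop (notch) filter
#'
#' Removes line noise in `[low_hz, high_hz]`. Two dialects are provided:
#' `method = "iir"` (default) is a zero-phase two-pass Butterworth band-stop,
#' the online-loop filter; `method = "fir"` is a one-pass zero-phase
#' linear-phase FIR design (Hamming window, transition width
#' `transition_hz`), the offline dialect, applied with group-delay
#' compensation. The realized FIR length follows the standard
#' Hamming transition-width rule and is reported via `attr(, "filter_length")`.
#'
#' @param recording An `eeg_recording`.
#' @param low_hz,high_hz Stop-band edges (defaults 49 and 51 Hz).
#' @param method `"iir"` or `"fir"`.
#' @param order IIR design order per pass (default 4).
#' @param transition_hz FIR transition bandwidth (default 0.5 Hz).
#' @return A filtered `eeg_recording`.
#' @export
notch <- function(recording, low_hz = 49, high_hz = 51,
                  method = c("iir", "fir"), order = 4, transition_hz = 0.5) {
  method <- match.arg(method)
  nyq <- recording$sfreq / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop_msnf("band edges must satisfy 0 < low < high < Nyquist", "filter")
  if (method == "iir") {
    bs <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "stop")
    pad <- round(3 * recording$sfreq / (high_hz - low_hz))
    x <- apply(recording$data, 2, function(ch) pad_filtfilt(bs, ch, pad))
    flen <- NA_integer_
  } else {
    # Hamming-window FIR: length ~ 3.3 / normalized transition width, odd
    flen <- ceiling(3.3 * recording$sfreq / transition_hz)
    if (flen %% 2 == 0) flen <- flen + 1L
    h <- as.numeric(signal::fir1(flen - 1, c(low_hz, high_hz) / nyq,
                                 type = "stop", window = signal::hamming(flen)))
    delay <- (flen - 1) / 2
    x <- apply(recording$data, 2, function(ch) {
      padded <- c(ch, numeric(delay))
      y <- as.numeric(signal::filter(h, 1, padded))
      y[(delay + 1):length(y)]
    })
  }
  out <- eeg_recording(x, recording$sfreq, recording$layout,
                       recording$annotations)
  attr(out, "filter_length") <- flen
  out
}

#' Detect gel-bridged electrode pairs
#'
#' Implements the intrinsic Hjorth / electrical-distance criterion: for every
#' channel pair the electrical distance is the temporal variance of the
#' difference signal. Bridged pairs form a near-zero cluster well separated
#' from the bulk. Distances are scaled to `100 * ed / median(ed)`; candidate
#' pairs below `candidate_cutoff` are thresholded at the local minimum of the
#' kernel density of scaled distances (searched below `candidate_cutoff`),
#' falling back to `fallback_cutoff` when no interior minimum exists.
#'
#' @param recording An `eeg_recording` (at least 2 channels and 2 s of data).
#' @param candidate_cutoff Scaled-distance ceiling for candidates (default 30).
#' @param fallback_cutoff Fixed scaled-distance threshold (default 5).
#' @return A tibble with columns `ch1`, `ch2`, `electrical_distance`,
#'   `scaled_distance` (zero rows when nothing is bridged).
#' @export
detect_bridges <- function(recording, candidate_cutoff = 30,
                           fallback_cutoff = 5) {
  x <- recording$data
  if (ncol(x) < 2L) stop_msnf("need at least 2 channels", "bridges")
  if (nrow(x) < 2 * recording$sfreq)
    stop_msnf("need at least 2 s of data", "bridges")
  cmb <- utils::combn(ncol(x), 2)
  ed <- apply(cmb, 2, function(ij) var(x[, ij[1]] - x[, ij[2]]))
  scaled <- 100 * ed / stats::median(ed)
  empty <- tibble::tibble(ch1 = character(), ch2 = character(),
                          electrical_distance = numeric(),
                          scaled_distance = numeric())
  cand <- scaled < candidate_cutoff
  if (!any(cand)) return(empty)
  cutoff <- fallback_cutoff
  if (sum(cand) < length(scaled)) {
    # local density minimum between the bridged cluster and the bulk
    d <- stats::density(scaled, from = 0, to = candidate_cutoff, n = 512)
    y <- d$y
    mins <- which(diff(sign(diff(y))) > 0) + 1L
    if (length(mins)) cutoff <- d$x[mins[1]]
  }
  hit <- which(scaled < cutoff)
  if (!length(hit)) return(empty)
  nm <- colnames(x)
  tibble::tibble(
    ch1 = nm[cmb[1, hit]], ch2 = nm[cmb[2, hit]],
    electrical_distance = ed[hit], scaled_distance = scaled[hit]
  )
}

# ---- spherical spline interpolation (Perrin-style) -------------------------

# g(x) = (1/4pi) * sum_{n=1}^{n_terms} (2n+1) / (n (n+1))^m * P_n(x),
# evaluated by the Legendre recurrence, vectorized over x
spline_g <- function(x, m = 4, n_terms = 50) {
  x <- pmin(pmax(x, -1), 1)
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  out <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (n in 2:n_terms) {
    p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    out <- out + (2 * n + 1) / (n * (n + 1))^m * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  out / (4 * pi)
}

#' Spherical-spline interpolation matrix
#'
#' Computes the linear operator mapping potentials at the good channels to
#' interpolated potentials at the bad channels, using spherical splines on
#' the unit sphere: a Legendre-series kernel `g(cos theta)` of stiffness `m`
#' (truncated at `n_terms` terms), spline coefficients solved on the good
#' channels under the usual zero-sum constraint with Tikhonov regularization
#' `reg` on the kernel diagonal. Because the spline reproduces constants, the
#' rows of the matrix sum to 1.
#'
#' @param layout An `msnf_layout`.
#' @param bads Channel names to interpolate (default `layout$bads`).
#' @param m Spline stiffness (default 4).
#' @param n_terms Legendre series truncation (default 50).
#' @param reg Regularization added to the kernel diagonal (default 1e-5).
#' @return A `length(bads)` x `n_good` matrix with dimnames.
#' @export
interpolation_matrix <- function(layout, bads = NULL, m = 4, n_terms = 50,
                                 reg = 1e-5) {
  bads <- bads %||% layout$bads
  good <- setdiff(layout$names, bads)
  if (length(good) < 4L) stop_msnf("need at least 4 good channels", "interp")
  if (!length(bads)) stop_msnf("no bad channels to interpolate", "interp")
  pg <- layout$positions[good, , drop = FALSE]
  pb <- layout$positions[bads, , drop = FALSE]
  G <- spline_g(tcrossprod(pg), m = m, n_terms = n_terms)
  dim(G) <- c(nrow(pg), nrow(pg))
  Gb <- spline_g(tcrossprod(pb, pg), m = m, n_terms = n_terms)
  dim(Gb) <- c(nrow(pb), nrow(pg))
  ng <- length(good)
  A <- rbind(cbind(G + diag(reg, ng), rep(1, ng)), c(rep(1, ng), 0))
  # columns of the solve give [c; d] for each unit potential at one good site
  sol <- solve(A, rbind(diag(ng), rep(0, ng)))
  W <- Gb %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1L, ], nrow(pb), ng, byrow = TRUE)
  dimnames(W) <- list(bads, good)
  W
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces the channels flagged bad in the layout (or `bads`) with their
#' spherical-spline reconstruction from the good channels; good channels are
#' untouched. Re-running with the same bads is idempotent since the
#' reconstruction depends only on good channels.
#'
#' @param recording An `eeg_recording`.
#' @param bads Channels to interpolate (default: the layout's bads).
#' @inheritParams interpolation_matrix
#' @return An `eeg_recording` with interpolated channels and no bads flagged.
#' @export
interpolate_bads <- function(recording, bads = NULL, m = 4, n_terms = 50,
                             reg = 1e-5) {
  lay <- recording$layout
  bads <- bads %||% lay$bads
  if (!length(bads)) return(recording)
  if (length(setdiff(lay$names, bads)) == 0L)
    stop_msnf("all channels are bad; nothing to interpolate from", "interp")
  W <- interpolation_matrix(lay, bads = bads, m = m, n_terms = n_terms,
                            reg = reg)
  x <- recording$data
  x[, rownames(W)] <- x[, colnames(W), drop = FALSE] %*% t(W)
  lay2 <- channel_layout(lay$names, lay$positions, bads = character(),
                         bridged_pairs = lay$bridged_pairs)
  eeg_recording(x, recording$sfreq, lay2, recording$annotations)
}

#' Average reference
#'
#' Re-references each sample to the mean across channels, so every sample's
#' channel mean is zero.
#'
#' @param recording An `eeg_recording`.
#' @return The re-referenced recording.
#' @export
average_reference <- function(recording) {
  eeg_recording(recording$data - rowMeans(recording$data), recording$sfreq,
                recording$layout, recording$annotations)
}

#' Stored ICA solutions
#'
#' Holds the mixing (channels x components) and unmixing (components x
#' channels) matrices of an independent component analysis computed
#' elsewhere, together with the set of rejected (artifactual) component
#' indices. Only the application of the stored solution is implemented here;
#' computing the decomposition is out of scope.
#'
#' @param mixing Channels x components matrix.
#' @param unmixing Components x channels matrix; `unmixing %*% mixing` must be
#'   the identity on the component subspace (tolerance 1e-6).
#' @param rejected Integer indices of rejected components.
#' @return An object of class `msnf_ica`.
#' @export
ica_solution <- function(mixing, unmixing, rejected = integer()) {
  mixing <- as.matrix(mixing); unmixing <- as.matrix(unmixing)
  if (ncol(mixing) != nrow(unmixing) || nrow(mixing) != ncol(unmixing))
    stop_msnf("mixing/unmixing dimensions do not match", "ica")
  I_hat <- unmixing %*% mixing
  if (max(abs(I_hat - diag(nrow(I_hat)))) > 1e-6)
    stop_msnf("unmixing %*% mixing is not the identity on the component subspace",
              "ica")
  rejected <- sort(unique(as.integer(rejected)))
  if (length(rejected) && (min(rejected) < 1L || max(rejected) > ncol(mixing)))
    stop_msnf("rejected component index out of range", "ica")
  structure(list(mixing = mixing, unmixing = unmixing, rejected = rejected),
            class = "msnf_ica")
}

#' Apply a stored ICA solution
#'
#' Reconstructs the signal from the retained components only, i.e. subtracts
#' the projection of the data onto the rejected components:
#' `X_clean = X - (A[, rej] U[rej, ] X')'`.
#'
#' @param recording An `eeg_recording`.
#' @param solution An [ica_solution()].
#' @return The cleaned `eeg_recording`.
#' @export
apply_ica <- function(recording, solution) {
  stopifnot(inherits(solution, "msnf_ica"))
  if (nrow(solution$mixing) != ncol(recording$data))
    stop_msnf("ICA solution channel count does not match recording", "ica")
  rej <- solution$rejected
  if (!length(rej)) return(recording)
  S <- recording$data %*% t(solution$unmixing[rej, , drop = FALSE])
  art <- S %*% t(solution$mixing[, rej, drop = FALSE])
  eeg_recording(recording$data - art, recording$sfreq, recording$layout,
                recording$annotations)
}

#' Read/write ICA solutions
#'
#' Matrices as delimited text (`<path>.mixing.tsv`, `<path>.unmixing.tsv`)
#' and the rejected-component list as JSON (`<path>.json`).
#'
#' @param solution An [ica_solution()].
#' @param path Base path (no extension).
#' @export
write_ica <- function(solution, path) {
  utils::write.table(solution$mixing, paste0(path, ".mixing.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(solution$unmixing, paste0(path, ".unmixing.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(rejected = solution$rejected), paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_ica
#' @export
read_ica <- function(path) {
  A <- as.matrix(utils::read.table(paste0(path, ".mixing.tsv"), sep = "\t"))
  U <- as.matrix(utils::read.table(paste0(path, ".unmixing.tsv"), sep = "\t"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ica_solution(unname(A), unname(U), meta$rejected %||% integer())
}

#' Split a recording into fixed-length windows
#'
#' Sliding windows of `length_s` seconds advancing by `length_s - overlap_s`
#' (so `overlap_s` is the duration shared by consecutive windows); the
#' trailing partial window is discarded. Windows overlapping an annotated bad
#' segment are dropped (with a message) unless `drop_annotated = FALSE`.
#' Sample indexing is 0-based half-open `[start, end)`.
#'
#' @param recording An `eeg_recording`.
#' @param length_s Window length in seconds (default 3).
#' @param overlap_s Shared duration between consecutive windows (default 0.5);
#'   must satisfy `0 <= overlap_s < length_s`.
#' @param drop_annotated Drop windows that intersect bad-segment annotations.
#' @return A list of `eeg_recording` windows; each carries its onset (s) in
#'   attribute `"onset_s"`.
#' @export
epoch_windows <- function(recording, length_s = 3.0, overlap_s = 0.5,
                          drop_annotated = TRUE) {
  if (!(length_s > overlap_s && overlap_s >= 0))
    stop_msnf("need length_s > overlap_s >= 0", "epoch")
  win <- round(length_s * recording$sfreq)
  step <- round((length_s - overlap_s) * recording$sfreq)
  n <- nrow(recording$data)
  if (n < win) return(list())
  starts <- seq(0L, n - win, by = step)
  eps <- lapply(starts, function(s) {
    e <- crop_samples(recording, s, s + win)
    attr(e, "onset_s") <- s / recording$sfreq
    e
  })
  if (drop_annotated && nrow(recording$annotations)) {
    onsets <- starts / recording$sfreq
    bad <- vapply(onsets, function(o) {
      any(o < recording$annotations$onset_s + recording$annotations$duration_s &
            o + length_s > recording$annotations$onset_s)
    }, logical(1))
    if (any(bad))
      rlang::inform(sprintf("dropping %d epoch(s) overlapping bad segments",
                            sum(bad)))
    eps <- eps[!bad]
  }
  eps
}
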