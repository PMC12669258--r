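#' Channel layouts on the unit sphere
#'
#' A channel layout records the ordered channel names, their 3-D positions on
#' the unit sphere, channels flagged bad, and any gel-bridged pairs. Positions
#' are used by the spherical-spline interpolator and for placing virtual
#' channels at the midpoint of bridged pairs.
#'
#' @param names Character vector of unique channel names.
#' @param positions Numeric matrix, one row per channel, 3 columns (x, y, z).
#'   Each row must have unit norm (tolerance 1e-9 on input validation is
#'   relaxed to 1e-6 to admit positions stored at limited precision).
#' @param bads Character vector of channel names flagged bad.
#' @param bridged_pairs List of length-2 character vectors naming bridged pairs.
#'
#' @return An object of class `msnf_layout`.
#' @export
channel_layout <- function(names, positions, bads = character(),
                           bridged_pairs = list()) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop_msnf("channel names must be unique", "layout")
  positions <- as.matrix(positions)
  if (nrow(positions) != length(names) || ncol(positions) != 3L)
    stop_msnf("positions must be a (n_channels x 3) matrix", "layout")
  nrm <- sqrt(rowSums(positions^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop_msnf("channel positions must lie on the unit sphere", "layout")
  if (!all(bads %in% names))
    stop_msnf("bads must be a subset of channel names", "layout")
  dimnames(positions) <- list(names, c("x", "y", "z"))
  structure(
    list(names = names, positions = positions, bads = as.character(bads),
         bridged_pairs = bridged_pairs),
    class = "msnf_layout"
  )
}

#' @export
print.msnf_layout <- function(x, ...) {
  cat(sprintf("<msnf_layout> %d channels (%d bad, %d bridged pairs)\n",
              length(x$names), length(x$bads), length(x$bridged_pairs)))
  invisible(x)
}

#' @export
length.msnf_layout <- function(x) length(x$names)

# quasi-uniform points on the spherical cap z >= z_min (Fibonacci lattice)
fibonacci_cap <- function(n, z_min = -0.25) {
  i <- seq_len(n) - 0.5
  z <- 1 - (1 - z_min) * i / n
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  cbind(x = sqrt(1 - z^2) * cos(phi), y = sqrt(1 - z^2) * sin(phi), z = z)
}

ten_ten_names_62 <- c(
  "Fp1", "Fpz", "Fp2",
  "AF7", "AF3", "AFz", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "POz", "PO4", "PO8",
  "O1", "Oz", "O2", "Iz"
)

#' Default idealized EEG layout
#'
#' Builds a layout of `n_channels` sensors quasi-uniformly distributed on the
#' upper portion of a unit sphere. With `n_channels = 62` the channels carry
#' extended 10-10 names (a 64-channel cap without the mastoids M1/M2); with
#' `include_mastoids = TRUE` two extra channels named M1 and M2 are appended at
#' low lateral positions. Other channel counts get generic names E1..En. The
#' geometry is an idealized quasi-uniform arrangement, not a measured montage;
#' downstream code only relies on unit-norm positions and channel names.
#'
#' @param n_channels Number of scalp channels (default 62).
#' @param include_mastoids Append mastoid channels M1/M2 (default FALSE).
#' @return An `msnf_layout`.
#' @export
default_layout <- function(n_channels = 62, include_mastoids = FALSE) {
  pos <- fibonacci_cap(n_channels)
  # order front-to-back then left-to-right so 10-10 names land sensibly
  ord <- order(round(-pos[, "y"], 3), pos[, "x"])
  pos <- pos[ord, , drop = FALSE]
  nm <- if (n_channels == 62L) ten_ten_names_62 else paste0("E", seq_len(n_channels))
  if (include_mastoids) {
    m <- rbind(M1 = c(-0.94, -0.15, -0.31), M2 = c(0.94, -0.15, -0.31))
    m <- m / sqrt(rowSums(m^2))
    pos <- rbind(pos, m)
    nm <- c(nm, "M1", "M2")
  }
  channel_layout(nm, pos)
}

#' Insert a virtual channel midway between a bridged pair
#'
#' Creates a new channel at the normalized chord midpoint of the pair's
#' positions (the spherical midpoint) and marks both parents bad, mirroring
#' the standard treatment of gel-bridged electrodes.
#'
#' @param layout An `msnf_layout`.
#' @param pair Length-2 character vector of channel names.
#' @param name Name for the virtual channel (default `"<a>-<b>"`).
#' @return A new `msnf_layout` with the virtual channel appended and the pair
#'   flagged bad.
#' @export
virtual_midpoint <- function(layout, pair, name = NULL) {
  stopifnot(inherits(layout, "msnf_layout"), length(pair) == 2L)
  if (!all(pair %in% layout$names))
    stop_msnf("pair channels not found in layout", "layout")
  p <- layout$positions[pair, , drop = FALSE]
  mid <- colMeans(p)
  nm2 <- sqrt(sum(mid^2))
  if (nm2 < 1e-9)
    stop_msnf("midpoint of an antipodal pair is undefined", "layout")
  mid <- mid / nm2
  name <- name %||% paste(pair, collapse = "-")
  channel_layout(
    c(layout$names, name),
    rbind(layout$positions, mid),
    bads = union(layout$bads, pair),
    bridged_pairs = c(layout$bridged_pairs, list(pair))
  )
}
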