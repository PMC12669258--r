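#' Microstate template sets
#'
#' A template set holds K microstate topographies as a K x C matrix of
#' unitless maps, one row per state. Maps are stored average-referenced
#' (channel mean zero) and L2-normalized, the convention under which the
#' spatial correlation used for backfitting reduces to a dot product.
#' Canonical resting-state template sets use five states named A, B, C, D, F.
#'
#' @param maps Numeric K x C matrix of topographies.
#' @param state_names Character vector of K state names (default A, B, C, D,
#'   F for K <= 5, else S1..SK).
#' @param layout `msnf_layout` matching the map columns.
#' @param normalize Center and rescale rows that are not already zero-mean
#'   unit-norm (default TRUE); with `normalize = FALSE` non-conforming maps
#'   are an error.
#' @return An object of class `msnf_templates`.
#' @export
template_set <- function(maps, state_names = NULL, layout = NULL,
                         normalize = TRUE) {
  maps <- as.matrix(maps)
  k <- nrow(maps)
  if (k < 1L) stop_msnf("need at least one template map", "templates")
  if (is.null(state_names))
    state_names <- if (k <= 5L) c("A", "B", "C", "D", "F")[seq_len(k)]
                   else paste0("S", seq_len(k))
  if (length(state_names) != k || anyDuplicated(state_names))
    stop_msnf("state_names must be unique and match the number of maps", "templates")
  if (normalize) {
    maps <- maps - rowMeans(maps)
    nrm <- sqrt(rowSums(maps^2))
    if (any(nrm < 1e-12)) stop_msnf("a template map is constant", "templates")
    maps <- maps / nrm
  } else {
    if (any(abs(rowMeans(maps)) > 1e-9) ||
        any(abs(sqrt(rowSums(maps^2)) - 1) > 1e-9))
      stop_msnf("maps must be zero-mean and unit-norm", "templates")
  }
  if (!is.null(layout)) {
    if (ncol(maps) != length(layout$names))
      stop_msnf("map columns do not match layout channels", "templates")
    colnames(maps) <- layout$names
  }
  rownames(maps) <- state_names
  structure(list(maps = maps, state_names = state_names, layout = layout),
            class = "msnf_templates")
}

#' @export
print.msnf_templates <- function(x, ...) {
  cat(sprintf("<msnf_templates> %d states (%s) x %d channels\n",
              nrow(x$maps), paste(x$state_names, collapse = ", "), ncol(x$maps)))
  invisible(x)
}

n_states <- function(templates) nrow(templates$maps)

# resolve a state name or index to an integer index
state_index <- function(templates, state) {
  if (is.character(state)) {
    i <- match(state, templates$state_names)
    if (is.na(i)) stop_msnf(sprintf("unknown state '%s'", state), "templates")
    return(i)
  }
  state <- as.integer(state)
  if (state < 1L || state > n_states(templates))
    stop_msnf("state index out of range", "templates")
  state
}

#' Deterministic synthetic template topographies
#'
#' Builds K smooth, mutually orthogonal topographies from low-order spatial
#' polynomials of the sensor positions (two tangential dipoles, a radial
#' gradient, and two quadrupolar patterns), centered and orthonormalized by
#' Gram-Schmidt. The result is a stand-in for grand-average resting-state
#' maps: smooth enough for spherical-spline tests and mutually orthogonal so
#' backfitting is unambiguous at low noise. Synthetic - not derived from any
#' recorded dataset.
#'
#' @param layout An `msnf_layout`.
#' @param k Number of states, 1 to 5 (default 5).
#' @return An `msnf_templates` with states named A, B, C, D, F.
#' @export
synth_templates <- function(layout, k = 5) {
  stopifnot(inherits(layout, "msnf_layout"), k >= 1, k <= 5)
  p <- layout$positions
  basis <- cbind(
    p[, 1],                 # left-right dipole
    p[, 2],                 # anterior-posterior dipole
    p[, 3],                 # radial gradient
    p[, 1]^2 - p[, 2]^2,    # quadrupole
    p[, 1] * p[, 3]         # oblique quadrupole
  )[, seq_len(k), drop = FALSE]
  basis <- sweep(basis, 2, colMeans(basis))
  q <- qr.Q(qr(basis))          # orthonormal, still zero-mean (centering is
                                # preserved because the constant vector is
                                # orthogonal to the centered basis)
  template_set(t(q), layout = layout, normalize = TRUE)
}

#' Read and write template sets as delimited text
#'
#' The maps are written as a TSV matrix with a `state` column and one column
#' per channel, plus a JSON sidecar `<path>.json` recording the normalization
#' convention.
#'
#' @param templates An `msnf_templates`.
#' @param path Path of the `.tsv` file.
#' @return `write_templates()` returns `path` invisibly; `read_templates()`
#'   an `msnf_templates`.
#' @export
write_templates <- function(templates, path) {
  df <- data.frame(state = templates$state_names, templates$maps,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(reference = "average", normalization = "l2", k = n_states(templates)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_templates
#' @param layout Optional `msnf_layout` for the channels of a read template
#'   file; when omitted an idealized spherical layout is attached.
#' @export
read_templates <- function(path, layout = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  maps <- as.matrix(df[, -1, drop = FALSE])
  lay <- layout %||% channel_layout(colnames(maps), fibonacci_cap(ncol(maps)))
  template_set(maps, state_names = df[[1]], layout = lay)
}
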