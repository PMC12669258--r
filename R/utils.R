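# internal helpers

# evaluate expr under a fixed seed without disturbing the caller's RNG state;
# seed = NULL means "use the current RNG stream"
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# run-length encoding of a label vector where NA is its own run label
label_runs <- function(labels) {
  n <- length(labels)
  stopifnot(n > 0L)
  key <- ifelse(is.na(labels), -1L, as.integer(labels))
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(
    label = ifelse(r$values == -1L, NA_integer_, r$values),
    start = starts, end = ends, length = r$lengths
  )
}

`%||%` <- rlang::`%||%`

stop_msnf <- function(msg, class) {
  rlang::abort(msg, class = paste0("msnf_", class))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
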