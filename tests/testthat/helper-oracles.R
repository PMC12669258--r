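# direct, unoptimized re-implementation of the boosted-criterion update used
# as the oracle for the production implementation
brute_smooth <- function(rec, tpl, labels, window_samples = 24, factor = 10,
                         max_iter = 1000) {
  x <- rec$data
  xc <- x - rowMeans(x)
  nrm <- sqrt(rowSums(xc^2))
  c2 <- ((xc %*% t(tpl$maps)) / nrm)^2
  half <- max(1, window_samples %/% 2)
  lab <- labels$labels
  n <- length(lab)
  k <- nrow(tpl$maps)
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (t in seq_len(n)) {
      if (is.na(lab[t])) next
      score <- numeric(k)
      for (s in seq_len(k)) {
        cnt <- 0
        for (u in max(1, t - half):min(n, t + half))
          if (u != t && !is.na(lab[u]) && lab[u] == s) cnt <- cnt + 1
        score[s] <- c2[t, s] + factor * cnt / window_samples
      }
      new <- which.max(score)
      if (new != lab[t]) { lab[t] <- new; changed <- TRUE }
    }
    if (!changed) break
  }
  lab
}
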