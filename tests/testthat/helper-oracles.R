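# Independent oracles and small fixture builders used across test files.

# Literal per-iteration SNIP loop: at pass m, every interior channel is
# clipped to the mean of its m-distant neighbours from the PREVIOUS pass.
snip_oracle <- function(y, iterations) {
  n <- length(y)
  b <- y
  for (m in seq_len(iterations)) {
    if (2 * m >= n) break
    nb <- b
    for (i in (m + 1):(n - m)) {
      a <- (b[i - m] + b[i + m]) / 2
      if (a < b[i]) nb[i] <- a
    }
    b <- nb
  }
  b
}

# Exhaustive maximum simplex volume over all k-subsets of pixels, on the
# (k-1)-dimensional PCA scores.
brute_force_volume <- function(scan, k) {
  Y <- stats::prcomp(scan$pixels, center = TRUE, rank. = k - 1)$x
  combos <- utils::combn(nrow(scan$pixels), k)
  vols <- apply(combos, 2, function(ix) {
    abs(det(rbind(rep(1, k), t(Y[ix, , drop = FALSE])))) / factorial(k - 1)
  })
  list(volume = max(vols), idx = combos[, which.max(vols)])
}

# A gaussian band rendered on an axis (independent of the generator).
gauss_band <- function(axis, center, fwhm, amp) {
  amp * exp(-0.5 * ((axis - center) / (fwhm / (2 * sqrt(2 * log(2)))))^2)
}

# Hand-built score table for the worked aggregation example.
worked_score_table <- function() {
  score_table(data.frame(
    modality = "raman", protocol = "E_24", batch = 1L,
    observer = c("obs1", "obs1", "obs2", "obs2"),
    parameter = c("p1", "p2", "p1", "p2"),
    score = c(2L, 1L, 1L, 2L)))
}
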