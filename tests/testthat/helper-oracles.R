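# Independent reference implementations used to cross-check the production
# code paths. These deliberately use different mechanics from the package
# internals (full distance matrices instead of a pair loop; run-length
# bookkeeping instead of a stateful scan).

# Naive sample entropy via full Chebyshev distance matrices over the
# templates-with-extension index set.
naive_sampen <- function(x, m, r) {
  nt <- length(x) - m
  cheb <- function(len) {
    D <- matrix(0, nt, nt)
    for (k in 0:(len - 1)) {
      D <- pmax(D, abs(outer(x[(1:nt) + k], x[(1:nt) + k], "-")))
    }
    D
  }
  B <- (sum(cheb(m) <= r) - nt) / 2
  A <- (sum(cheb(m + 1) <= r) - nt) / 2
  -log(A / B)
}

# Exhaustive run-scan desaturation oracle: classify samples, bridge interior
# invalid runs no longer than gmax samples that are flanked by below-threshold
# samples, rejoin runs whose separating stretch is shorter than sep_n samples
# (with at most gmax invalid samples in it), then report maximal below runs of
# sufficient length.
oracle_detect <- function(spo2, valid, baseline, thr, min_samples, gmax,
                          sep_n = 3L) {
  state <- ifelse(!valid, "i", ifelse(spo2 <= baseline - thr, "b", "a"))
  r <- rle(state)
  k <- seq_along(r$values)
  interior <- k > 1 & k < length(r$values)
  bridge <- r$values == "i" & r$lengths <= gmax & interior &
    c("", head(r$values, -1)) == "b" & c(tail(r$values, -1), "") == "b"
  r$values[bridge] <- "b"
  rr <- rle(inverse.rle(r))
  ends <- cumsum(rr$lengths)
  starts <- ends - rr$lengths + 1L
  runs <- data.frame(start = starts[rr$values == "b"],
                     end = ends[rr$values == "b"])
  repeat {
    if (nrow(runs) < 2) break
    gap_len <- runs$start[-1] - runs$end[-nrow(runs)] - 1L
    gap_inv <- vapply(seq_len(nrow(runs) - 1), function(j) {
      sum(!valid[(runs$end[j] + 1L):(runs$start[j + 1L] - 1L)])
    }, numeric(1))
    j <- which(gap_len - gap_inv < sep_n & gap_inv <= gmax)
    if (!length(j)) break
    j <- j[1]
    runs$end[j] <- runs$end[j + 1L]
    runs <- runs[-(j + 1L), , drop = FALSE]
  }
  runs[runs$end - runs$start + 1L >= min_samples, , drop = FALSE]
}

# Short random recordings with invalid samples and occasional dips, for
# detector-vs-oracle comparisons.
random_short_recording <- function(n = NULL) {
  if (is.null(n)) n <- sample(20:200, 1)
  x <- 96 + cumsum(sample(c(-1, 0, 0, 1), n, replace = TRUE)) * 0.5
  ndip <- sample(0:3, 1)
  for (d in seq_len(ndip)) {
    len <- sample(1:8, 1)
    i0 <- sample(seq_len(max(1, n - len)), 1)
    x[i0:(i0 + len - 1)] <- x[i0:(i0 + len - 1)] - runif(1, 2, 8)
  }
  valid <- runif(n) > 0.08
  oximetry_recording(pmin(pmax(round(x), 0), 100), valid = valid)
}
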