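# Independent brute-force oracles used throughout the suite.  These are
# deliberately written as plain loops so that they share no code with
# the implementations they check.

# centered rolling median, shrinking at edges, interpolated median for
# even counts; even full windows one element heavier on the left
oracle_rolling_median <- function(x, w) {
  n <- length(x)
  left <- w %/% 2
  right <- w - 1 - left
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - left)
    hi <- min(n, i + right)
    v <- sort(x[lo:hi])
    m <- length(v)
    out[i] <- if (m %% 2 == 1) v[(m + 1) / 2] else
      (v[m / 2] + v[m / 2 + 1]) / 2
  }
  out
}

# maximal sub-threshold runs of length >= min_ep epochs, by linear scan
oracle_bouts <- function(metric, thr, min_ep) {
  out <- NULL
  s <- NA
  for (i in seq_along(metric)) {
    if (metric[i] < thr) {
      if (is.na(s)) s <- i
    } else if (!is.na(s)) {
      if (i - s >= min_ep) out <- rbind(out, c(s, i - 1))
      s <- NA
    }
  }
  if (!is.na(s) && length(metric) - s + 1 >= min_ep)
    out <- rbind(out, c(s, length(metric)))
  if (is.null(out)) data.frame(start = integer(), end = integer())
  else data.frame(start = out[, 1], end = out[, 2])
}

# transitive merge of sorted disjoint bouts with gaps < gap_ep epochs
oracle_merge <- function(bouts, gap_ep) {
  if (nrow(bouts) == 0)
    return(data.frame(start = integer(), end = integer(), n_bouts = integer()))
  res <- data.frame(start = bouts$start[1], end = bouts$end[1], n_bouts = 1L)
  for (i in seq_len(nrow(bouts))[-1]) {
    j <- nrow(res)
    if (bouts$start[i] - res$end[j] - 1L < gap_ep) {
      res$end[j] <- bouts$end[i]
      res$n_bouts[j] <- res$n_bouts[j] + 1L
    } else {
      res <- rbind(res, data.frame(start = bouts$start[i], end = bouts$end[i],
                                   n_bouts = 1L))
    }
  }
  res
}

# weighted 50% percentile with linear interpolation on the standardized
# cumulative weights, by explicit scan
oracle_weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(x[1])
  for (i in seq_along(s)[-1]) {
    if (s[i] >= 0.5)
      return(x[i - 1] + (x[i] - x[i - 1]) * (0.5 - s[i - 1]) / (s[i] - s[i - 1]))
  }
  x[length(x)]
}

# exact binomial upper tail by full enumeration of sign vectors (n <= 12)
oracle_sign_tail <- function(k, n) {
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  mean(rowSums(grid) >= k)
}
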