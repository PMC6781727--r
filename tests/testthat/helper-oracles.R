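# Independent brute-force oracles, deliberately naive and separate from the
# package's implementations.

# The nine series characteristics recomputed from first principles on the
# time-sorted truncated list.
oracle_summary <- function(times, values, cutoff) {
  keep <- which(times <= cutoff)
  if (length(keep) == 0) return(NULL)
  v <- values[keep][order(times[keep])]
  n <- length(v)
  mn <- v[1]; mx <- v[1]; imin <- 1; imax <- 1; s <- 0
  for (i in seq_len(n)) {
    if (v[i] < mn) { mn <- v[i]; imin <- i }
    if (v[i] > mx) { mx <- v[i]; imax <- i }
    s <- s + v[i]
  }
  m <- s / n
  sdv <- if (n == 1) 0 else sqrt(sum((v - m)^2) / (n - 1))
  last3 <- v[seq(max(1, n - 2), n)]
  fd <- if (n == 1) 0 else {
    d <- numeric(n - 1)
    for (i in 2:n) d[i - 1] <- v[i] - v[i - 1]
    mean(d)
  }
  list(n = n, mean = m, sd = sdv, min = mn, max = mx,
       idx_min_norm = imin / n, idx_max_norm = imax / n,
       mean_last3 = mean(last3), mean_first_diff = fd)
}

# All-pairs Mann-Whitney AUC, ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Kruskal-Wallis H from the rank formula with explicit tie correction.
oracle_kw <- function(values, groups) {
  g <- factor(groups)
  r <- rank(values)
  N <- length(values)
  ssum <- 0
  for (lev in levels(g)) {
    ri <- r[g == lev]
    ssum <- ssum + sum(ri)^2 / length(ri)
  }
  H <- 12 / (N * (N + 1)) * ssum - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr == 0) return(0)
  H / corr
}
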