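# Independent brute-force oracles used to check the package's
# implementations. Each is written as naively as possible and must stay
# independent of the code paths it checks.

# O(n^2) redundancy grouping: build the full pairwise adjacency
# (same chromosome, summit distance <= proximity), take connected
# components by BFS, and keep the member with the highest count
# (leftmost summit on ties) in each component.
dedup_oracle <- function(chrom, summit, count, proximity) {
  n <- length(summit)
  adj <- lapply(seq_len(n), function(i) {
    which(chrom == chrom[i] & abs(summit - summit[i]) <= proximity)
  })
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  keep <- vapply(split(seq_len(n), comp), function(idx) {
    best <- idx[count[idx] == max(count[idx])]
    best[order(summit[best])][1L]
  }, integer(1))
  sort(unname(keep))
}

# Step-up Benjamini-Hochberg, written directly from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  adj <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  q[o] <- pmin(adj, 1)
  q
}

# Hand product-limit estimator: survival at each distinct event time.
km_oracle <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = tt, surv = NA_real_)
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# Risk-table log-rank statistic with hypergeometric variance.
logrank_oracle <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  tt <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in tt) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(list(chisq = 0))
  list(chisq = (O - E)^2 / V)
}

# Small random scored-peak table on 1-2 chromosomes.
random_peaks <- function(n, chroms = c("chr1", "chr2"), span = 1e6,
                         width = 200) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(span, n)
  scored_peaks(chrom, start, start + width,
               raw_summit_count = sample.int(100, n, replace = TRUE))
}
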