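# Independent brute-force oracles used to cross-check the package's
# statistical routines. These deliberately avoid the code paths they test.

# Exhaustive hypergeometric upper tail: enumerate every |B|-subset of the
# background and count how many overlap A by at least `ov`.
bruteHypergeomTail <- function(N, a, b, ov) {
  A <- seq_len(a)
  subsets <- utils::combn(N, b)
  hits <- apply(subsets, 2, function(s) sum(s %in% A) >= ov)
  mean(hits)
}

# Sliding-window motif count, written without regex or Biostrings.
bruteKmerCount <- function(s, motif) {
  k <- nchar(motif)
  n <- nchar(s)
  if (n < k) return(0L)
  sum(vapply(seq_len(n - k + 1),
             function(i) substr(s, i, i + k - 1) == motif, logical(1)))
}

# Brute-force Benjamini-Hochberg: adjusted p_i = min over j with
# p_(j) >= p_(i) of p_(j) * m / j, capped at 1.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  adj
}

# Brute-force Holm step-down: cumulative max of p_(i) * (m - i + 1).
bruteHolm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, min(1, p[o[i]] * (m - i + 1)))
    adj[o[i]] <- run
  }
  adj
}

# Exact two-sided rank-sum p by complete enumeration of group splits.
bruteRankSumP <- function(x, y) {
  vals <- c(x, y)
  nx <- length(x)
  W <- sum(rank(vals)[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(length(vals), nx)
  Wnull <- apply(splits, 2, function(idx)
    sum(rank(vals)[idx]) - nx * (nx + 1) / 2)
  pl <- mean(Wnull <= W)
  pu <- mean(Wnull >= W)
  min(1, 2 * min(pl, pu))
}

# Small synthetic fixtures shared across test files.
smallGeometry <- function(n = 30, seed = 1) makeGeometry(n, "sphere", seed = seed)
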