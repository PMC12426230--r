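# Independent oracles, kept deliberately naive: loops and enumeration, no
# shared code with the implementation under test.

# Step-up FDR adjustment by direct definition: for sorted p, the adjusted
# value at rank i is the minimum of p_(j) * m / j over all ranks j >= i.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * (m / j))
    q[i] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Pearson chi-square by cell-wise loops.
chisq_bruteforce <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, p_value = pchisq(stat, df, lower.tail = FALSE))
}

# Exact two-sided Wilcoxon p by enumeration of all group labelings.
wilcox_enumerate <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  labelings <- utils::combn(n1 + n2, n1)
  us <- apply(labelings, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  lower <- mean(us <= u_obs)
  upper <- mean(us >= u_obs)
  min(1, 2 * min(lower, upper))
}
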