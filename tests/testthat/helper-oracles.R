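# Independent statistical oracles used to cross-check the package's
# implementations.  They are deliberately written from first principles
# (explicit binomial-coefficient arithmetic, hand-coded rank statistics)
# rather than reusing the code paths they validate.

# Two-sided Fisher p-value by exhaustive enumeration of all 2x2 tables
# with the observed margins; point probabilities from log binomial
# coefficients.
oracle_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + c   # altered margin
  c1 <- a + b   # group margin
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  ks <- lo:hi
  logp <- lchoose(c1, ks) + lchoose(n - c1, r1 - ks) - lchoose(n, r1)
  p <- exp(logp)
  p_obs <- p[ks == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Tie-corrected Kruskal-Wallis H statistic evaluated by the direct formula.
oracle_kw <- function(values, groups) {
  groups <- as.factor(groups)
  n_tot <- length(values)
  r <- rank(values)
  rsum <- tapply(r, groups, sum)
  ng <- tapply(r, groups, length)
  h <- 12 / (n_tot * (n_tot + 1)) * sum(rsum^2 / ng) - 3 * (n_tot + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n_tot^3 - n_tot)
  h <- h / corr
  list(statistic = h,
       p_value = stats::pchisq(h, nlevels(groups) - 1, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up evaluated by hand (sort, scale, cummin,
# unsort).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Pearson chi-square statistic/p evaluated by the direct formula.
oracle_chisq <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
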