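# Independent oracles, written from first principles and kept separate from
# the package code paths they check.

# Kruskal-Wallis by the textbook rank formula with tie correction.
oracle_kw <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) sum(x)^2 / length(x))) - 3 * (N + 1)
  t <- table(values)
  C <- 1 - sum(t^3 - t) / (N^3 - N)
  H / C
}

# Two-sided normal-approximation Wilcoxon rank-sum p (no continuity
# correction), for cross-checking the two-group KW chi-square p.
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2
  sigma <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  2 * pnorm(-abs((W - mu) / sigma))
}

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration over all
# tables with the observed margins.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(support, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Spearman rho and t-approximation p from first principles (average ranks).
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), n - 2))
}

# Exhaustive re-derivation of the high-confidence filter decision for one
# site's level vector.
oracle_filter_decision <- function(lv, is_known, min_level, min_samples) {
  n_pass <- 0L
  for (v in lv) if (!is.na(v) && v >= min_level) n_pass <- n_pass + 1L
  n_pass >= min_samples || is_known
}
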