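# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths.

# AUC as the pair-counting estimator: P(pos > neg) + 0.5 P(pos == neg),
# computed by explicit enumeration of all (pos, neg) pairs.
oracle_auc_paircount <- function(pos, neg) {
  g <- expand.grid(p = pos, n = neg)
  mean((g$p > g$n) + 0.5 * (g$p == g$n))
}

# Exhaustive Youden scan over candidate thresholds (observed values plus
# sentinels), positivity rule od >= t, ties broken to the lowest
# threshold.
oracle_youden <- function(pos, neg) {
  obs <- sort(unique(c(pos, neg)))
  cand <- c(obs[1] - 1, obs, obs[length(obs)] + 1)
  j <- vapply(cand, function(t) mean(pos >= t) - mean(neg >= t), numeric(1))
  i <- which(j >= max(j) - 1e-12)[1]
  list(value = cand[i], j = j[i])
}

# Textbook Welch t: statistic, Satterthwaite df, one-sided lower-tail p.
oracle_welch <- function(s, h) {
  n1 <- length(s); n2 <- length(h)
  v1 <- var(s); v2 <- var(h)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(s) - mean(h)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = pt(t, df))
}

# Exhaustive permutation p-value of the Welch t statistic over all
# reassignments of replicates to arms (lower tail, observed included).
oracle_perm_p <- function(s, h) {
  all <- c(s, h); n1 <- length(s)
  idx <- utils::combn(length(all), n1)
  tstat <- function(a, b) {
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }
  t_obs <- tstat(s, h)
  t_perm <- apply(idx, 2, function(ii) tstat(all[ii], all[-ii]))
  mean(t_perm <= t_obs + 1e-12)
}

# Forward 4PL, written independently of the package internals.
oracle_fpl <- function(conc, lower, upper, ec50, hill) {
  lower + (upper - lower) / (1 + (ec50 / conc)^hill)
}

# Numeric arc length of r = a + b*theta by adaptive quadrature.
oracle_arc_length <- function(a, b, th0, th1) {
  integrate(function(th) sqrt((a + b * th)^2 + b^2), th0, th1,
            rel.tol = 1e-10)$value
}
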