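# Independent brute-force oracles used to pin down the package's exact
# tests.  Each is implemented from a different formulation than the
# package code it checks.

# Hardy-Weinberg exact p by counting arrangements: conditional on the
# allele counts, the number of ways to seat n individuals with h
# heterozygotes is choose(n, AA) * choose(n - AA, h) * 2^h.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- n_Aa + 2 * n_aa
  n_A <- n_Aa + 2 * n_AA
  if (n_a == 0 || n_A == 0) return(1)
  hs <- seq(min(n_a, n_A) %% 2, min(n_a, n_A), by = 2)
  logw <- vapply(hs, function(h) {
    AA <- (n_A - h) / 2
    lchoose(n, AA) + lchoose(n - AA, h) + h * log(2)
  }, numeric(1))
  w <- exp(logw - max(logw))
  pr <- w / sum(w)
  obs <- pr[match(n_Aa, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Fisher two-sided p by direct hypergeometric enumeration over all tables
# with the observed margins.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b          # foreground size
  k <- a + c          # total overlaps
  n_tot <- a + b + c + d
  xs <- max(0, k - (n_tot - m)):min(k, m)
  pr <- dhyper(xs, m, n_tot - m, k)
  obs <- dhyper(a, m, n_tot - m, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Exact signed-rank two-sided p by enumerating all 2^n sign assignments.
wilcoxon_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d), ties.method = "average")
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# OLS by explicit normal equations, with coefficient standard errors and
# two-sided t-test p-values.
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- drop(beta) / se
  list(beta = drop(beta), se = se, t = tval,
       p = 2 * pt(-abs(tval), df), df = df)
}
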