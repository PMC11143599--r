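## Vectorized two-sided Wilcoxon rank-sum (normal approximation with tie
## correction and continuity correction) for many features against one
## group split. Precomputing ranks lets label permutations reuse them.

row_ranks <- function(X) t(apply(X, 1, rank))

## per-row tie term sum(t^3 - t) needed by the variance formula
row_tie_term <- function(R) {
  apply(R, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  })
}

## R: precomputed ranks (features x samples); g: logical group indicator.
## Returns two-sided p-values.
ranksum_p <- function(R, g, tie_term = row_tie_term(R)) {
  n <- ncol(R)
  n1 <- sum(g)
  n2 <- n - n1
  if (n1 == 0 || n2 == 0) stop("empty group in rank-sum test")
  W <- as.numeric(R %*% g)
  mu <- n1 * (n + 1) / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  sigma <- sqrt(pmax(sigma2, 0))
  z <- ifelse(sigma > 0, (W - mu - sign(W - mu) * 0.5) / sigma, 0)
  2 * stats::pnorm(-abs(z))
}
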