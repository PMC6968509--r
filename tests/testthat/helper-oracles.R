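# Independent oracles, deliberately written without reusing package code.

## NIPALS PLS1: full deflation algorithm, fitted response on the
## centred scale
oraclePls1 <- function(X, y, ncomp) {
  X <- sweep(X, 2, colMeans(X))
  f <- y - mean(y)
  That <- NULL
  qv <- numeric(0)
  E <- X
  for (k in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    t <- drop(E %*% w)
    p <- drop(crossprod(E, t)) / sum(t^2)
    q <- sum(f * t) / sum(t^2)
    E <- E - tcrossprod(t, p)
    f <- f - t * q
    That <- cbind(That, t)
    qv <- c(qv, q)
  }
  drop(That %*% qv)
}

## exact two-sided Mann-Whitney p by full enumeration of rank
## assignments (untied data only)
oracleWilcoxExact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  ranks <- rank(c(a, b))
  uObs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  allRanks <- seq_len(n1 + n2)
  us <- apply(combos, 2, function(ix) sum(allRanks[ix])) - n1 * (n1 + 1) / 2
  center <- n1 * n2 / 2
  mean(abs(us - center) >= abs(uObs - center) - 1e-9)
}

## sample covariance eigendecomposition (PCA oracle)
oracleCovEigen <- function(X) {
  eigen(stats::cov(X), symmetric = TRUE)
}

## direct trapezoidal integral
oracleTrapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
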