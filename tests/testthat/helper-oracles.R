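# Independent scalar oracles used across the suite. These deliberately share
# no code with the package: plain loops and brute-force integration.

# Grey relational analysis, re-derived step by step with explicit loops.
gra_oracle <- function(scores, alpha = 0.5, weights = NULL) {
  m <- nrow(scores); n <- ncol(scores)
  if (is.null(weights)) weights <- rep(1 / n, n)
  x <- matrix(NA_real_, m, n)
  for (j in seq_len(n)) {
    lo <- min(scores[, j]); hi <- max(scores[, j])
    for (i in seq_len(m)) x[i, j] <- (scores[i, j] - lo) / (hi - lo)
  }
  delta <- abs(1 - x)
  dmin <- min(delta); dmax <- max(delta)
  co <- matrix(NA_real_, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      co[i, j] <- (dmin + alpha * dmax) / (delta[i, j] + alpha * dmax)
    }
  }
  grades <- numeric(m)
  for (i in seq_len(m)) grades[i] <- sum(weights * co[i, ])
  grades
}

# Squared-exponential kernel matrix written independently.
se_kern_oracle <- function(X1, X2, ell, sf) {
  K <- matrix(NA_real_, nrow(X1), nrow(X2))
  for (i in seq_len(nrow(X1))) {
    for (j in seq_len(nrow(X2))) {
      K[i, j] <- sf^2 * exp(-0.5 * sum((X1[i, ] - X2[j, ])^2 / ell^2))
    }
  }
  K
}

# Exact log marginal likelihood of a 3-point logistic GP classifier by dense
# trapezoidal integration. Integration runs in whitened coordinates f = L z
# (K = L L'), so the grid stays accurate even when K is nearly singular:
# log Z = log \int N(z; 0, I) prod_i sigma(y_i (Lz)_i) dz.
gp_logZ_oracle <- function(K, y, lim = 8, npts = 121L) {
  stopifnot(length(y) == 3L)
  g <- seq(-lim, lim, length.out = npts)
  h <- g[2] - g[1]
  Z <- as.matrix(expand.grid(z1 = g, z2 = g, z3 = g))
  L <- t(chol(K))
  F <- Z %*% t(L)
  logdens <- -0.5 * rowSums(Z^2) - 1.5 * log(2 * pi)
  loglik <- plogis(F[, 1] * y[1], log.p = TRUE) +
    plogis(F[, 2] * y[2], log.p = TRUE) +
    plogis(F[, 3] * y[3], log.p = TRUE)
  log(sum(exp(logdens + loglik))) + 3 * log(h)
}

# Exact predictive probability at one test point: outer trapezoidal sum over
# the whitened 3-D latent posterior, inner trapezoidal integral of the
# logistic over the conditional Gaussian at the test point.
gp_pred_oracle <- function(K, kstar, kss, y, lim = 8, npts = 81L) {
  g <- seq(-lim, lim, length.out = npts)
  Z <- as.matrix(expand.grid(z1 = g, z2 = g, z3 = g))
  L <- t(chol(K))
  F <- Z %*% t(L)
  logdens <- -0.5 * rowSums(Z^2)
  loglik <- plogis(F[, 1] * y[1], log.p = TRUE) +
    plogis(F[, 2] * y[2], log.p = TRUE) +
    plogis(F[, 3] * y[3], log.p = TRUE)
  wpost <- exp(logdens + loglik)
  Kinv_ks <- solve(K, kstar)
  mstar <- drop(F %*% Kinv_ks)
  vstar <- max(kss - sum(kstar * Kinv_ks), 1e-12)
  zg <- seq(-8, 8, by = 0.2)
  hz <- zg[2] - zg[1]
  esig <- numeric(nrow(F))
  for (t in zg) {
    esig <- esig + plogis(mstar + sqrt(vstar) * t) * dnorm(t) * hz
  }
  sum(wpost * esig) / sum(wpost)
}
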