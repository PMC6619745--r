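# Independent oracles, deliberately implemented by routes different from the
# package's own code paths.

# plain-loop trapezoid cumulative integral
cumtrapz_loop <- function(t, y) {
  out <- numeric(length(y))
  for (i in 2:length(y)) {
    out[i] <- out[i - 1] + (t[i] - t[i - 1]) * (y[i] + y[i - 1]) / 2
  }
  out
}

# marginal Gaussian log-likelihood of the random-intercept model at fixed
# variance components, via dense covariance matrices and solve()
lme_loglik_direct <- function(y, X, groups, sigma2_b, sigma2_e) {
  g <- factor(groups)
  Z <- stats::model.matrix(~ g - 1)
  V <- sigma2_e * diag(length(y)) + sigma2_b * tcrossprod(Z)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (length(y) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       t(r) %*% Vi %*% r))
}

# brute-force ML: grid over (sigma2_b, sigma2_e) with two refinement passes
lme_grid_oracle <- function(y, X, groups, passes = 3, n_grid = 25) {
  v <- stats::var(y)
  b_rng <- c(1e-8, 2 * v)
  e_rng <- c(1e-8 * v, 2 * v)
  best <- c(NA, NA, -Inf)
  for (p in seq_len(passes)) {
    bg <- seq(b_rng[1], b_rng[2], length.out = n_grid)
    eg <- seq(e_rng[1], e_rng[2], length.out = n_grid)
    ll <- outer(bg, eg, Vectorize(function(b, e) lme_loglik_direct(y, X, groups, b, e)))
    ix <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(bg[ix[1]], eg[ix[2]], max(ll))
    db <- diff(b_rng) / (n_grid - 1); de <- diff(e_rng) / (n_grid - 1)
    b_rng <- c(max(0, bg[ix[1]] - db), bg[ix[1]] + db)
    e_rng <- c(max(1e-12, eg[ix[2]] - de), eg[ix[2]] + de)
  }
  list(sigma2_b = best[1], sigma2_e = best[2], loglik = best[3])
}

# penalised least squares via the augmented-regression route: append the
# matrix square root of lambda * P to the design and use qr.solve
penalised_ridge_oracle <- function(B, P, y, lambda) {
  ep <- eigen(P, symmetric = TRUE)
  L <- ep$vectors %*% (sqrt(pmax(ep$values, 0)) * t(ep$vectors))
  qr.solve(rbind(B, sqrt(lambda) * L), c(y, numeric(nrow(P))))
}

# discrete PCA proportions of a samples-x-variables matrix (covariance,
# uncentred scale), by eigen of the covariance matrix
discrete_pca_prop <- function(X) {
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev / sum(ev)
}
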