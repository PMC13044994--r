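# Shared fixtures and independent oracles, built in code at test time.

# simple exponential regression dataset
make_exp_data <- function(N = 120, beta0 = -1, beta1 = 0.7, seed = 1,
                          cens_rate = 0) {
  set.seed(seed)
  z <- rnorm(N)
  t_ev <- rexp(N, exp(beta0 + beta1 * z))
  if (cens_rate > 0) {
    cc <- rexp(N, cens_rate)
    data.frame(time = pmin(t_ev, cc), status = as.numeric(t_ev <= cc), z = z)
  } else {
    data.frame(time = t_ev, status = 1, z = z)
  }
}

fixed_partition <- function(S) {
  structure(list(S = S, J = length(S) - 1L), class = "interval_partition")
}

# Dense joint-Gaussian oracle for the random-walk state-space model:
# beta_0 ~ N(a0, diag(P0)); beta_j = beta_{j-1} + N(0, diag(Q)); observations
# x = H vec(beta_{0:J}) + N(0, diag(v)). Returns the exact posterior mean,
# covariance, and marginal log-likelihood of x.
dense_ssm_oracle <- function(x, v, Zmat, interval, J, Q, a0, P0 = Q) {
  p <- length(Q)
  dim_tot <- (J + 1L) * p
  # prior: Cov(beta_j, beta_j') = diag(P0) + min(j, j') * diag(Q)
  Sig <- matrix(0, dim_tot, dim_tot)
  for (j in 0:J) for (jp in 0:J) {
    block <- diag(P0, p) + min(j, jp) * diag(Q, p)
    Sig[j * p + 1:p, jp * p + 1:p] <- block
  }
  mu <- rep(a0, J + 1L)
  H <- matrix(0, length(x), dim_tot)
  for (m in seq_along(x)) {
    H[m, interval[m] * p + 1:p] <- Zmat[m, ]
  }
  S_obs <- H %*% Sig %*% t(H) + diag(v, length(x))
  K <- Sig %*% t(H) %*% solve(S_obs)
  post_mean <- mu + drop(K %*% (x - drop(H %*% mu)))
  post_cov <- Sig - K %*% H %*% Sig
  ll <- mvn_logdens(x, drop(H %*% mu), S_obs)
  list(mean = matrix(post_mean, J + 1L, p, byrow = TRUE),
       cov = post_cov, loglik = ll)
}

mvn_logdens <- function(x, mu, Sigma) {
  R <- chol(Sigma)
  r <- backsolve(R, x - mu, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi)) - sum(log(diag(R))) - 0.5 * sum(r^2)
}

# minimal dsm_fit-like object for prediction tests: beta_draws is a
# n_draws x (J+1) x (K+1) array of coefficient paths
fake_fit <- function(beta_draws, S, covariate_names = "z",
                     theta = NULL, variance_floor = 1e-12) {
  n_draws <- dim(beta_draws)[1L]
  p <- dim(beta_draws)[3L]
  structure(list(
    draws = list(beta = beta_draws,
                 theta = if (is.null(theta)) {
                   matrix(variance_floor, n_draws, p)
                 } else theta),
    n_draws = n_draws,
    partition = fixed_partition(S),
    dataset = list(covariate_names = covariate_names,
                   K = length(covariate_names)),
    factor = FALSE, G = 0L,
    config = list(variance_floor = variance_floor)
  ), class = "dsm_fit")
}

# two-sample KS rejection helper (alpha = 0.01)
ks_reject <- function(x, y_or_cdf, ...) {
  suppressWarnings(stats::ks.test(x, y_or_cdf, ...)$p.value) < 0.01
}
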