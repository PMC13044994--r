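test_that("the shipped Gumbel mixture satisfies its quality invariants", {
  mix <- gumbel_mixture()
  expect_equal(mix$R, 10L)
  expect_equal(sum(mix$w), 1, tolerance = 1e-8)
  mom <- dynshrink:::mixture_moments(mix)
  expect_equal(unname(mom["mean"]), -digamma(1), tolerance = 0.01)
  expect_equal(unname(mom["var"]), pi^2 / 6, tolerance = 0.02)
  grid <- seq(-10, 15, length.out = 20000)
  expect_lt(max(abs(dynshrink:::mixture_cdf(mix, grid) - exp(-exp(-grid)))), 0.01)
})

test_that("the run-time KL fit reproduces the cached table", {
  # mixture parameters are only weakly identified along the EM path, so the
  # comparison is distributional: the refit and the cached table must define
  # nearly the same law
  refit <- gumbel_mixture("kl_fit", iters = 400L)
  tab <- gumbel_mixture("table")
  grid <- seq(-10, 15, length.out = 5000)
  expect_lt(max(abs(dynshrink:::mixture_cdf(refit, grid) -
                    dynshrink:::mixture_cdf(tab, grid))), 0.01)
  mom_r <- dynshrink:::mixture_moments(refit)
  mom_t <- dynshrink:::mixture_moments(tab)
  expect_lt(max(abs(mom_r - mom_t)), 0.01)
})

test_that("residual survival times complete censored exposures exponentially", {
  df <- data.frame(time = c(3, 5), status = c(1, 0), z = c(0, 0))
  sd <- survival_data(df, covariates = "z")
  ex <- expand_survival(sd, fixed_partition(c(0, 2, 6)))
  set.seed(1)
  tau <- draw_residual_times(ex, rep(2, nrow(ex$pairs)))
  ev <- ex$pairs$event
  expect_equal(tau[ev], ex$pairs$exposure[ev])        # events: tau = u exactly
  expect_true(all(tau[!ev] > ex$pairs$exposure[!ev])) # censored: tau > u
  # huge hazard: residual collapses
  tau_big <- draw_residual_times(ex, rep(1e12, nrow(ex$pairs)))
  expect_equal(tau_big, ex$pairs$exposure, tolerance = 1e-6)
  expect_error(draw_residual_times(ex, rep(-1, nrow(ex$pairs))), "non-positive hazard")
  # distribution: tau - u ~ Exponential(2) at fixed hazard 2
  dfc <- data.frame(time = rep(1, 4000), status = 0)
  sdc <- survival_data(dfc)
  exc <- expand_survival(sdc, fixed_partition(c(0, 1)))
  set.seed(2)
  resid <- draw_residual_times(exc, rep(2, 4000)) - 1
  expect_false(ks_reject(resid, "pexp", rate = 2))
})

test_that("mixture indicators follow the normalized component posteriors", {
  mix <- gumbel_mixture()
  # analytic posterior at a fixed residual e = 0.5 (linpred 0, tau = e^-0.5)
  e <- 0.5
  probs <- mix$w * dnorm(e, mix$m, sqrt(mix$v))
  probs <- probs / sum(probs)
  set.seed(3)
  n <- 40000
  r <- draw_mixture_indicators(rep(exp(-e), n), rep(0, n), mix)
  freq <- tabulate(r, 10) / n
  expect_lt(max(abs(freq - probs)), 4 * max(sqrt(probs * (1 - probs) / n)) + 1e-3)
  # dominant-likelihood selection: residual at a component mean, tiny variance
  mix2 <- dynshrink:::new_mixture(mix$w, mix$m, rep(1e-10, 10), "spiky")
  r2 <- draw_mixture_indicators(exp(-mix$m[4]), 0, mix2)
  expect_equal(r2, 4L)
  expect_error(draw_mixture_indicators(c(-1, 1), c(0, 0), mix), "non-finite")
})

test_that("pseudo-observations are consistent with their defining identity", {
  mix <- gumbel_mixture()
  set.seed(4)
  tau <- rexp(200) + 0.05
  r <- sample.int(10, 200, replace = TRUE)
  ps <- build_pseudo_observations(tau, r, mix)
  expect_equal(ps$x, -log(tau) - mix$m[r])
  expect_equal(ps$v, mix$v[r])
  # tau = 1 with a zero-mean component gives x = 0
  mix0 <- dynshrink:::new_mixture(mix$w, c(0, mix$m[-1]), mix$v, "m1zero")
  expect_equal(build_pseudo_observations(1, 1L, mix0)$x, 0)
  expect_error(build_pseudo_observations(c(1, -2), c(1L, 1L), mix), "non-positive")
})

test_that("integrating out the augmentation recovers the exact likelihood", {
  # 3 subjects, 2 intervals: log E[prod Gumbel-density ratios] equals the
  # piecewise-exponential log-likelihood
  df <- data.frame(time = c(0.8, 1.4, 2.0), status = c(1, 0, 1), z = c(-1, 0, 1))
  sd <- survival_data(df, covariates = "z")
  ex <- expand_survival(sd, fixed_partition(c(0, 1, 2)))
  Zp <- cbind(1, sd$Z[ex$pairs$subject, , drop = FALSE])
  beta <- c(-0.3, 0.4)
  lin <- drop(Zp %*% beta)
  exact <- piecewise_exp_loglik(ex, exp(lin))
  set.seed(5)
  n_mc <- 4000
  ev <- ex$pairs$event
  u <- ex$pairs$exposure
  mix <- gumbel_mixture()
  mix_logdens <- function(e) {
    d <- 0
    for (r in 1:10) d <- d + mix$w[r] * dnorm(e, mix$m[r], sqrt(mix$v[r]))
    log(d)
  }
  lr <- replicate(n_mc, {
    tau <- draw_residual_times(ex, exp(lin))
    eps <- -log(tau) - lin
    # complete-data density under the 10-component Gaussian approximation,
    # over the proposal density of the residual draws (events contribute
    # their density directly)
    num <- sum(mix_logdens(eps) - log(tau))
    den <- sum(dexp((tau - u)[!ev], exp(lin)[!ev], log = TRUE))
    num - den
  })
  mc <- max(lr) + log(mean(exp(lr - max(lr))))
  expect_equal(mc, exact, tolerance = 0.02)
})

test_that("augmented residuals follow the standard Gumbel law", {
  set.seed(6)
  N <- 3000
  df <- data.frame(time = rexp(N, exp(0.4)), status = 1)
  sd <- survival_data(df)
  ex <- expand_survival(sd, build_partition(sd$y, 2, max(sd$y)))
  lin <- rep(0.4, nrow(ex$pairs))
  tau <- draw_residual_times(ex, exp(lin))
  eps <- -log(tau) - lin
  expect_lt(abs(mean(eps) + digamma(1)), 4 * sqrt(pi^2 / 6 / length(eps)))
  expect_equal(var(eps), pi^2 / 6, tolerance = 0.1)
})
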