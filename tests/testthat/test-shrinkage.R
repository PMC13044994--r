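test_that("prior replicates respect supports and the horseshoe special case", {
  set.seed(30)
  reps <- sample_prior_replicates(4, n = 500)
  expect_true(all(reps$theta > 0))
  expect_true(all(reps$lam_theta > 0 & reps$tau_theta > 0))
  expect_true(all(reps$a_theta > 0 & reps$a_theta < 0.5))
  expect_true(all(reps$c_beta > 0 & reps$c_beta < 0.5))
  # a = c = 0.5 fixed puts an F(1,1) scale on the lambda layer (horseshoe):
  # |beta| tails are heavier than Gaussian
  hs <- ngg_hyper(learn_a = FALSE, learn_c = FALSE, a_fixed = 0.5, c_fixed = 0.5)
  set.seed(31)
  rb <- sample_prior_replicates(1, hyper_beta = hs, n = 20000)$beta
  kurt <- mean((rb - mean(rb))^4) / var(rb)^2 - 3
  expect_gt(kurt, 0)
})

test_that("the gamma-ratio construction matches direct F sampling", {
  set.seed(32)
  a <- 0.3; c <- 0.2
  hy <- ngg_hyper(learn_a = FALSE, learn_c = FALSE, a_fixed = a, c_fixed = c)
  lam <- sample_prior_replicates(1, hyper_theta = hy, n = 20000)$lam_theta
  expect_false(ks_reject(lam, "pf", df1 = 2 * a, df2 = 2 * c))
})

test_that("initial-mean conjugate draws obey their limits and moments", {
  set.seed(33)
  # flat-prior limit: the posterior mean goes to beta_k0
  b <- mean(replicate(4000, sample_initial_means(beta0 = 2, theta = 1,
                                                 lam = 1e12, tau = 1)))
  expect_equal(b, 2, tolerance = 0.08)
  # point-mass-prior limit: posterior collapses to zero
  b0 <- sample_initial_means(beta0 = 2, theta = 1, lam = 1e-14, tau = 1)
  expect_equal(b0, 0, tolerance = 1e-4)
  # finite case: precision 2, mean 1, variance 0.5
  draws <- replicate(20000, sample_initial_means(2, 1, 1, 1))
  expect_equal(mean(draws), 1, tolerance = 4 * sqrt(0.5 / 20000))
  expect_equal(var(draws), 0.5, tolerance = 0.02)
})

test_that("the centered variance draw matches 1-D quadrature", {
  # one-state toy: J = 1, K = 0; conditional of theta given the path is
  # proportional to theta^(1/2-1) e^(-theta/(2 lam tau)) x RW likelihood
  states <- matrix(c(0.8, 1.1), 2, 1)
  bm <- 0.2; lam <- 0.7; tau <- 1.3
  set.seed(34)
  draws <- replicate(40000, sample_theta_centered(states, bm, lam, tau))
  chi <- (0.8 - 0.2)^2 + (1.1 - 0.8)^2
  g <- seq(1e-6, quantile(draws, 0.9995), length.out = 20000)
  ld <- (0.5 - 1) * log(g) - g / (2 * lam * tau) - (2 / 2) * log(g) - chi / (2 * g)
  d <- exp(ld - max(ld)); d <- d / sum(d)
  h <- hist(draws[draws <= max(g)], breaks = 120, plot = FALSE)
  emp <- h$counts / length(draws)
  thr <- vapply(seq_along(h$mids), function(i) {
    sum(d[g >= h$breaks[i] & g < h$breaks[i + 1]])
  }, numeric(1))
  expect_lt(0.5 * sum(abs(emp - thr)), 0.02)  # total-variation distance
})

test_that("local/global conditionals replicate the prior when run with no data", {
  # successive-conditional check: hierarchy drawn from the prior, theta
  # regenerated, one application of the package conditional; outputs are iid
  # and must still follow the F priors
  set.seed(35)
  a <- 0.3; c <- 0.2; K <- 3
  hy <- ngg_hyper(learn_a = FALSE, learn_c = FALSE, a_fixed = a, c_fixed = c)
  n_rep <- 8000L
  lam_out <- numeric(n_rep); tau_out <- numeric(n_rep)
  blk <- dynshrink:::ngg_block_init(K, hy)
  for (i in seq_len(n_rep)) {
    blk$lam <- rgamma(K, a, rate = a) / rgamma(K, c, rate = c)
    blk$tau <- rgamma(1, c, rate = c) / rgamma(1, a, rate = a)
    blk$kappa <- rgamma(K, a + c, rate = c + a * blk$lam)
    blk$kappa_tau <- rgamma(1, a + c, rate = a + c * blk$tau)
    theta <- rgamma(K, 0.5, rate = 1 / (2 * blk$lam * blk$tau))
    blk <- sample_local_global(theta, blk, hy)
    lam_out[i] <- blk$lam[2]; tau_out[i] <- blk$tau
  }
  expect_false(ks_reject(lam_out, "pf", df1 = 2 * a, df2 = 2 * c))
  expect_false(ks_reject(tau_out, "pf", df1 = 2 * c, df2 = 2 * a))
  expect_true(all(lam_out > 0) && all(tau_out > 0))
})

test_that("stronger coefficients push the global scale up", {
  set.seed(36)
  hy <- ngg_hyper()
  med_tau <- function(beta) {
    blk <- dynshrink:::ngg_block_init(length(beta), hy)
    taus <- replicate(800, {
      blk <<- sample_local_global(beta^2, blk, hy)
      blk$tau
    })
    median(taus[-(1:200)])
  }
  beta <- c(0.2, -0.4, 0.3, -0.1)
  expect_gt(med_tau(10 * beta), med_tau(beta))
})

test_that("pole/tail MH respects learn flags, support, and its prior", {
  hy <- ngg_hyper(learn_a = FALSE)
  res <- sample_pole_tail_mh(0.2, 0.3, "a", lam = c(1, 2), tau = 1, hy)
  expect_equal(res$value, 0.2)
  expect_false(res$attempted)
  # prior-only chain recovers the scaled-beta prior of 2a
  set.seed(37)
  hy2 <- ngg_hyper(alpha_a = 5, beta_a = 10)
  a <- 0.25
  tr <- numeric(20000)
  for (t in seq_along(tr)) {
    res <- sample_pole_tail_mh(a, 0.25, "a", lam = 1, tau = 1, hy2,
                               prior_only = TRUE)
    a <- res$value
    tr[t] <- a
  }
  expect_true(all(tr > 0 & tr < 0.5))
  keep <- 2 * tr[seq(2000, 20000, by = 20)]
  expect_false(ks_reject(keep, "pbeta", shape1 = 5, shape2 = 10))
})

test_that("the interweaved NCP draw tracks a strong constant signal", {
  # theta ~ 0 with a nonzero level: the joint (mean, scale) draw must place
  # the level at the GLS fit rather than pinning it at the old mean
  set.seed(38)
  J <- 6L; n <- 240
  itv <- rep(1:J, each = n / J)
  Z <- matrix(1, n, 1)
  x <- rnorm(n, 1.5, 0.4)
  states <- matrix(0, J + 1, 1)
  out <- sample_theta_ncp(states, beta_mean = 0, theta = 1e-12, x = x,
                          v = rep(0.16, n), Zmat = Z, interval = itv,
                          lam = 1, tau = 1, lam_beta = 1e6, tau_beta = 1,
                          variance_floor = 1e-12)
  expect_equal(out$beta_mean, 1.5, tolerance = 0.1)
  expect_true(all(out$theta >= 1e-12))
  expect_equal(dim(out$states), dim(states))
})
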