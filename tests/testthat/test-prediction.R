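test_that("constant-hazard draws give exponential predictive times", {
  # one stored draw with flat coefficient path: lambda = exp(beta0)
  lam <- 0.8
  S <- c(0, 1, 2, 3)
  beta <- array(0, c(1, 4, 2))
  beta[1, , 1] <- log(lam)
  fit <- fake_fit(beta, S)
  set.seed(60)
  pred <- predict_survival_times(fit, data.frame(z = 0), n_pred = 40000)
  tms <- drop(pred$times)
  expect_true(all(tms > 0))
  expect_equal(median(tms), log(2) / lam, tolerance = 0.05)
  expect_false(ks_reject(tms, "pexp", rate = lam))
  # risk score: minus the mean survival time = -1/lambda
  set.seed(61)
  rs <- risk_score(fit, data.frame(z = 0), n_pred = 40000)
  expect_equal(rs, -1 / lam, tolerance = 0.03)
})

test_that("predictive times shift stochastically with the hazard scale", {
  S <- c(0, 2, 4)
  beta <- array(0, c(1, 3, 2))
  fit1 <- fake_fit(beta, S)           # lambda = 1
  beta4 <- beta; beta4[1, , 1] <- log(4)
  fit4 <- fake_fit(beta4, S)
  set.seed(62)
  t1 <- drop(predict_survival_times(fit1, data.frame(z = 0), n_pred = 30000)$times)
  t4 <- drop(predict_survival_times(fit4, data.frame(z = 0), n_pred = 30000)$times)
  expect_equal(median(t4) / median(t1), 1 / 4, tolerance = 0.05)
  set.seed(63)
  r1 <- risk_score(fit1, data.frame(z = 0), n_pred = 20000)
  r4 <- risk_score(fit4, data.frame(z = 0), n_pred = 20000)
  expect_gt(r4, r1)  # uniformly higher hazard, strictly larger risk
})

test_that("the predictive mean matches quadrature for a 3-interval hazard", {
  S <- c(0, 1, 2.5, 4)
  lam_path <- c(0.3, 1.1, 0.6)
  beta <- array(0, c(1, 4, 2))
  beta[1, 2:4, 1] <- log(lam_path)
  fit <- fake_fit(beta, S)
  # closed form: E[T] = int S(t) dt over the grid + tail S(s_J)/lambda_J
  Sfun <- function(t) {
    H <- ifelse(t <= 1, 0.3 * t,
         ifelse(t <= 2.5, 0.3 + 1.1 * (t - 1), 0.3 + 1.1 * 1.5 + 0.6 * (t - 2.5)))
    exp(-H)
  }
  expected <- integrate(Sfun, 0, 4)$value + Sfun(4) / 0.6
  set.seed(64)
  tms <- drop(predict_survival_times(fit, data.frame(z = 0), n_pred = 60000)$times)
  expect_equal(mean(tms), expected, tolerance = 0.02)
})

test_that("survival curves start at one and decrease", {
  set.seed(65)
  beta <- array(rnorm(5 * 4 * 2, 0, 0.3), c(5, 4, 2))
  fit <- fake_fit(beta, c(0, 1, 2, 3))
  pred <- predict_survival_times(fit, data.frame(z = c(-1, 1)), n_pred = 50)
  curve <- pred$survival_curve
  for (s in unique(curve$subject)) {
    sv <- curve$survival[curve$subject == s]
    expect_equal(sv[1], 1, tolerance = 1e-9)
    expect_true(all(diff(sv) <= 1e-9))
  }
  expect_error(predict_survival_times(fit, data.frame(w = 1), n_pred = 5),
               "covariates")
})

test_that("random-walk extension beyond the grid is available", {
  beta <- array(0, c(2, 3, 2))
  theta <- matrix(0.04, 2, 2)
  fit <- fake_fit(beta, c(0, 1, 2), theta = theta)
  set.seed(66)
  pred <- predict_survival_times(fit, data.frame(z = 0), n_pred = 200,
                                 horizon_rule = "extend_rw", n_extra = 20)
  expect_true(all(pred$times > 0))
})

test_that("the concordance index matches hand and survival-package oracles", {
  # perfect ranking, no censoring
  expect_equal(concordance_index(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1)), 1)
  # 4-subject toy with one censored record, enumerated by hand:
  # comparable pairs: (1,2) (1,3) (1,4) (2,4*cens at 2? no: smaller time is 2,
  # event) (2,3) (2,4) minus pairs whose earlier time is censored
  tm <- c(1, 2, 3, 2.5); ev <- c(1, 1, 1, 0); sc <- c(4, 1, 2, 3)
  # earlier-event pairs: (1,2),(1,3),(1,4),(2,3),(2,4); concordant: (1,*) all 3;
  # (2,3): sc 1 < 2 discordant; (2,4): 1 < 3 discordant -> 3/5
  expect_equal(concordance_index(tm, ev, sc), 3 / 5)
  set.seed(67)
  n <- 150
  tm <- rexp(n); ev <- rbinom(n, 1, 0.7); sc <- rnorm(n) + tm
  ours <- concordance_index(tm, ev, sc)
  ref <- survival::concordance(survival::Surv(tm, ev) ~ sc, reverse = TRUE)$concordance
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("concordance handles ties, transforms and degenerate input", {
  set.seed(68)
  n <- 1000
  tm <- rexp(n); ev <- rep(1, n); sc <- rnorm(n)
  ci <- concordance_index(tm, ev, sc)
  expect_lt(abs(ci - 0.5), 0.03)  # random scores: no information
  # invariance under strictly increasing transforms
  expect_equal(concordance_index(tm, ev, exp(sc) + 5), ci)
  # score ties count one half
  expect_equal(concordance_index(c(1, 2), c(1, 1), c(1, 1)), 0.5)
  expect_error(concordance_index(c(1, 2), c(0, 0), c(1, 2)), "no comparable")
})

test_that("predictions at the true parameters reproduce the generating law", {
  # piecewise hazard treated as truth: simulate from the model and compare
  # with predictive draws at a point-mass posterior
  S <- c(0, 1, 2, 5)
  lam_path <- c(0.5, 0.9, 0.4)
  beta <- array(0, c(1, 4, 2))
  beta[1, 2:4, 1] <- log(lam_path)
  fit <- fake_fit(beta, S)
  set.seed(69)
  pred <- drop(predict_survival_times(fit, data.frame(z = 0), n_pred = 20000)$times)
  # direct simulation via inversion of the same piecewise cumulative hazard
  e <- rexp(20000)
  H <- c(0.5, 0.5 + 0.9, 0.5 + 0.9 + 0.4 * 3)
  direct <- ifelse(e < H[1], e / 0.5,
            ifelse(e < H[2], 1 + (e - H[1]) / 0.9,
            ifelse(e < H[3], 2 + (e - H[2]) / 0.4, 5 + (e - H[3]) / 0.4)))
  expect_false(ks_reject(pred, direct))
})
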