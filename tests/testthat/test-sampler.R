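test_that("run-length bookkeeping and determinism hold", {
  # defaults mirror the simulation-study protocol: 4,000 stored draws
  fm <- formals(fit_dsm)
  expect_equal(eval(fm$n_iter), 50000L)
  expect_equal(eval(fm$burn_in), 10000L)
  expect_equal(eval(fm$thin), 10L)
  expect_equal(floor((eval(fm$n_iter) - eval(fm$burn_in)) / eval(fm$thin)), 4000)
  df <- make_exp_data(N = 40, seed = 50)
  fit1 <- fit_dsm(df, covariates = "z", n_iter = 120, burn_in = 40, thin = 3, seed = 11)
  expect_equal(fit1$n_draws, floor((120 - 40) / 3))
  expect_equal(dim(fit1$draws$beta), c(fit1$n_draws, fit1$partition$J + 1, 2))
  fit2 <- fit_dsm(df, covariates = "z", n_iter = 120, burn_in = 40, thin = 3, seed = 11)
  expect_identical(fit1$draws, fit2$draws)
  expect_error(fit_dsm(df, covariates = "z", n_iter = 50, burn_in = 50, thin = 1))
  expect_true(all(is.finite(fit1$draws$loglik)))
})

test_that("piecewise-exponential log-likelihood matches naive computation", {
  df <- data.frame(time = 1, status = 1)
  ex <- expand_survival(survival_data(df), fixed_partition(c(0, 1)))
  expect_equal(piecewise_exp_loglik(ex, 1), -1)  # ln 1 - 1 * 1
  # 3-subject toy vs per-subject exponential survival/density products
  df3 <- data.frame(time = c(0.5, 1.2, 2.0), status = c(1, 0, 1))
  sd3 <- survival_data(df3)
  pt <- fixed_partition(c(0, 1, 2))
  ex3 <- expand_survival(sd3, pt)
  lam <- c(0.8, 1.5)  # per-interval hazards shared by all subjects
  haz <- lam[ex3$pairs$interval]
  naive <- log(0.8 * exp(-0.8 * 0.5)) +          # event at 0.5 in interval 1
    (-0.8 * 1 - 1.5 * 0.2) +                     # censored at 1.2
    (-0.8 * 1) + log(1.5 * exp(-1.5 * 1))        # event at 2.0 in interval 2
  expect_equal(piecewise_exp_loglik(ex3, haz), naive, tolerance = 1e-12)
  # doubling exposures decreases the value by sum(lambda u)
  ex_doubled <- ex3
  ex_doubled$pairs$exposure <- 2 * ex3$pairs$exposure
  expect_equal(piecewise_exp_loglik(ex_doubled, haz),
               piecewise_exp_loglik(ex3, haz) - sum(haz * ex3$pairs$exposure))
  expect_error(piecewise_exp_loglik(ex3, haz[-1]), "do not match")
  expect_error(piecewise_exp_loglik(ex3, -haz), "non-positive")
})

test_that("diagnostics flag stuck chains and match the AR(1) effective size", {
  set.seed(51)
  iid <- matrix(rnorm(4000), ncol = 2, dimnames = list(NULL, c("x", "y")))
  d <- mcmc_diagnostics(iid)
  expect_true(all(abs(d$rhat - 1) < 0.05))
  expect_false(any(d$flagged))
  stuck <- cbind(ok = rnorm(500), stuck = rep(1, 500))
  d2 <- mcmc_diagnostics(stuck)
  expect_true(d2$flagged[d2$parameter == "stuck"])
  expect_equal(unname(d2$ess[d2$parameter == "stuck"]), 0)
  # AR(1) with rho = 0.6: ESS = n (1 - rho) / (1 + rho)
  rho <- 0.6
  n <- 200000
  e <- rnorm(n)
  x <- as.numeric(stats::filter(e, rho, method = "recursive"))
  ess <- mcmc_diagnostics(matrix(x, ncol = 1))$ess
  expect_equal(ess, n * (1 - rho) / (1 + rho), tolerance = 0.1)
  expect_error(mcmc_diagnostics(iid[1:50, ]), "at least 100")
})

test_that("fitting with the factor disabled matches a factorless fit bitwise", {
  df <- make_exp_data(N = 50, seed = 52)
  df$g <- rep(1:5, each = 10)
  f1 <- fit_dsm(df, covariates = "z", group = "g", factor = FALSE,
                n_iter = 150, burn_in = 50, thin = 2, seed = 3)
  f2 <- fit_dsm(df[, c("time", "status", "z")], covariates = "z",
                n_iter = 150, burn_in = 50, thin = 2, seed = 3)
  expect_identical(f1$draws$beta, f2$draws$beta)
  expect_identical(f1$draws$theta, f2$draws$theta)
})

test_that("multi-chain wrapper and draw persistence round-trip", {
  df <- make_exp_data(N = 40, seed = 53)
  fits <- fit_dsm_chains(df, chains = 2L, seeds = c(1L, 2L), covariates = "z",
                         n_iter = 300, burn_in = 100, thin = 1)
  expect_s3_class(fits, "dsm_fit_list")
  dg <- mcmc_diagnostics(fits)
  expect_true(all(is.finite(dg$rhat[dg$parameter == "loglik"])))
  dir <- tempfile()
  save_draws(fits[[1]], dir)
  back <- read_draws(dir)
  expect_equal(back$draws$beta, fits[[1]]$draws$beta, tolerance = 1e-10)
  expect_equal(back$draws$theta, fits[[1]]$draws$theta, tolerance = 1e-10)
  expect_equal(back$meta$config$seed, 1)
})

test_that("tidy, glance and autoplot expose posterior summaries", {
  df <- make_exp_data(N = 50, seed = 54)
  fit <- fit_dsm(df, covariates = "z", n_iter = 300, burn_in = 100, thin = 2,
                 seed = 5)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2 * fit$partition$J)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  sc <- tidy(fit, "scalars")
  expect_true(all(c("beta_mean:z", "theta:z", "a_theta") %in% sc$term))
  gl <- glance(fit)
  expect_equal(gl$n, 50L)
  expect_equal(gl$n_draws, 100)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("time-varying covariates enter through the per-interval design", {
  set.seed(55)
  # covariate flips sign at t = 1: detectable only through the tv design
  df <- make_exp_data(N = 60, seed = 55)
  sd <- survival_data(df, covariates = "z")
  pt <- fixed_partition(c(0, 1, max(df$time)))
  tv <- tidyr::expand_grid(subject = 1:60, interval = 1:2) |>
    dplyr::mutate(covariate = "z", value = df$z[subject] * ifelse(interval == 2, -1, 1))
  fit <- fit_dsm(df, covariates = "z", partition = pt, tv = as.data.frame(tv),
                 n_iter = 200, burn_in = 80, thin = 2, seed = 6)
  expect_equal(fit$partition$J, 2L)
  expect_true(is.finite(median(fit$draws$beta[, 2, 2])))
})
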