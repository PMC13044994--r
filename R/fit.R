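# MCMC orchestration for the dynamic survival model.

#' Fit a sparse Bayesian dynamic survival model
#'
#' Piecewise-exponential hazard model on an event-driven interval partition,
#' with every coefficient (including the baseline log-hazard) following a
#' Gaussian random walk, triple-gamma shrinkage on the innovation variances,
#' a normal-gamma-gamma prior on the initial means, and an optional grouped
#' latent-factor frailty with stochastic volatility. Estimation is by Gibbs
#' sampling on the Gumbel auxiliary-mixture augmentation; each sweep runs,
#' in this fixed order: residual survival times, mixture indicators, FFBS for
#' the coefficient paths (residualised on the factor when enabled), the
#' initial means, the innovation variances (centered GIG draw interwoven
#' with a non-centered signed-scale draw), the local/global shrinkage scales
#' with MH for the pole/tail parameters, and the factor block.
#'
#' @param data A data frame (one row per subject) or a [survival_data()]
#'   object.
#' @inheritParams survival_data
#' @param tv Optional long-format data frame of time-varying covariate values
#'   (see [tv_design()]).
#' @param events_per_interval Grid rule: one cut after every m-th observed
#'   event (default 2).
#' @param partition Optional pre-built [build_partition()] object (overrides
#'   `events_per_interval`).
#' @param n_iter,burn_in,thin MCMC run length; defaults mirror the package's
#'   simulation-study settings (50,000 / 10,000 / 10, storing 4,000 draws).
#' @param seed Integer seed; the fit is bitwise reproducible given the seed
#'   and inputs.
#' @param theta_hyper,beta_hyper,phi_hyper [ngg_hyper()] configurations for
#'   the variance, mean and loading shrinkage blocks.
#' @param factor Enable the grouped latent-factor frailty (requires `group`).
#' @param sv [sv_hyper()] configuration for the factor's stochastic
#'   volatility.
#' @param constant_coefficients Fix all innovation variances at the floor,
#'   giving the internal constant-coefficient baseline model.
#' @param allow_individual_frailty Permit `G = N` (one group per subject);
#'   off by default because individual frailty is weakly identified in a
#'   time-varying parameter model.
#' @param variance_floor Lower bound on innovation variances inside the
#'   filter.
#' @param verbose Print progress every 10% of iterations plus MH acceptance
#'   rates.
#' @return An object of class `dsm_fit` holding thinned posterior draws
#'   (coefficient paths, initial means, innovation variances, shrinkage
#'   scales and pole/tail parameters, factor block), the partition and
#'   expanded data, per-draw piecewise-exponential log-likelihoods, MH
#'   acceptance rates, and the configuration.
#' @examples
#' sim <- simulate_dsm_data(dgp_config(kind = "constant", N = 60, K = 2, seed = 1))
#' fit <- fit_dsm(sim, n_iter = 200, burn_in = 100, thin = 1, seed = 1)
#' fit
#' @export
fit_dsm <- function(data, time = "time", status = "status", covariates = NULL,
                    group = NULL, tv = NULL,
                    events_per_interval = 2L, partition = NULL,
                    n_iter = 50000L, burn_in = 10000L, thin = 10L, seed = NULL,
                    theta_hyper = ngg_hyper(), beta_hyper = ngg_hyper(),
                    phi_hyper = ngg_hyper(), factor = !is.null(group),
                    sv = sv_hyper(), constant_coefficients = FALSE,
                    allow_individual_frailty = FALSE,
                    variance_floor = 1e-12, verbose = FALSE) {
  sd <- if (inherits(data, "survival_data")) {
    data
  } else {
    survival_data(data, time = time, status = status, covariates = covariates,
                  group = group)
  }
  stopifnot(burn_in < n_iter, thin >= 1L, n_iter >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(partition)) {
    partition <- build_partition(sd$y[sd$d == 1], events_per_interval, max(sd$y))
  }
  expanded <- expand_survival(sd, partition)
  Z_tv <- if (!is.null(tv)) tv_design(sd, partition, tv)
  Zp <- pair_design(sd, expanded, Z_tv)

  J <- partition$J
  p <- ncol(Zp)
  jj <- expanded$interval
  u <- expanded$u
  M <- length(u)

  if (factor) {
    if (is.null(sd$group)) stop("`factor = TRUE` requires a group column", call. = FALSE)
    G <- length(unique(sd$group))
    if (G >= sd$N && !allow_individual_frailty) {
      stop("G = N gives an individual-level frailty, which is weakly ",
           "identified here; set `allow_individual_frailty = TRUE` to override",
           call. = FALSE)
    }
    gpair <- sd$group[expanded$subject]
    lmix <- logchisq_mixture()
  } else {
    G <- 0L
  }
  gmix <- gumbel_mixture()

  # initial sampler state: warm-start the coefficient level at the
  # piecewise-exponential MLE (Poisson regression with log-exposure offset).
  # The augmented chain moves towards the posterior at a rate governed by the
  # ratio of real to auxiliary information, so a data-informed start shortens
  # burn-in substantially.
  beta_mean <- tryCatch({
    cf <- suppressWarnings(stats::glm.fit(
      Zp, as.numeric(expanded$pairs$event), family = stats::poisson(),
      offset = log(u)))$coefficients
    cf[!is.finite(cf)] <- 0
    pmin(pmax(cf, -20), 20)
  }, error = function(e) rep(0, p))
  theta <- if (constant_coefficients) rep(variance_floor, p) else rep(0.01, p)
  states <- matrix(beta_mean, J + 1L, p, byrow = TRUE)
  blk_theta <- ngg_block_init(p, theta_hyper)
  blk_beta <- ngg_block_init(p, beta_hyper)
  if (factor) {
    blk_phi <- ngg_block_init(G, phi_hyper)
    f <- rep(0, J)
    h <- rep(0, J + 1L)
    phi <- rep(0, G)
    phi_sv <- 0.9
    sigma2_f <- 0.1
    ls_sv <- log(0.3)
    acc_sv <- 0L
  }

  n_store <- floor((n_iter - burn_in) / thin)
  dr <- list(
    beta = array(NA_real_, c(n_store, J + 1L, p)),
    beta_mean = matrix(NA_real_, n_store, p),
    theta = matrix(NA_real_, n_store, p),
    lam_theta = matrix(NA_real_, n_store, p),
    tau_theta = numeric(n_store),
    lam_beta = matrix(NA_real_, n_store, p),
    tau_beta = numeric(n_store),
    a_theta = numeric(n_store), c_theta = numeric(n_store),
    a_beta = numeric(n_store), c_beta = numeric(n_store),
    loglik = numeric(n_store)
  )
  if (factor) {
    dr$f <- matrix(NA_real_, n_store, J)
    dr$h <- matrix(NA_real_, n_store, J + 1L)
    dr$phi <- matrix(NA_real_, n_store, G)
    dr$phi_sv <- numeric(n_store)
    dr$sigma2_f <- numeric(n_store)
    dr$lam_phi <- matrix(NA_real_, n_store, G)
    dr$tau_phi <- numeric(n_store)
    dr$a_phi <- numeric(n_store)
    dr$c_phi <- numeric(n_store)
  }

  store_i <- 0L
  milestones <- unique(pmax(1L, floor(n_iter * seq(0.1, 1, by = 0.1))))
  for (t in seq_len(n_iter)) {
    adapt <- t <= burn_in
    lin_beta <- rowSums(Zp * states[jj + 1L, , drop = FALSE])
    lin <- if (factor) lin_beta + phi[gpair] * f[jj] else lin_beta
    haz <- exp(lin)
    tau_aux <- draw_residual_times(expanded, haz)
    r_ind <- draw_mixture_indicators(tau_aux, lin, gmix)
    pseudo <- build_pseudo_observations(tau_aux, r_ind, gmix)
    x <- pseudo$x
    v <- pseudo$v
    xb <- if (factor) x - phi[gpair] * f[jj] else x

    Q <- pmax(theta, variance_floor)
    if (constant_coefficients) {
      # theta pinned at the floor: the path is flat, so draw its level from
      # the conjugate normal regression on the pseudo-observations
      Xv <- Zp / v
      Prec <- crossprod(Xv, Zp) + diag(1 / (blk_beta$lam * blk_beta$tau), p)
      Cov <- chol_inv(Prec)
      beta_mean <- draw_mvnorm(drop(Cov %*% crossprod(Xv, xb)), Cov)
      states <- matrix(beta_mean, J + 1L, p, byrow = TRUE)
    } else {
      model <- state_space_model(xb, v, Zp, jj, J, Q = Q, a0 = beta_mean,
                                 P0 = Q, variance_floor = variance_floor)
      states <- ffbs(model)
      beta_mean <- sample_initial_means(states[1L, ], Q, blk_beta$lam, blk_beta$tau)
    }
    if (any(!is.finite(states))) {
      stop("non-finite state draw at sweep ", t, " (FFBS block)", call. = FALSE)
    }

    if (!constant_coefficients) {
      theta <- sample_theta_centered(states, beta_mean, blk_theta$lam, blk_theta$tau)
      ncp <- sample_theta_ncp(states, beta_mean, theta, xb, v, Zp, jj,
                              blk_theta$lam, blk_theta$tau,
                              blk_beta$lam, blk_beta$tau, variance_floor)
      theta <- ncp$theta
      beta_mean <- ncp$beta_mean
      states <- ncp$states
      blk_theta <- sample_local_global(theta, blk_theta, theta_hyper, adapt = adapt)
    }
    blk_beta <- sample_local_global(beta_mean^2, blk_beta, beta_hyper, adapt = adapt)

    if (factor) {
      resid <- x - rowSums(Zp * states[jj + 1L, , drop = FALSE])
      f <- sample_factor(resid, v, jj, phi[gpair], h, J)
      phi <- sample_loadings(resid, v, jj, gpair, f, G, blk_phi$lam, blk_phi$tau)
      blk_phi <- sample_local_global(phi^2, blk_phi, phi_hyper, adapt = adapt)
      svres <- sample_sv_block(f, h, phi_sv, sigma2_f, sv, lmix, ls_sv)
      h <- svres$h
      phi_sv <- svres$phi_sv
      sigma2_f <- svres$sigma2
      acc_sv <- acc_sv + svres$accepted
      if (adapt) ls_sv <- ls_sv + 0.05 * (svres$alpha - 0.35)
    }

    if (t > burn_in && (t - burn_in) %% thin == 0L) {
      store_i <- store_i + 1L
      dr$beta[store_i, , ] <- states
      dr$beta_mean[store_i, ] <- beta_mean
      dr$theta[store_i, ] <- theta
      dr$lam_theta[store_i, ] <- blk_theta$lam
      dr$tau_theta[store_i] <- blk_theta$tau
      dr$lam_beta[store_i, ] <- blk_beta$lam
      dr$tau_beta[store_i] <- blk_beta$tau
      dr$a_theta[store_i] <- blk_theta$a
      dr$c_theta[store_i] <- blk_theta$c
      dr$a_beta[store_i] <- blk_beta$a
      dr$c_beta[store_i] <- blk_beta$c
      lin_s <- rowSums(Zp * states[jj + 1L, , drop = FALSE])
      if (factor) lin_s <- lin_s + phi[gpair] * f[jj]
      dr$loglik[store_i] <- piecewise_exp_loglik(expanded, exp(lin_s))
      if (factor) {
        dr$f[store_i, ] <- f
        dr$h[store_i, ] <- h
        dr$phi[store_i, ] <- phi
        dr$phi_sv[store_i] <- phi_sv
        dr$sigma2_f[store_i] <- sigma2_f
        dr$lam_phi[store_i, ] <- blk_phi$lam
        dr$tau_phi[store_i] <- blk_phi$tau
        dr$a_phi[store_i] <- blk_phi$a
        dr$c_phi[store_i] <- blk_phi$c
      }
    }
    if (verbose && t %in% milestones) {
      message(sprintf("sweep %d/%d (%.0f%%)", t, n_iter, 100 * t / n_iter))
    }
  }

  if (factor) {
    fixed <- identify_signs(dr$phi, dr$f)
    dr$phi <- fixed$phi
    dr$f <- fixed$f
  }

  rates <- list(
    a_theta = if (blk_theta$try_a) blk_theta$acc_a / blk_theta$try_a else NA_real_,
    c_theta = if (blk_theta$try_c) blk_theta$acc_c / blk_theta$try_c else NA_real_,
    a_beta = if (blk_beta$try_a) blk_beta$acc_a / blk_beta$try_a else NA_real_,
    c_beta = if (blk_beta$try_c) blk_beta$acc_c / blk_beta$try_c else NA_real_
  )
  if (factor) {
    rates$a_phi <- if (blk_phi$try_a) blk_phi$acc_a / blk_phi$try_a else NA_real_
    rates$c_phi <- if (blk_phi$try_c) blk_phi$acc_c / blk_phi$try_c else NA_real_
    rates$phi_sv <- acc_sv / n_iter
  }
  if (verbose) {
    message("MH acceptance rates: ",
            paste(names(rates), sprintf("%.2f", unlist(rates)), collapse = ", "))
  }

  structure(
    list(draws = dr, n_draws = n_store, partition = partition,
         expanded = expanded, dataset = sd, design = Zp, factor = factor,
         G = G, acceptance = rates,
         config = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                       seed = seed, events_per_interval = events_per_interval,
                       factor = factor, constant_coefficients = constant_coefficients,
                       variance_floor = variance_floor,
                       theta_hyper = theta_hyper, beta_hyper = beta_hyper,
                       phi_hyper = if (factor) phi_hyper else NULL,
                       sv = if (factor) sv else NULL)),
    class = "dsm_fit"
  )
}

#' Run several independent chains serially
#'
#' @inheritParams fit_dsm
#' @param chains Number of chains.
#' @param seeds Integer vector of seeds, one per chain.
#' @param ... Passed to [fit_dsm()].
#' @return A list of `dsm_fit` objects with class `dsm_fit_list`.
#' @export
fit_dsm_chains <- function(data, chains = 2L, seeds = seq_len(chains), ...) {
  stopifnot(length(seeds) == chains)
  fits <- lapply(seeds, function(s) fit_dsm(data, seed = s, ...))
  structure(fits, class = "dsm_fit_list")
}

#' Exact piecewise-exponential log-likelihood
#'
#' `sum over pairs of event * log(hazard) - hazard * exposure`; used for
#' diagnostics and the marginal-augmentation checks.
#'
#' @param expanded An [expand_survival()] result.
#' @param hazards Positive hazard per at-risk pair, aligned with
#'   `expanded$pairs`.
#' @return Scalar log-likelihood.
#' @export
piecewise_exp_loglik <- function(expanded, hazards) {
  stopifnot(inherits(expanded, "expanded_survival"))
  u <- expanded$pairs$exposure
  if (length(hazards) != length(u)) {
    stop("hazards do not match the expanded exposures", call. = FALSE)
  }
  if (any(hazards <= 0)) stop("non-positive hazard", call. = FALSE)
  sum(expanded$pairs$event * log(hazards)) - sum(hazards * u)
}

#' @export
print.dsm_fit <- function(x, ...) {
  cat("<dsm_fit> ", x$n_draws, " stored draws (", x$config$n_iter, " sweeps, burn-in ",
      x$config$burn_in, ", thin ", x$config$thin, ")\n", sep = "")
  cat("  ", x$dataset$N, " subjects, ", sum(x$dataset$d), " events, K = ",
      x$dataset$K, ", J = ", x$partition$J, " intervals",
      if (x$factor) paste0(", factor over ", x$G, " groups"), "\n", sep = "")
  invisible(x)
}
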