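# Tidiers and plotting methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy posterior summaries of a fitted dynamic survival model
#'
#' @param x A `dsm_fit`.
#' @param pars `"paths"` (default): per-term, per-interval coefficient
#'   summaries; `"scalars"`: initial means, innovation variances and
#'   shrinkage hyperparameters.
#' @param conf_level Credible-band level for the pointwise intervals.
#' @param ... Unused.
#' @return A tibble. For `pars = "paths"`: `term`, `interval`, `time_lower`,
#'   `time_upper`, `estimate` (posterior median), `conf.low`, `conf.high`.
#'   For `pars = "scalars"`: `term`, `estimate`, `conf.low`, `conf.high`.
#' @method tidy dsm_fit
#' @export
tidy.dsm_fit <- function(x, pars = c("paths", "scalars"), conf_level = 0.95, ...) {
  pars <- match.arg(pars)
  alpha <- (1 - conf_level) / 2
  terms <- c("(baseline)", x$dataset$covariate_names)
  if (pars == "paths") {
    J <- x$partition$J
    S <- x$partition$S
    b <- x$draws$beta[, -1L, , drop = FALSE]   # drop the pre-sample state
    qs <- apply(b, c(2L, 3L), stats::quantile, probs = c(alpha, 0.5, 1 - alpha))
    tidyr::expand_grid(term = terms, interval = seq_len(J)) |>
      dplyr::arrange(match(.data$term, terms), .data$interval) |>
      dplyr::mutate(
        time_lower = S[.data$interval],
        time_upper = S[.data$interval + 1L],
        estimate = as.vector(qs[2L, , ]),
        conf.low = as.vector(qs[1L, , ]),
        conf.high = as.vector(qs[3L, , ])
      )
  } else {
    summ <- function(m, nm) {
      q <- apply(m, 2L, stats::quantile, probs = c(alpha, 0.5, 1 - alpha))
      tibble::tibble(term = nm, estimate = q[2L, ], conf.low = q[1L, ],
                     conf.high = q[3L, ])
    }
    dplyr::bind_rows(
      summ(x$draws$beta_mean, paste0("beta_mean:", terms)),
      summ(x$draws$theta, paste0("theta:", terms)),
      summ(cbind(x$draws$a_theta, x$draws$c_theta, x$draws$a_beta, x$draws$c_beta),
           c("a_theta", "c_theta", "a_beta", "c_beta")),
      if (x$factor) summ(x$draws$phi, paste0("phi:", seq_len(x$G)))
    )
  }
}

#' One-row model summary
#'
#' @param x A `dsm_fit`.
#' @param ... Unused.
#' @return A tibble with `n`, `n_events`, `K`, `J`, `n_draws`,
#'   `mean_loglik` (posterior mean piecewise-exponential log-likelihood) and
#'   `max_rhat` across the stored scalar chains (NA when too few draws).
#' @method glance dsm_fit
#' @export
glance.dsm_fit <- function(x, ...) {
  max_rhat <- if (x$n_draws >= 100) {
    max(mcmc_diagnostics(x)$rhat)
  } else {
    NA_real_
  }
  tibble::tibble(
    n = x$dataset$N, n_events = sum(x$dataset$d), K = x$dataset$K,
    J = x$partition$J, n_draws = x$n_draws,
    mean_loglik = mean(x$draws$loglik), max_rhat = max_rhat
  )
}

#' Plot posterior coefficient paths
#'
#' Step-function posterior medians with pointwise credible ribbons, one facet
#' per term: visually separates excluded (flat at zero), constant (flat,
#' nonzero) and time-varying effects.
#'
#' @param object A `dsm_fit`.
#' @param terms Optional subset of term names.
#' @param conf_level Credible level for the ribbons.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dsm_fit
#' @export
autoplot.dsm_fit <- function(object, terms = NULL, conf_level = 0.95, ...) {
  td <- tidy(object, pars = "paths", conf_level = conf_level)
  if (!is.null(terms)) td <- dplyr::filter(td, .data$term %in% terms)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$time_lower)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_step(ggplot2::aes(y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "time", y = "log-hazard effect")
}

#' Plot posterior predictive survival curves
#'
#' @param object A `dsm_prediction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dsm_prediction
#' @export
autoplot.dsm_prediction <- function(object, ...) {
  ggplot2::ggplot(object$survival_curve,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               group = .data$subject)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time", y = "survival probability")
}

#' @export
plot.dsm_fit <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.dsm_prediction <- function(x, ...) print(autoplot(x, ...))
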