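# Posterior predictive survival simulation, risk scores and concordance.

# Hazard matrix for new subjects under one posterior draw d.
draw_hazard_matrix <- function(fit, Znew, d, group = NULL, horizon_rule = "carry_last",
                               n_extra = 0L) {
  B <- fit$draws$beta[d, , ]          # (J+1) x p
  J <- fit$partition$J
  lam <- exp(Znew %*% t(B[-1L, , drop = FALSE]))  # n x J
  if (!is.null(group) && fit$factor) {
    lam <- lam * rep(exp(fit$draws$phi[d, group] * fit$draws$f[d, ]), each = nrow(lam))
  }
  if (n_extra > 0L) {
    p <- ncol(B)
    theta <- pmax(fit$draws$theta[d, ], fit$config$variance_floor)
    bj <- B[J + 1L, ]
    extra <- matrix(0, nrow(Znew), n_extra)
    for (m in seq_len(n_extra)) {
      bj <- bj + stats::rnorm(p, 0, sqrt(theta))
      extra[, m] <- exp(Znew %*% bj)
    }
    lam <- cbind(lam, extra)
  }
  lam
}

#' Simulate posterior predictive survival times for new subjects
#'
#' For each posterior draw, the interval hazards
#' `lambda_j = exp(z beta_j^{(draw)})` are formed (with intercept; the factor
#' offset is included only when a group is specified, since a new subject of
#' unknown group gets the marginal prediction) and event times are drawn from
#' the piecewise-exponential law. Beyond the last grid point the final
#' interval's hazard is carried forward (`horizon_rule = "carry_last"`); with
#' `"extend_rw"` the coefficient random walk is instead propagated with fresh
#' innovations over `n_extra` extra intervals before carrying forward.
#'
#' @param fit A [fit_dsm()] result.
#' @param newdata Data frame (or matrix) of covariate values, columns
#'   matching the fitted covariates.
#' @param n_pred Number of predictive times per subject (posterior draws are
#'   cycled; default 10,000).
#' @param group Optional group index (into the fitted groups) whose frailty
#'   term should be included.
#' @param horizon_rule `"carry_last"` (default) or `"extend_rw"`.
#' @param n_extra Number of random-walk extension intervals for
#'   `"extend_rw"`.
#' @param curve_grid Number of points for the posterior mean survival curve.
#' @return An object of class `dsm_prediction`: list with `times` (matrix,
#'   subjects x `n_pred`) and `survival_curve` (tibble: `time`, `survival`,
#'   `lower`, `upper` pointwise 95% band, per subject).
#' @export
predict_survival_times <- function(fit, newdata, n_pred = 10000L, group = NULL,
                                   horizon_rule = c("carry_last", "extend_rw"),
                                   n_extra = 50L, curve_grid = 101L) {
  horizon_rule <- match.arg(horizon_rule)
  stopifnot(inherits(fit, "dsm_fit"), n_pred >= 1L)
  missing_cols <- setdiff(fit$dataset$covariate_names, colnames(newdata))
  if (length(missing_cols) > 0) {
    stop("`newdata` must supply the fitted covariates; missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  Z <- as.matrix(newdata[, fit$dataset$covariate_names, drop = FALSE])
  Znew <- cbind(1, Z)
  n <- nrow(Znew)
  S <- fit$partition$S
  J <- fit$partition$J
  widths <- diff(S)
  n_draws <- fit$n_draws
  reps <- ceiling(n_pred / n_draws)
  use_draws <- rep(seq_len(n_draws), length.out = n_pred)
  per_draw <- table(factor(use_draws, levels = seq_len(n_draws)))
  times <- matrix(NA_real_, n, n_pred)
  n_ext <- if (horizon_rule == "extend_rw") n_extra else 0L
  Sx <- if (n_ext > 0L) c(S, S[J + 1L] + cumsum(rep(mean(widths), n_ext))) else S
  wx <- diff(Sx)
  col <- 0L
  surv_accum <- matrix(0, n, curve_grid)
  surv_sq <- list()
  tgrid <- seq(0, S[J + 1L], length.out = curve_grid)
  for (d in seq_len(n_draws)) {
    kd <- as.integer(per_draw[d])
    if (kd == 0L) next
    haz <- draw_hazard_matrix(fit, Znew, d, group, horizon_rule, n_ext)
    cumH <- haz * rep(wx, each = n)
    for (j in seq_len(ncol(cumH) - 1L)) cumH[, j + 1L] <- cumH[, j + 1L] + cumH[, j]
    # survival curve S(t) = exp(-H(t)) on tgrid (piecewise-linear H)
    Ht <- interp_cumhaz(cumH, haz, Sx, tgrid)
    surv_sq[[length(surv_sq) + 1L]] <- exp(-Ht)
    surv_accum <- surv_accum + surv_sq[[length(surv_sq)]]
    for (rep_i in seq_len(kd)) {
      e <- stats::rexp(n)
      jstar <- rowSums(cumH < e) + 1L
      Jx <- ncol(cumH)
      t_out <- numeric(n)
      beyond <- jstar > Jx
      if (any(beyond)) {
        t_out[beyond] <- Sx[Jx + 1L] + (e[beyond] - cumH[beyond, Jx]) / haz[beyond, Jx]
      }
      inside <- which(!beyond)
      if (length(inside)) {
        js <- jstar[inside]
        prev <- ifelse(js == 1L, 0, cumH[cbind(inside, pmax(js - 1L, 1L))])
        t_out[inside] <- Sx[js] + (e[inside] - prev) / haz[cbind(inside, js)]
      }
      col <- col + 1L
      times[, col] <- t_out
    }
  }
  curve_mean <- surv_accum / length(surv_sq)
  qs <- apply(simplify2array(surv_sq), c(1L, 2L), stats::quantile,
              probs = c(0.025, 0.975))
  curve <- tidyr::expand_grid(subject = seq_len(n), time = tgrid) |>
    dplyr::arrange(.data$subject, .data$time)
  curve$survival <- as.vector(t(curve_mean))
  curve$lower <- as.vector(t(qs[1L, , ]))
  curve$upper <- as.vector(t(qs[2L, , ]))
  structure(list(times = times, survival_curve = curve, S = S),
            class = "dsm_prediction")
}

# piecewise-linear cumulative hazard interpolated onto tgrid
interp_cumhaz <- function(cumH, haz, Sx, tgrid) {
  n <- nrow(cumH)
  Jx <- ncol(cumH)
  out <- matrix(0, n, length(tgrid))
  idx <- findInterval(tgrid, Sx, rightmost.closed = FALSE)
  idx[idx > Jx] <- Jx
  for (g in seq_along(tgrid)) {
    j <- idx[g]
    if (j < 1L) next
    prev <- if (j == 1L) 0 else cumH[, j - 1L]
    out[, g] <- prev + haz[, j] * (tgrid[g] - Sx[j])
  }
  out
}

#' @export
print.dsm_prediction <- function(x, ...) {
  cat("<dsm_prediction>", nrow(x$times), "subject(s) x", ncol(x$times),
      "posterior predictive survival times\n")
  invisible(x)
}

#' Posterior predictive risk scores
#'
#' The risk score of a covariate vector is minus the mean of `n_pred`
#' posterior predictive survival times (default 10,000): higher score, higher
#' risk.
#'
#' @inheritParams predict_survival_times
#' @return Numeric vector of risk scores, one per row of `newdata`.
#' @export
risk_score <- function(fit, newdata, n_pred = 10000L, group = NULL,
                       horizon_rule = "carry_last") {
  pred <- predict_survival_times(fit, newdata, n_pred = n_pred, group = group,
                                 horizon_rule = horizon_rule, curve_grid = 2L)
  -rowMeans(pred$times)
}

#' Harrell's concordance index
#'
#' A pair of subjects is comparable when the smaller observed time belongs
#' to an observed event; the pair is concordant when that subject carries the
#' larger risk score, and score ties count one half. Returns the concordant
#' share among comparable pairs.
#'
#' @param time Observed survival times.
#' @param status Event indicators (1 = event).
#' @param score Risk scores (larger = shorter expected survival).
#' @return Scalar in `[0, 1]`.
#' @examples
#' concordance_index(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1))
#' @export
concordance_index <- function(time, status, score) {
  n <- length(time)
  stopifnot(length(status) == n, length(score) == n)
  dt <- outer(time, time, "<")                 # dt[i,j]: y_i < y_j
  comparable <- dt & (status == 1)             # row i is the earlier event
  nc <- sum(comparable)
  if (nc == 0) stop("no comparable pairs", call. = FALSE)
  sc <- outer(score, score, ">")
  tie <- outer(score, score, "==")
  (sum(sc & comparable) + 0.5 * sum(tie & comparable)) / nc
}
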