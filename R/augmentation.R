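# Data augmentation: residual survival times and Gumbel mixture indicators.
#
# Conditional on the hazards, each censored-within-interval exposure u_ij is
# completed to a total interval survival time tau_ij = u_ij + xi_ij with
# xi_ij ~ Exp(lambda_ij) by memorylessness; an observed failure fixes
# tau = u exactly. Taking -log tau leaves a standard Gumbel error which the
# 10-component normal mixture turns into conditionally Gaussian
# pseudo-observations.

#' Draw auxiliary total survival times
#'
#' For every at-risk subject-interval pair, completes the observed exposure
#' to a full interval survival time: `tau = u` exactly when the subject's
#' failure was observed in that interval, otherwise `tau = u + xi` with
#' `xi ~ Exponential(lambda_ij)`.
#'
#' @param expanded An [expand_survival()] result.
#' @param hazards Positive hazard `lambda_ij` per at-risk pair, aligned with
#'   `expanded$pairs`.
#' @return Numeric vector `tau` aligned with `expanded$pairs`.
#' @export
draw_residual_times <- function(expanded, hazards) {
  stopifnot(inherits(expanded, "expanded_survival"))
  u <- expanded$u
  if (length(hazards) != length(u)) stop("hazards/pairs length mismatch", call. = FALSE)
  if (any(!is.finite(hazards)) || any(hazards <= 0)) {
    stop("non-positive hazard encountered in residual-time draw", call. = FALSE)
  }
  tau <- u + stats::rexp(length(u), rate = hazards)
  ev <- expanded$event
  tau[ev] <- u[ev]
  tau
}

#' Sample Gumbel-mixture component indicators
#'
#' Computes the Gumbel residual `e_ij = -log(tau_ij) - linpred_ij` and samples
#' each indicator `r_ij` with probability proportional to
#' `w_r * N(e_ij; m_r, v_r)`.
#'
#' @param tau Auxiliary total survival times.
#' @param linpred Linear predictor `z_i beta_j` (plus any factor offset) per
#'   pair.
#' @param mixture A [gumbel_mixture()].
#' @return Integer vector of component indicators in `1..mixture$R`.
#' @export
draw_mixture_indicators <- function(tau, linpred, mixture = gumbel_mixture()) {
  e <- -log(tau) - linpred
  if (any(!is.finite(e))) {
    bad <- which(!is.finite(e))[1L]
    stop("non-finite Gumbel residual at pair ", bad, call. = FALSE)
  }
  M <- length(e)
  R <- mixture$R
  # manual normal log-density: the constants are precomputable and this is
  # the hottest loop of every sweep
  lw <- log(mixture$w) - 0.5 * log(2 * pi * mixture$v)
  half_prec <- 0.5 / mixture$v
  lp <- matrix(0, M, R)
  for (r in seq_len(R)) {
    d <- e - mixture$m[r]
    lp[, r] <- lw[r] - d * d * half_prec[r]
  }
  mx <- lp[cbind(seq_len(M), max.col(lp))]
  pr <- exp(lp - mx)
  # vectorised categorical draw via cumulative sums
  cum <- pr
  for (r in 2:R) cum[, r] <- cum[, r] + cum[, r - 1L]
  u <- stats::runif(M) * cum[, R]
  idx <- rep.int(1L, M)
  for (r in seq_len(R - 1L)) idx <- idx + (u > cum[, r])
  idx
}

#' Build Gaussian pseudo-observations from the augmented state
#'
#' @param tau Auxiliary total survival times (positive).
#' @param r Mixture component indicators.
#' @param mixture A [gumbel_mixture()].
#' @return List with `x = -log(tau) - m[r]` and `v = v[r]`, aligned with the
#'   pair ordering (by interval, matching the risk-set index lists).
#' @export
build_pseudo_observations <- function(tau, r, mixture = gumbel_mixture()) {
  if (any(tau <= 0)) stop("non-positive auxiliary survival time", call. = FALSE)
  list(x = -log(tau) - mixture$m[r], v = mixture$v[r])
}
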