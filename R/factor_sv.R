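# Grouped latent-factor frailty with stochastic volatility.
#
# With groups g = 1..G the hazard gains a multiplicative term exp(phi_g f_j):
# a single factor f_j per interval with SV law of motion
#   f_j | h_j ~ N(0, exp(h_j)),  h_j = phi_sv h_{j-1} + N(0, sigma_f^2),
#   h_0 ~ N(0, sigma_f^2 / (1 - phi_sv^2)),
# triple-gamma shrinkage on the loadings phi_g, and post-hoc sign
# identification (phi_1 >= 0).

#' Stochastic-volatility hyperparameters
#'
#' `(phi_sv + 1)/2 ~ Beta(a_sv, b_sv)` and `sigma_f^2 ~ G(1/2, 1/(2 B_sv))`.
#' Defaults are weakly informative conventional values.
#'
#' @param a_sv,b_sv Translated-beta shapes for the persistence.
#' @param B_sv Scale of the gamma prior on the innovation variance.
#' @return A list of class `sv_hyper`.
#' @export
sv_hyper <- function(a_sv = 5, b_sv = 1.5, B_sv = 1) {
  stopifnot(a_sv > 0, b_sv > 0, B_sv > 0)
  structure(list(a_sv = a_sv, b_sv = b_sv, B_sv = B_sv), class = "sv_hyper")
}

#' Sample the latent factor path
#'
#' Per interval `j`, `f_j` is conditionally normal given the Gaussian
#' pseudo-observations (residualised on the coefficient paths), the group
#' loadings and its `N(0, exp(h_j))` prior, independently across intervals.
#'
#' @param resid Pair-level residuals `x_ij - z_i beta_j` (pseudo-observation
#'   minus coefficient linear predictor).
#' @param v Pair-level observation variances.
#' @param interval Pair interval indices.
#' @param phi_pair Loading `phi_{g_i}` per pair.
#' @param h Log-variance path `h_0..h_J`.
#' @param J Number of intervals.
#' @return Numeric vector `f_1..f_J`.
#' @export
sample_factor <- function(resid, v, interval, phi_pair, h, J) {
  if (length(phi_pair) != length(resid)) {
    stop("factor update called without group loadings per pair", call. = FALSE)
  }
  w <- phi_pair / v
  prec <- rep(1 / exp(h[-1L]), length.out = J) +
    as.numeric(rowsum_by(w * phi_pair, interval, J))
  mu <- as.numeric(rowsum_by(w * resid, interval, J)) / prec
  stats::rnorm(J, mu, sqrt(1 / prec))
}

# fast grouped sum over intervals 1..J
rowsum_by <- function(x, interval, J) {
  out <- numeric(J)
  s <- rowsum(x, interval)
  out[as.integer(rownames(s))] <- s
  out
}

#' Sample the factor loadings
#'
#' Per group `g`, `phi_g` is conditionally normal under the scale-mixture
#' representation of its triple-gamma prior, `phi_g ~ N(0, lam_g tau)`.
#' An empty group falls back to a prior draw with a warning.
#'
#' @param resid,v,interval As in [sample_factor()].
#' @param group_pair Group index per pair.
#' @param f Factor path `f_1..f_J`.
#' @param G Number of groups.
#' @param lam,tau Local and global scales of the loading block.
#' @return Numeric vector `phi_1..phi_G`.
#' @export
sample_loadings <- function(resid, v, interval, group_pair, f, G, lam, tau) {
  fp <- f[interval]
  w <- fp / v
  prec_data <- rowsum_by(w * fp, group_pair, G)
  mu_data <- rowsum_by(w * resid, group_pair, G)
  empty <- tabulate(group_pair, G) == 0L
  if (any(empty)) {
    warning("group(s) without observations: loading drawn from prior")
  }
  prec <- prec_data + 1 / (lam * tau)
  stats::rnorm(G, mu_data / prec, sqrt(1 / prec))
}

# Scalar FFBS for the AR(1) log-volatility path h_0..h_J with observations
# y_j = h_j + N(0, v_j) for j = 1..J (from the log chi^2_1 mixture).
ffbs_ar1 <- function(y, v, phi, sigma2, J) {
  m <- numeric(J + 1L)
  C <- numeric(J + 1L)
  m[1L] <- 0
  C[1L] <- sigma2 / (1 - phi^2)
  for (j in seq_len(J)) {
    mp <- phi * m[j]
    Pp <- phi^2 * C[j] + sigma2
    K <- Pp / (Pp + v[j])
    m[j + 1L] <- mp + K * (y[j] - mp)
    C[j + 1L] <- Pp * (1 - K)
  }
  h <- numeric(J + 1L)
  h[J + 1L] <- stats::rnorm(1L, m[J + 1L], sqrt(C[J + 1L]))
  for (j in seq(J, 1L)) {
    Pp <- phi^2 * C[j] + sigma2
    G <- phi * C[j] / Pp
    mean_j <- m[j] + G * (h[j + 1L] - phi * m[j])
    var_j <- C[j] - G * phi * C[j]
    h[j] <- stats::rnorm(1L, mean_j, sqrt(max(var_j, 0)))
  }
  h
}

sv_phi_logpost <- function(phi, h, sigma2, hyper) {
  if (abs(phi) >= 1) return(-Inf)
  J1 <- length(h)
  stats::dbeta((phi + 1) / 2, hyper$a_sv, hyper$b_sv, log = TRUE) +
    stats::dnorm(h[1L], 0, sqrt(sigma2 / (1 - phi^2)), log = TRUE) +
    sum(stats::dnorm(h[-1L], phi * h[-J1], sqrt(sigma2), log = TRUE))
}

#' Sample the stochastic-volatility block
#'
#' Approximates `log(f_j^2 + offset)` by the 10-component normal mixture for
#' the log chi-squared(1) error, draws the log-variance path by scalar
#' forward-filtering backward-sampling, the persistence by random-walk MH on
#' its Fisher transform under the translated-beta prior, and the innovation
#' variance from its GIG full conditional.
#'
#' @param f Factor path.
#' @param h Current log-variance path (`h_0..h_J`).
#' @param phi_sv Current persistence.
#' @param sigma2 Current innovation variance.
#' @param hyper An [sv_hyper()].
#' @param mixture A [logchisq_mixture()].
#' @param ls Log proposal sd for the persistence MH step.
#' @param offset Guard added to `f_j^2` before taking logs.
#' @return List with `h`, `phi_sv`, `sigma2`, `accepted`, `alpha`.
#' @export
sample_sv_block <- function(f, h, phi_sv, sigma2, hyper = sv_hyper(),
                            mixture = logchisq_mixture(), ls = log(0.3),
                            offset = 1e-8) {
  J <- length(f)
  ylog <- log(f^2 + offset)
  # mixture indicators for the log chi^2_1 errors
  resid <- ylog - h[-1L]
  r <- sv_indicators(resid, mixture)
  yobs <- ylog - mixture$m[r]
  vobs <- mixture$v[r]
  h_new <- ffbs_ar1(yobs, vobs, phi_sv, sigma2, J)
  # persistence via MH on atanh(phi)
  t_cur <- atanh(phi_sv)
  t_prop <- t_cur + exp(ls) * stats::rnorm(1L)
  phi_prop <- tanh(t_prop)
  lp <- function(phi) sv_phi_logpost(phi, h_new, sigma2, hyper) + log1p(-phi^2)
  log_ratio <- lp(phi_prop) - lp(phi_sv)
  acc <- is.finite(log_ratio) && log(stats::runif(1L)) < log_ratio
  phi_new <- if (acc) phi_prop else phi_sv
  # innovation variance: G(1/2, 1/(2 B_sv)) prior x AR(1) path likelihood
  S <- (1 - phi_new^2) * h_new[1L]^2 +
    sum((h_new[-1L] - phi_new * h_new[-(J + 1L)])^2)
  sigma2_new <- rgig(1L, p = 0.5 - (J + 1L) / 2, chi = S, psi = 1 / hyper$B_sv)
  list(h = h_new, phi_sv = phi_new, sigma2 = sigma2_new, accepted = acc,
       alpha = min(1, exp(log_ratio)))
}

sv_indicators <- function(resid, mixture) {
  R <- mixture$R
  lp <- vapply(seq_len(R), function(rr) {
    log(mixture$w[rr]) + stats::dnorm(resid, mixture$m[rr], sqrt(mixture$v[rr]), log = TRUE)
  }, numeric(length(resid)))
  lp <- matrix(lp, ncol = R)
  mx <- lp[cbind(seq_len(nrow(lp)), max.col(lp))]
  pr <- exp(lp - mx)
  cum <- pr
  for (rr in 2:R) cum[, rr] <- cum[, rr] + cum[, rr - 1L]
  u <- stats::runif(nrow(lp)) * cum[, R]
  idx <- rep.int(1L, nrow(lp))
  for (rr in seq_len(R - 1L)) idx <- idx + (u > cum[, rr])
  idx
}

#' Post-hoc sign identification of factor draws
#'
#' The likelihood only identifies the products `phi_g * f_j`; for every
#' stored draw with `phi_1 < 0`, all loadings and the whole factor path are
#' negated, leaving the products unchanged. A draw with `phi_1` exactly zero
#' is left as is (counted in the `zero_phi1` attribute).
#'
#' @param phi Matrix of loading draws (draws x G).
#' @param f Matrix of factor draws (draws x J).
#' @return List with sign-fixed `phi` and `f`; attribute `zero_phi1` counts
#'   draws whose leading loading was exactly zero.
#' @export
identify_signs <- function(phi, f) {
  stopifnot(nrow(phi) == nrow(f))
  flip <- phi[, 1L] < 0
  zero <- sum(phi[, 1L] == 0)
  if (zero > 0) warning(zero, " draw(s) with phi_1 exactly zero left unchanged")
  phi[flip, ] <- -phi[flip, , drop = FALSE]
  f[flip, ] <- -f[flip, , drop = FALSE]
  out <- list(phi = phi, f = f)
  attr(out, "zero_phi1") <- zero
  out
}
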