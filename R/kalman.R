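# Conditionally Gaussian state-space core.
#
# Model (per interval j = 1..J):
#   x_j = Z_j beta_j + eps_j,   eps_j ~ N(0, diag(v_j))
#   beta_j = beta_{j-1} + w_j,  w_j ~ N(0, Q),  Q = diag(theta_0..theta_K)
#   beta_0 ~ N(a0, Q)           (initial state, sampled in the backward pass)
#
# Observation updates use the information form: posterior precision =
# prior precision + Z' V^-1 Z. With diagonal noise this is a single
# crossprod per interval, the same O(n_j (K+1)^2) cost as sequential
# univariate updates but vectorised. Intervals with n_j = 0 are pure
# prediction steps. A variance floor keeps Q invertible while the shrinkage
# prior drives theta towards zero.

#' Build a Gaussian state-space model for the coefficient paths
#'
#' @param x Numeric vector of stacked pseudo-observations, ordered by
#'   interval (as in `expand_survival()$pairs`).
#' @param v Observation variances aligned with `x`.
#' @param Zmat Design matrix (`length(x)` rows, `K + 1` columns, first column
#'   the intercept) aligned with `x`.
#' @param interval Interval index of each row of `x` (values in `1..J`).
#' @param J Number of intervals.
#' @param Q Diagonal of the state-innovation covariance (`theta_0..theta_K`).
#' @param a0 Initial state mean (`beta_0..beta_K` means).
#' @param P0 Diagonal of the initial state covariance; defaults to `Q` since
#'   `beta_{k0} ~ N(beta_k, theta_k)`.
#' @param variance_floor Lower bound applied to `Q` and `P0` inside the filter.
#' @return An object of class `dsm_ssm`.
#' @export
state_space_model <- function(x, v, Zmat, interval, J, Q, a0 = rep(0, ncol(Zmat)),
                              P0 = Q, variance_floor = 1e-12) {
  stopifnot(length(x) == length(v), nrow(Zmat) == length(x),
            length(interval) == length(x), length(Q) == ncol(Zmat),
            length(a0) == ncol(Zmat), all(v > 0), all(Q >= 0), all(P0 >= 0))
  rows <- split(seq_along(x), factor(interval, levels = seq_len(J)))
  structure(
    list(x = x, v = v, Zmat = Zmat, rows = rows, J = J, p = ncol(Zmat),
         Q = pmax(Q, variance_floor), a0 = a0, P0 = pmax(P0, variance_floor)),
    class = "dsm_ssm"
  )
}

chol_inv <- function(A) {
  R <- tryCatch(chol(A), error = function(e) {
    stop("non-positive-definite covariance in the Kalman filter; ",
         "check the variance floor configuration", call. = FALSE)
  })
  chol2inv(R)
}

#' Kalman forward filter
#'
#' Runs the forward filter over intervals `1..J` with a random-walk
#' transition, returning per-interval filtered moments (plus the `j = 0`
#' initial-state prior as the first slot) and the Gaussian marginal
#' log-likelihood of the observations.
#'
#' @param model A [state_space_model()].
#' @param with_loglik Also accumulate the Gaussian marginal log-likelihood of
#'   `x` (skipped inside the sampler, where only the moments are needed).
#' @return List with `m` (`(J+1) x p` filtered means, row `j+1` is interval
#'   `j`), `C` (`p x p x (J+1)` filtered covariances), and `loglik` (`NA`
#'   when not requested).
#' @export
kalman_filter <- function(model, with_loglik = TRUE) {
  stopifnot(inherits(model, "dsm_ssm"))
  p <- model$p
  J <- model$J
  m <- matrix(0, J + 1L, p)
  C <- array(0, c(p, p, J + 1L))
  m[1L, ] <- model$a0
  C[, , 1L] <- diag(model$P0, p)
  mj <- model$a0
  Cj <- diag(model$P0, p)
  Qd <- diag(model$Q, p)
  loglik <- if (with_loglik) 0 else NA_real_
  for (j in seq_len(J)) {
    # predict
    Pp <- Cj + Qd
    mp <- mj
    idx <- model$rows[[j]]
    nj <- length(idx)
    if (nj > 0L) {
      Zj <- model$Zmat[idx, , drop = FALSE]
      vj <- model$v[idx]
      xj <- model$x[idx]
      R_pp <- tryCatch(chol(Pp), error = function(e) {
        stop("non-positive-definite covariance in the Kalman filter; ",
             "check the variance floor configuration", call. = FALSE)
      })
      Pinv <- chol2inv(R_pp)
      Zv <- Zj / vj
      Prec <- Pinv + crossprod(Zv, Zj)
      R_prec <- tryCatch(chol(Prec), error = function(e) {
        stop("non-positive-definite covariance in the Kalman filter; ",
             "check the variance floor configuration", call. = FALSE)
      })
      Cj <- chol2inv(R_prec)
      Cj <- (Cj + t(Cj)) / 2
      mj <- drop(Cj %*% (Pinv %*% mp + crossprod(Zv, xj)))
      if (with_loglik) {
        # marginal log-likelihood via matrix determinant lemma / Woodbury
        r <- xj - drop(Zj %*% mp)
        rv <- r / vj
        Zr <- crossprod(Zj, rv)
        quad <- sum(r * rv) - drop(crossprod(Zr, Cj %*% Zr))
        logdet <- sum(log(vj)) +
          2 * sum(log(diag(R_pp))) + 2 * sum(log(diag(R_prec)))
        loglik <- loglik - 0.5 * (nj * log(2 * pi) + logdet + quad)
      }
    } else {
      Cj <- Pp
      mj <- mp
    }
    m[j + 1L, ] <- mj
    C[, , j + 1L] <- Cj
  }
  list(m = m, C = C, loglik = loglik)
}

draw_mvnorm <- function(mean, Sigma) {
  p <- length(mean)
  Sigma <- (Sigma + t(Sigma)) / 2
  R <- tryCatch(chol(Sigma), error = function(e) chol(Sigma + diag(1e-12, p)))
  drop(mean + t(R) %*% stats::rnorm(p))
}

#' Forward-filtering backward-sampling draw of the coefficient paths
#'
#' Returns one exact joint draw of `beta_{0:J}` from its full conditional
#' given the pseudo-observations, noise variances, innovation variances and
#' initial mean. The initial state `beta_0` is sampled as an extra node in
#' the backward pass so its draw is available to the shrinkage updates.
#'
#' @param model A [state_space_model()].
#' @param filter Optional precomputed [kalman_filter()] result.
#' @return A `(J+1) x p` matrix of states; row 1 is the initial state
#'   `beta_0`, row `j+1` is interval `j`.
#' @export
ffbs <- function(model, filter = NULL) {
  if (is.null(filter)) filter <- kalman_filter(model, with_loglik = FALSE)
  J <- model$J
  p <- model$p
  Qd <- diag(model$Q, p)
  beta <- matrix(0, J + 1L, p)
  beta[J + 1L, ] <- draw_mvnorm(filter$m[J + 1L, ], filter$C[, , J + 1L])
  for (j in seq(J, 1L)) {
    Cj <- filter$C[, , j]
    S <- Cj + Qd
    G <- Cj %*% chol_inv(S)
    mean_j <- filter$m[j, ] + drop(G %*% (beta[j + 1L, ] - filter$m[j, ]))
    var_j <- Cj - G %*% Cj
    beta[j, ] <- draw_mvnorm(mean_j, var_j)
  }
  beta
}
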