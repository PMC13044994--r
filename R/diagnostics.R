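# MCMC convergence diagnostics: split-Rhat and Geyer initial-monotone ESS.

ess_geyer <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(0)
  lag_max <- min(n - 1L, 2000L)
  rho <- drop(stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf)
  # pair sums Gamma_m = rho_{2m} + rho_{2m+1}; keep while positive, enforce
  # monotone non-increasing (Geyer's initial monotone sequence)
  n_pairs <- floor((lag_max + 1L) / 2L)
  gam <- rho[2 * seq_len(n_pairs) - 1L] + rho[2 * seq_len(n_pairs)]
  pos <- which(gam <= 0)
  if (length(pos) > 0) gam <- gam[seq_len(pos[1L] - 1L)]
  if (length(gam) > 1) gam <- cummin(gam)
  iact <- max(-1 + 2 * sum(gam), 1e-8)
  min(n, n / iact)
}

split_rhat <- function(chains) {
  # chains: list of numeric vectors; each split in half
  halves <- unlist(lapply(chains, function(x) {
    n2 <- floor(length(x) / 2L)
    list(x[seq_len(n2)], x[n2 + seq_len(n2)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1L]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' MCMC diagnostics for stored scalar chains
#'
#' Computes the effective sample size (Geyer initial-monotone sequence
#' estimator) and split-Rhat per scalar, flagging any Rhat above 1.1. A
#' chain with zero variance (stuck) gets ESS 0 and an infinite Rhat, and is
#' flagged.
#'
#' @param x A `dsm_fit`, a list of `dsm_fit`s (parallel chains), or a numeric
#'   matrix with one column per scalar parameter (rows are draws).
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `mean`, `ess`, `rhat`,
#'   `flagged`.
#' @export
mcmc_diagnostics <- function(x, ...) {
  UseMethod("mcmc_diagnostics")
}

#' @export
mcmc_diagnostics.matrix <- function(x, ...) {
  if (nrow(x) < 100) stop("need at least 100 draws for diagnostics", call. = FALSE)
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("par", seq_len(ncol(x)))
  tibble::tibble(
    parameter = nm,
    mean = colMeans(x),
    ess = apply(x, 2L, ess_geyer),
    rhat = apply(x, 2L, function(col) split_rhat(list(col)))
  ) |>
    dplyr::mutate(flagged = .data$rhat > 1.1 | !is.finite(.data$rhat))
}

scalar_chain_matrix <- function(fit) {
  dr <- fit$draws
  p <- ncol(dr$theta)
  out <- cbind(dr$theta, dr$beta_mean, dr$a_theta, dr$c_theta, dr$a_beta,
               dr$c_beta, dr$tau_theta, dr$tau_beta, dr$loglik)
  colnames(out) <- c(paste0("theta_", seq_len(p) - 1L),
                     paste0("beta_mean_", seq_len(p) - 1L),
                     "a_theta", "c_theta", "a_beta", "c_beta",
                     "tau_theta", "tau_beta", "loglik")
  if (fit$factor) {
    extra <- cbind(dr$phi, dr$phi_sv, dr$sigma2_f)
    colnames(extra) <- c(paste0("phi_", seq_len(ncol(dr$phi))), "phi_sv", "sigma2_f")
    out <- cbind(out, extra)
  }
  out
}

#' @export
mcmc_diagnostics.dsm_fit <- function(x, ...) {
  if (x$n_draws < 100) stop("need at least 100 stored draws", call. = FALSE)
  mcmc_diagnostics(scalar_chain_matrix(x))
}

#' @export
mcmc_diagnostics.dsm_fit_list <- function(x, ...) {
  if (length(x) < 2) stop("need at least 2 chains", call. = FALSE)
  mats <- lapply(x, scalar_chain_matrix)
  nm <- colnames(mats[[1L]])
  tibble::tibble(
    parameter = nm,
    mean = rowMeans(vapply(mats, colMeans, numeric(length(nm)))),
    ess = rowSums(vapply(mats, function(m) apply(m, 2L, ess_geyer),
                         numeric(length(nm)))),
    rhat = vapply(seq_along(nm), function(k) {
      split_rhat(lapply(mats, function(m) m[, k]))
    }, numeric(1))
  ) |>
    dplyr::mutate(flagged = .data$rhat > 1.1 | !is.finite(.data$rhat))
}
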