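# On-disk persistence of posterior draws: one CSV per parameter block
# (draws x columns, language-agnostic) plus a JSON metadata sidecar.

#' Save posterior draws to a directory
#'
#' Writes each stored parameter block as a CSV (rows are draws; array blocks
#' are flattened column-major with dimension info in the sidecar) and a
#' `meta.json` with the run configuration, partition and covariate names.
#'
#' @param fit A `dsm_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_draws <- function(fit, dir) {
  stopifnot(inherits(fit, "dsm_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dims <- list()
  for (nm in names(fit$draws)) {
    block <- fit$draws[[nm]]
    dims[[nm]] <- if (is.array(block)) dim(block) else c(length(block), 1L)
    flat <- if (length(dim(block)) > 2L) {
      matrix(block, nrow = dim(block)[1L])
    } else {
      as.matrix(block)
    }
    utils::write.csv(flat, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  meta <- list(
    package = "dynshrink",
    blocks = dims,
    n_draws = fit$n_draws,
    partition = fit$partition$S,
    covariates = fit$dataset$covariate_names,
    factor = fit$factor,
    G = fit$G,
    config = fit$config[c("n_iter", "burn_in", "thin", "seed",
                          "events_per_interval", "constant_coefficients",
                          "variance_floor")]
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read posterior draws saved by [save_draws()]
#'
#' @param dir Directory written by [save_draws()].
#' @return A list with `draws` (parameter blocks with their original
#'   dimensions) and `meta`.
#' @export
read_draws <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  draws <- list()
  for (nm in names(meta$blocks)) {
    flat <- as.matrix(utils::read.csv(file.path(dir, paste0(nm, ".csv"))))
    dn <- unlist(meta$blocks[[nm]])
    draws[[nm]] <- if (length(dn) > 2L) {
      array(flat, dim = dn)
    } else if (dn[2L] == 1L) {
      as.numeric(flat)
    } else {
      unname(flat)
    }
  }
  list(draws = draws, meta = meta)
}
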