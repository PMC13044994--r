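#' Assemble a right-censored survival dataset from a data frame
#'
#' Validates and packages subject-level survival records: an observed time
#' (the minimum of the failure and censoring times), an event indicator,
#' a numeric covariate matrix, and an optional group label used by the
#' latent-factor frailty. Covariates that vary across intervals can be
#' supplied later via [tv_design()].
#'
#' @param data A data frame with one row per subject.
#' @param time Name of the column holding the observed survival time
#'   (strictly positive).
#' @param status Name of the event-indicator column (1 = failure observed,
#'   0 = right censored).
#' @param covariates Character vector of covariate column names. Defaults to
#'   every numeric column other than `time`, `status` and `group`.
#' @param group Optional name of a group-label column. Labels are converted
#'   to a contiguous index `1..G`.
#' @return An object of class `survival_data`: a list with elements `y`, `d`,
#'   `Z` (an `N x K` numeric matrix, no intercept), `group` (integer or
#'   `NULL`), `group_levels`, and `covariate_names`.
#' @examples
#' df <- data.frame(time = c(2, 5, 3), status = c(1, 0, 1), x = c(-1, 0, 2))
#' sd <- survival_data(df, covariates = "x")
#' sd$y
#' @export
survival_data <- function(data, time = "time", status = "status",
                          covariates = NULL, group = NULL) {
  stopifnot(is.data.frame(data))
  for (col in c(time, status, covariates, group)) {
    if (!col %in% names(data)) {
      stop("column '", col, "' not found in `data`", call. = FALSE)
    }
  }
  y <- as.numeric(data[[time]])
  d <- as.numeric(data[[status]])
  if (anyNA(y) || any(!is.finite(y))) stop("non-finite survival times", call. = FALSE)
  bad <- which(y <= 0)
  if (length(bad) > 0) {
    stop("observed times must be strictly positive; offending subject(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (!all(d %in% c(0, 1))) stop("`status` must be 0/1", call. = FALSE)
  if (is.null(covariates)) {
    cand <- setdiff(names(data), c(time, status, group))
    covariates <- cand[vapply(data[cand], is.numeric, logical(1))]
  }
  Z <- as.matrix(data[covariates])
  if (length(covariates) > 0) storage.mode(Z) <- "double"
  if (anyNA(Z)) stop("missing values in covariates", call. = FALSE)
  grp <- NULL
  grp_levels <- NULL
  if (!is.null(group)) {
    f <- factor(data[[group]])
    grp <- as.integer(f)
    grp_levels <- levels(f)
    if (nlevels(f) > length(y)) stop("more groups than subjects", call. = FALSE)
  }
  structure(
    list(y = y, d = d, Z = Z, group = grp, group_levels = grp_levels,
         covariate_names = covariates, N = length(y), K = length(covariates)),
    class = "survival_data"
  )
}

#' @export
print.survival_data <- function(x, ...) {
  cat("<survival_data> ", x$N, " subjects, ", sum(x$d), " events, ",
      x$K, " covariates", sep = "")
  if (!is.null(x$group)) cat(", ", length(unique(x$group)), " groups", sep = "")
  cat("\n")
  invisible(x)
}

#' Read a survival dataset from a delimited file
#'
#' @inheritParams survival_data
#' @param path Path to a CSV (or TSV, by extension) file.
#' @param ... Passed on to [survival_data()].
#' @return A `survival_data` object.
#' @export
read_survival_data <- function(path, ...) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  survival_data(df, ...)
}

#' Build an event-driven interval partition
#'
#' Places a grid point after every `events_per_interval`-th observed failure,
#' so that every interior interval carries the same amount of event
#' information. Tied event times each count toward the tally, but duplicate
#' cut points are collapsed so the grid stays strictly increasing. A final
#' point at `max_time` is appended when the last cut falls short of it, so
#' every observation (including censoring times beyond the last event) is
#' representable.
#'
#' @param event_times Numeric vector of observed failure times (subjects with
#'   `status == 1` only).
#' @param events_per_interval Positive integer `m`: one cut after every m-th
#'   sorted event.
#' @param max_time Largest observed time in the dataset; the grid is extended
#'   to cover it.
#' @return An object of class `interval_partition`: list with `S` (grid
#'   `s_0 = 0 < s_1 < ... < s_J`) and `J` (number of intervals).
#' @examples
#' build_partition(c(1, 2, 3, 4), events_per_interval = 2, max_time = 4)$S
#' @export
build_partition <- function(event_times, events_per_interval = 2L, max_time = max(event_times)) {
  if (length(event_times) == 0) stop("no observed events: cannot place a grid", call. = FALSE)
  m <- as.integer(events_per_interval)
  stopifnot(m >= 1L, max_time > 0, all(event_times > 0))
  ev <- sort(as.numeric(event_times))
  if (m > length(ev)) {
    warning("`events_per_interval` exceeds the number of events; using a single interval")
    cuts <- numeric(0)
  } else {
    cuts <- unique(ev[seq(m, length(ev), by = m)])
  }
  if (length(cuts) == 0 || max(cuts) < max_time) cuts <- c(cuts, max_time)
  S <- c(0, cuts)
  if (any(diff(S) <= 0)) stop("internal error: grid not strictly increasing")
  structure(list(S = S, J = length(S) - 1L), class = "interval_partition")
}

#' @export
print.interval_partition <- function(x, ...) {
  cat("<interval_partition> J =", x$J, "intervals on [0,", max(x$S), "]\n")
  invisible(x)
}

#' Expand subject records into per-interval exposures and risk sets
#'
#' Every subject contributes one record per interval they enter: the exposure
#' `u_ij = min(y_i, s_j) - s_{j-1}`, an event flag in their final interval
#' when the failure was observed, and membership in the interval's risk set.
#' Intervals are half-open `(s_{j-1}, s_j]`, so a time equal to a grid point
#' belongs to the interval ending there.
#'
#' @param dataset A [survival_data()] object.
#' @param partition An [build_partition()] object with `s_J >= max(y)`.
#' @return An object of class `expanded_survival`: list with
#'   `pairs` (tibble: `subject`, `interval`, `exposure`, `event`, ordered by
#'   interval then subject), `li` (per-subject final interval index),
#'   `n_risk` (risk-set size per interval), `risk_sets` (list of subject
#'   indices per interval), and the partition.
#' @examples
#' df <- data.frame(time = c(5, 3), status = c(1, 1), x = c(0, 1))
#' sd <- survival_data(df, covariates = "x")
#' pt <- structure(list(S = c(0, 2, 4, 6), J = 3L), class = "interval_partition")
#' expand_survival(sd, pt)$pairs
#' @export
expand_survival <- function(dataset, partition) {
  stopifnot(inherits(dataset, "survival_data"), inherits(partition, "interval_partition"))
  S <- partition$S
  J <- partition$J
  y <- dataset$y
  if (max(y) > S[J + 1L]) {
    stop("subject ", which.max(y), " has time ", max(y),
         " beyond the last grid point ", S[J + 1L], call. = FALSE)
  }
  li <- as.integer(cut(y, breaks = S, right = TRUE, labels = FALSE))
  if (anyNA(li)) {
    stop("subject ", which(is.na(li))[1L], " could not be assigned an interval",
         call. = FALSE)
  }
  risk_sets <- lapply(seq_len(J), function(j) which(li >= j))
  n_risk <- lengths(risk_sets)
  ii <- unlist(risk_sets, use.names = FALSE)
  jj <- rep.int(seq_len(J), n_risk)
  u <- pmin(y[ii], S[jj + 1L]) - S[jj]
  event <- dataset$d[ii] == 1 & jj == li[ii]
  pairs <- tibble::tibble(subject = ii, interval = jj, exposure = u, event = event)
  structure(
    list(pairs = pairs, li = li, n_risk = n_risk, risk_sets = risk_sets,
         partition = partition, N = dataset$N,
         # plain-vector mirrors of the pair columns for the sampler hot path
         u = u, event = event, subject = ii, interval = jj),
    class = "expanded_survival"
  )
}

#' @export
print.expanded_survival <- function(x, ...) {
  cat("<expanded_survival>", nrow(x$pairs), "subject-interval records over",
      x$partition$J, "intervals\n")
  invisible(x)
}

#' Write the expanded subject-by-interval table to CSV
#'
#' @param expanded An [expand_survival()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_expanded <- function(expanded, path) {
  stopifnot(inherits(expanded, "expanded_survival"))
  utils::write.csv(expanded$pairs, path, row.names = FALSE)
  invisible(path)
}

#' Per-interval covariate values in long format
#'
#' Converts a long-format table of time-varying covariate values into the
#' `N x J x K` lookup used by the sampler. Covariates absent from the table
#' are filled from the static covariate matrix.
#'
#' @param dataset A [survival_data()] object.
#' @param partition The interval partition the values refer to.
#' @param tv A data frame with columns `subject`, `interval`, `covariate`,
#'   `value`; `interval` must range over `1..J`.
#' @return A numeric array of dimension `N x J x K`.
#' @export
tv_design <- function(dataset, partition, tv) {
  stopifnot(inherits(dataset, "survival_data"))
  need <- c("subject", "interval", "covariate", "value")
  if (!all(need %in% names(tv))) {
    stop("`tv` needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  J <- partition$J
  if (any(tv$interval < 1 | tv$interval > J)) {
    stop("time-varying covariate intervals do not match the partition (J = ",
         J, ")", call. = FALSE)
  }
  k_idx <- match(tv$covariate, dataset$covariate_names)
  if (anyNA(k_idx)) stop("unknown covariate in `tv`", call. = FALSE)
  arr <- array(rep(dataset$Z, times = J), dim = c(dataset$N, dataset$K, J))
  arr <- aperm(arr, c(1, 3, 2))
  arr[cbind(tv$subject, tv$interval, k_idx)] <- tv$value
  arr
}

#' Covariate vector for a subject-interval pair, with leading intercept
#'
#' Returns `(1, z_i1, ..., z_iK)` for static covariates, or the interval-`j`
#' values when a time-varying design array is present. The intercept column
#' carries the baseline log-hazard.
#'
#' @param dataset A [survival_data()] object.
#' @param i Subject index.
#' @param j Interval index.
#' @param Z_tv Optional `N x J x K` array from [tv_design()].
#' @return Numeric vector of length `K + 1`.
#' @export
covariate_row <- function(dataset, i, j, Z_tv = NULL) {
  stopifnot(inherits(dataset, "survival_data"))
  if (i < 1 || i > dataset$N) stop("subject index out of range", call. = FALSE)
  if (j < 1) stop("interval index out of range", call. = FALSE)
  if (is.null(Z_tv)) {
    z <- if (dataset$K > 0) dataset$Z[i, ] else numeric(0)
  } else {
    if (j > dim(Z_tv)[2]) stop("interval index out of range", call. = FALSE)
    z <- Z_tv[i, j, ]
  }
  c(1, unname(z))
}

# Pair-level design matrix (M x (K+1)) aligned with expanded$pairs.
pair_design <- function(dataset, expanded, Z_tv = NULL) {
  ii <- expanded$subject
  jj <- expanded$interval
  if (is.null(Z_tv)) {
    cbind(1, dataset$Z[ii, , drop = FALSE])
  } else {
    if (dim(Z_tv)[2] != expanded$partition$J) {
      stop("time-varying design has ", dim(Z_tv)[2],
           " intervals but the partition has ", expanded$partition$J, call. = FALSE)
    }
    K <- dim(Z_tv)[3]
    out <- matrix(1, nrow = length(ii), ncol = K + 1L)
    for (k in seq_len(K)) out[, k + 1L] <- Z_tv[cbind(ii, jj, rep.int(k, length(ii)))]
    out
  }
}
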