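#' Per-pattern sufficient statistics of a family dataset
#'
#' Splits a family dataset by observation pattern and computes, for each
#' pattern present, the sample size, sample mean vector and maximum-likelihood
#' (divide-by-n) covariance matrix of the observed variables.  These are the
#' sufficient statistics for the multivariate-normal model, so fitting to
#' them is exactly equivalent to fitting to the raw records.
#'
#' @param data A family dataset (see [load_family_table] or
#'   [simulate_dyads]): a data frame with columns \code{bw},
#'   \code{bw_offspring}, \code{dosage} and a \code{pattern} label.
#' @return A list of \code{"group_summary"} objects (fields \code{pattern},
#'   \code{n}, \code{mean}, \code{cov}).
#' @export
group_summaries <- function(data) {
  data <- as_family_dataset(data)
  out <- list()
  for (pat in OBSERVATION_PATTERNS) {
    rows <- data$pattern == pat
    if (!any(rows)) next
    x <- observed_matrix(data[rows, , drop = FALSE], pat)
    out[[pat]] <- group_summary(pat, nrow(x), colMeans(x), ml_cov(x))
  }
  if (!length(out)) stop("no recognizable observation patterns in data")
  out
}

#' Construct a single group summary
#'
#' @param pattern Observation pattern label.
#' @param n Sample size of the group.
#' @param mean Sample mean vector of the observed variables, in the order
#'   given by [pattern_vars].
#' @param cov Sample covariance matrix (maximum-likelihood, divide-by-n
#'   convention) of the observed variables.
#' @return A \code{"group_summary"} object.
#' @export
group_summary <- function(pattern, n, mean, cov) {
  pattern <- match.arg(pattern, OBSERVATION_PATTERNS)
  vars <- pattern_vars(pattern)
  k <- length(vars)
  mean <- stats::setNames(as.numeric(mean), vars)
  cov <- as.matrix(cov)
  stopifnot(nrow(cov) == k, ncol(cov) == k)
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("sample covariance matrix must be symmetric")
  if (n < k + 1) stop("group sample size below number of observed variables + 1")
  dimnames(cov) <- list(vars, vars)
  structure(list(pattern = pattern, n = as.numeric(n), mean = mean,
                 cov = (cov + t(cov)) / 2),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Group summary: pattern %s, n = %g\n", x$pattern, x$n))
  print(round(x$mean, digits)); print(round(x$cov, digits))
  invisible(x)
}

# extract the observed-variable matrix for rows of one pattern
observed_matrix <- function(rows, pattern) {
  cols <- c(bw = "bw", bw_offspring = "bw_offspring", snp = "dosage")
  x <- as.matrix(rows[, cols[pattern_vars(pattern)], drop = FALSE])
  colnames(x) <- pattern_vars(pattern)
  x
}

ml_cov <- function(x) crossprod(sweep(x, 2, colMeans(x))) / nrow(x)

#' Multigroup -2 log-likelihood from covariance summaries
#'
#' Evaluates minus twice the multivariate-normal log-likelihood of the path
#' model from per-pattern sufficient statistics: the sum over groups of
#' \eqn{n [\log|\Sigma| + tr(S\Sigma^{-1}) +
#' (\bar x - \mu)' \Sigma^{-1} (\bar x - \mu) + k \log 2\pi]},
#' where \eqn{\Sigma} and \eqn{\mu} are the model-implied moments for the
#' group's observation pattern.  With maximum-likelihood (divide-by-n) sample
#' covariances this equals [neg2_loglik_raw] on the underlying records.
#'
#' @param params A [path_model_params] object.
#' @param groups A list of group summaries (see [group_summaries]).
#' @param on_invalid What to do when the implied covariance is singular or
#'   indefinite at \code{params}: \code{"error"} signals an
#'   invalid-parameter condition, \code{"inf"} returns \code{Inf} (useful
#'   inside optimizers).
#' @return Scalar value of -2 log L.
#' @export
neg2_loglik_cov <- function(params, groups, on_invalid = c("error", "inf")) {
  on_invalid <- match.arg(on_invalid)
  if (inherits(groups, "group_summary")) groups <- list(groups)
  total <- 0
  for (g in groups) {
    vars <- pattern_vars(g$pattern)
    sigma <- implied_cov_full(params)[vars, vars, drop = FALSE]
    ch <- try(chol(sigma), silent = TRUE)
    if (inherits(ch, "try-error")) {
      if (on_invalid == "inf") return(Inf)
      invalid_params("implied covariance not positive definite for pattern " %+% g$pattern)
    }
    sinv <- chol2inv(ch)
    d <- g$mean - implied_mean_full(params)[vars]
    logdet <- 2 * sum(log(diag(ch)))
    k <- length(vars)
    total <- total + g$n * (logdet + sum(sinv * g$cov) +
                              drop(d %*% sinv %*% d) + k * log(2 * pi))
  }
  total
}

`%+%` <- function(a, b) paste0(a, b)

#' Full-information -2 log-likelihood from raw records
#'
#' Evaluates minus twice the log-likelihood of the path model by summing the
#' multivariate-normal log-density of each record's observed subvector under
#' the implied moments for its observation pattern.  Records missing one
#' phenotype contribute through their two-variable marginal, so no case is
#' deleted (full-information maximum likelihood).
#'
#' This deliberately walks the records one pattern at a time rather than
#' collapsing to sufficient statistics; [neg2_loglik_cov] on
#' [group_summaries] of the same data gives the identical value and is the
#' fast route.
#'
#' @inheritParams neg2_loglik_cov
#' @param data A family dataset with pattern labels.
#' @return Scalar value of -2 log L.
#' @export
neg2_loglik_raw <- function(params, data, on_invalid = c("error", "inf")) {
  on_invalid <- match.arg(on_invalid)
  data <- as_family_dataset(data)
  total <- 0
  for (pat in OBSERVATION_PATTERNS) {
    rows <- data$pattern == pat
    if (!any(rows)) next
    x <- observed_matrix(data[rows, , drop = FALSE], pat)
    vars <- pattern_vars(pat)
    sigma <- implied_cov_full(params)[vars, vars, drop = FALSE]
    ch <- try(chol(sigma), silent = TRUE)
    if (inherits(ch, "try-error")) {
      if (on_invalid == "inf") return(Inf)
      invalid_params("implied covariance not positive definite for pattern " %+% pat)
    }
    sinv <- chol2inv(ch)
    d <- sweep(x, 2, implied_mean_full(params)[vars])
    quad <- rowSums((d %*% sinv) * d)
    k <- length(vars)
    total <- total + nrow(x) * (2 * sum(log(diag(ch))) + k * log(2 * pi)) +
      sum(quad)
  }
  total
}
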