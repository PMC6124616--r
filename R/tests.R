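#' Wald test for a single path
#'
#' Tests the maternal or fetal path against zero using the squared ratio of
#' estimate to standard error, referred to a chi-square distribution with one
#' degree of freedom.
#'
#' @param fit A converged [fit_sem] result in which the requested path is
#'   free.
#' @param which \code{"maternal"} or \code{"fetal"}.
#' @return A \code{"sem_test"} object: \code{name} (\code{wald_m} /
#'   \code{wald_f}), \code{statistic}, \code{df}, \code{p_value}.
#' @export
wald_test <- function(fit, which = c("maternal", "fetal")) {
  which <- match.arg(which)
  stopifnot(inherits(fit, "sem_fit"))
  par <- if (which == "maternal") "m" else "f"
  free <- if (which == "maternal") fit$spec$free_maternal else fit$spec$free_fetal
  if (!free) stop("the ", which, " path is fixed at zero in this fit")
  est <- fit$theta[par]; se <- fit$se[par]
  if (!is.finite(se) || se <= 0)
    stop("standard error unavailable (singular Hessian); cannot form Wald test")
  stat <- unname((est / se)^2)
  sem_test(if (which == "maternal") "wald_m" else "wald_f", stat, 1L)
}

sem_test <- function(name, statistic, df) {
  structure(list(name = name, statistic = statistic, df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE)),
            class = "sem_test")
}

#' Likelihood-ratio test between nested model variants
#'
#' Compares a full fit with a reduced fit in which one or both paths are
#' fixed at zero.  The statistic is the difference in -2 log-likelihood
#' (floored at zero against optimizer noise) on chi-square with degrees of
#' freedom equal to the number of paths dropped.  Dropping both paths gives
#' the 2-degrees-of-freedom omnibus test of any SNP effect.
#'
#' @param full,reduced [fit_sem] results on the same data; \code{reduced}'s
#'   free paths must be a strict subset of \code{full}'s.
#' @return A \code{"sem_test"} with name \code{lrt_m} (maternal path
#'   dropped), \code{lrt_f} (fetal dropped) or \code{two_df} (both).
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "sem_fit"), inherits(reduced, "sem_fit"))
  drop_m <- full$spec$free_maternal && !reduced$spec$free_maternal
  drop_f <- full$spec$free_fetal && !reduced$spec$free_fetal
  gain_m <- !full$spec$free_maternal && reduced$spec$free_maternal
  gain_f <- !full$spec$free_fetal && reduced$spec$free_fetal
  if (gain_m || gain_f)
    stop("reduced model must be nested in the full model")
  if (!identical(full$n_by_pattern, reduced$n_by_pattern))
    stop("fits appear to come from different data (group sizes differ)")
  df <- drop_m + drop_f
  stat <- max(0, reduced$neg2ll - full$neg2ll)
  if (df == 0) # identical specs: no evidence either way
    return(structure(list(name = "lrt_0df", statistic = 0, df = 0L,
                          p_value = 1), class = "sem_test"))
  sem_test(if (df == 2) "two_df" else if (drop_m) "lrt_m" else "lrt_f",
           stat, df)
}

#' Omnibus 2-degrees-of-freedom test of any SNP effect
#'
#' Convenience wrapper: fits the full model and the null model (both paths
#' fixed at zero) to the same data and returns their likelihood-ratio test.
#'
#' @inheritParams fit_sem
#' @return A \code{"sem_test"} with name \code{two_df}.
#' @export
two_df_test <- function(data, restarts = 10, seed = NULL) {
  full <- fit_sem(data, model_spec(TRUE, TRUE), restarts = restarts, seed = seed)
  null <- fit_sem(data, model_spec(FALSE, FALSE), restarts = restarts, seed = seed)
  lrt(full, null)
}

#' @export
print.sem_test <- function(x, digits = 4, ...) {
  cat(sprintf("%s: chi-square = %.*f, df = %d, p = %.3g\n",
              x$name, digits, x$statistic, x$df, x$p_value))
  invisible(x)
}
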