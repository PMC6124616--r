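#' Model variant specification
#'
#' The four SEM variants are obtained by freeing or fixing the maternal and
#' fetal paths: both free (the full model), fetal only, maternal only, or
#' neither (the null model used by the 2-degrees-of-freedom omnibus test).
#'
#' @param free_maternal Estimate the maternal path? (otherwise fixed at 0)
#' @param free_fetal Estimate the fetal path?
#' @return A \code{"model_spec"} object.
#' @export
model_spec <- function(free_maternal = TRUE, free_fetal = TRUE) {
  structure(list(free_maternal = isTRUE(free_maternal),
                 free_fetal = isTRUE(free_fetal)),
            class = "model_spec")
}

# Working-scale parameterization: m, f and rho unconstrained, variances on
# the log scale (positivity by construction); means free.  Which entries are
# free depends on the model spec and on which variables any group observes:
# rho enters only the complete-data pattern, var_eo/mu_bwo only patterns
# observing the offspring phenotype, etc.
free_param_names <- function(spec, groups) {
  pats <- vapply(groups, function(g) g$pattern, character(1))
  has_bw  <- any(pats %in% c("both", "own_only"))
  has_bwo <- any(pats %in% c("both", "offspring_only"))
  has_both <- any(pats == "both")
  nm <- c(if (spec$free_maternal) "m",
          if (spec$free_fetal) "f",
          "log_phi",
          if (has_bw) "log_var_e",
          if (has_bwo) "log_var_eo",
          if (has_both) "rho",
          if (has_bw) "mu_bw",
          if (has_bwo) "mu_bwo",
          "mu_snp")
  nm
}

theta_to_params <- function(theta, spec) {
  g <- function(nm, default) if (nm %in% names(theta)) unname(theta[nm]) else default
  path_model_params(
    m = if (spec$free_maternal) unname(theta["m"]) else 0,
    f = if (spec$free_fetal) unname(theta["f"]) else 0,
    phi = exp(unname(theta["log_phi"])),
    var_e  = exp(g("log_var_e", 0)),
    var_eo = exp(g("log_var_eo", 0)),
    rho = g("rho", if ("rho" %in% names(theta)) NA else 0),
    mu_bw = g("mu_bw", 0), mu_bwo = g("mu_bwo", 0),
    mu_snp = unname(theta["mu_snp"]),
    validate = FALSE)
}

# Moment-based starting values.  For complete data the full model is
# just-identified, so these solve the moment equations exactly and are the
# MLE up to sampling of the reduced patterns; for reduced models they are a
# good neighborhood.
start_values <- function(spec, groups) {
  pats <- vapply(groups, function(g) g$pattern, character(1))
  wmean <- function(vals, ns) sum(vals * ns) / sum(ns)
  phi0 <- wmean(vapply(groups, function(g) g$cov["snp", "snp"], 0),
                vapply(groups, function(g) g$n, 0))
  pick <- function(var) {
    sel <- vapply(groups, function(g) var %in% pattern_vars(g$pattern), logical(1))
    groups[sel]
  }
  covsnp <- function(gs, var) {
    if (!length(gs)) return(NA_real_)
    wmean(vapply(gs, function(g) g$cov[var, "snp"], 0),
          vapply(gs, function(g) g$n, 0))
  }
  g_bw <- pick("bw"); g_bwo <- pick("bw_offspring")
  c1 <- covsnp(g_bw, "bw") / phi0          # f + m/2
  c2 <- covsnp(g_bwo, "bw_offspring") / phi0  # m + f/2
  if (is.na(c1)) c1 <- 0
  if (is.na(c2)) c2 <- 0
  if (spec$free_maternal && spec$free_fetal) {
    f0 <- (4 * c1 - 2 * c2) / 3; m0 <- (4 * c2 - 2 * c1) / 3
  } else if (spec$free_fetal) {
    m0 <- 0; f0 <- (c1 + c2 / 2) / 1.25
  } else if (spec$free_maternal) {
    f0 <- 0; m0 <- (c2 + c1 / 2) / 1.25
  } else m0 <- f0 <- 0
  gvar <- phi0 * (m0^2 + f0^2 + m0 * f0)
  v_bw <- if (length(g_bw))
    wmean(vapply(g_bw, function(g) g$cov["bw", "bw"], 0),
          vapply(g_bw, function(g) g$n, 0)) else 1
  v_bwo <- if (length(g_bwo))
    wmean(vapply(g_bwo, function(g) g$cov["bw_offspring", "bw_offspring"], 0),
          vapply(g_bwo, function(g) g$n, 0)) else 1
  ve0 <- max(v_bw - gvar, 0.05 * v_bw)
  veo0 <- max(v_bwo - gvar, 0.05 * v_bwo)
  bothg <- groups[pats == "both"]
  rho0 <- if (length(bothg)) {
    cb <- wmean(vapply(bothg, function(g) g$cov["bw", "bw_offspring"], 0),
                vapply(bothg, function(g) g$n, 0))
    cb - phi0 * ((m0^2 + f0^2) / 2 + 1.25 * m0 * f0)
  } else 0
  rho0 <- sign(rho0) * min(abs(rho0), 0.95 * sqrt(ve0 * veo0))
  mu <- function(gs, var) {
    if (!length(gs)) return(0)
    wmean(vapply(gs, function(g) g$mean[var], 0),
          vapply(gs, function(g) g$n, 0))
  }
  full <- c(m = m0, f = f0, log_phi = log(phi0),
            log_var_e = log(ve0), log_var_eo = log(veo0), rho = rho0,
            mu_bw = mu(g_bw, "bw"), mu_bwo = mu(g_bwo, "bw_offspring"),
            mu_snp = mu(groups, "snp"))
  full[free_param_names(spec, groups)]
}

#' Fit the maternal/fetal path model by maximum likelihood
#'
#' Minimizes the multigroup -2 log-likelihood over the free parameters of the
#' requested model variant.  Variances are optimized on the log scale;
#' positive definiteness of the implied covariance is checked at every
#' evaluation.  Starting values come from closed-form moment equations;
#' if a fit fails to converge (or its Hessian is singular), up to
#' \code{restarts} jittered restarts are attempted and the best converged fit
#' returned.  Standard errors come from the inverse of a central
#' finite-difference Hessian of the negative log-likelihood at the optimum.
#'
#' @param data A family dataset (data frame) or a list of group summaries
#'   (see [group_summaries] and [summary_stats_to_group]).
#' @param spec A [model_spec]; default estimates both paths.
#' @param restarts Maximum number of jittered restarts on failure.
#' @param seed Optional seed for restart jitter.
#' @param engine \code{"cov"} fits to per-pattern sufficient statistics
#'   (fast, exactly equivalent); \code{"raw"} evaluates the record-wise
#'   full-information likelihood directly.
#' @return A \code{"sem_fit"} object: estimates (a [path_model_params]),
#'   \code{se} (named vector on the working scale; \code{se["m"]} and
#'   \code{se["f"]} are directly interpretable), \code{vcov}, \code{neg2ll},
#'   \code{converged}, \code{n_restarts_used}, group sizes.
#' @examples
#' d <- simulate_dyads(scenario_config(n_families = 3000, v_fetal = 0.01, seed = 2))
#' fit <- fit_sem(d)
#' coef(fit)[c("m", "f")]
#' @export
fit_sem <- function(data, spec = model_spec(), restarts = 10, seed = NULL,
                    engine = c("cov", "raw")) {
  engine <- match.arg(engine)
  stopifnot(inherits(spec, "model_spec"))
  if (is.data.frame(data)) {
    raw <- as_family_dataset(data)
    groups <- group_summaries(raw)
  } else {
    if (inherits(data, "group_summary")) data <- list(data)
    stopifnot(all(vapply(data, inherits, logical(1), "group_summary")))
    groups <- data
    if (engine == "raw") stop("engine = 'raw' requires a raw family dataset")
  }
  objective <- if (engine == "cov") {
    function(theta) neg2_loglik_cov(theta_to_params(theta, spec), groups,
                                    on_invalid = "inf")
  } else {
    function(theta) neg2_loglik_raw(theta_to_params(theta, spec), raw,
                                    on_invalid = "inf")
  }
  nm <- free_param_names(spec, groups)
  start <- start_values(spec, groups)
  if (!is.null(seed)) set.seed(seed)

  attempt <- function(theta0) {
    fit <- try(stats::optim(theta0, function(x) objective(stats::setNames(x, nm)),
                            method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) return(NULL)
    fit
  }

  best <- attempt(start)
  used <- 0L
  ok <- function(fit) !is.null(fit) && fit$convergence == 0
  while (!ok(best) && used < restarts) {
    used <- used + 1L
    jitter <- stats::rnorm(length(start), 0, 0.2 * pmax(abs(start), 0.05))
    cand <- attempt(start + jitter)
    if (!is.null(cand) && (is.null(best) || cand$value < best$value)) best <- cand
  }
  if (is.null(best))
    return(failed_fit(spec, nm, groups, used))
  theta <- stats::setNames(best$par, nm)

  h <- fd_hessian(function(x) objective(stats::setNames(x, nm)) / 2, best$par)
  vc <- try(solve(h), silent = TRUE)
  se <- rep(NA_real_, length(nm)); names(se) <- nm
  hess_ok <- !inherits(vc, "try-error") && all(is.finite(diag(vc))) &&
    all(diag(vc) > 0)
  if (hess_ok) {
    se <- sqrt(diag(vc)); names(se) <- nm
    dimnames(vc) <- list(nm, nm)
  } else vc <- NULL

  params <- theta_to_params(theta, spec)
  # mark structurally absent pieces as NA in the reported estimates
  if (!("rho" %in% nm)) params$rho <- NA_real_
  if (!("log_var_eo" %in% nm)) { params$var_eo <- NA_real_; params$mu_bwo <- NA_real_ }
  if (!("log_var_e" %in% nm)) { params$var_e <- NA_real_; params$mu_bw <- NA_real_ }
  structure(list(spec = spec, estimates = params, theta = theta, se = se,
                 vcov = vc, neg2ll = best$value,
                 converged = best$convergence == 0 && hess_ok,
                 n_restarts_used = used,
                 n_by_pattern = vapply(groups, function(g) g$n,
                                       numeric(1),
                                       USE.NAMES = FALSE) |>
                   stats::setNames(vapply(groups, function(g) g$pattern, character(1))),
                 engine = engine),
            class = "sem_fit")
}

failed_fit <- function(spec, nm, groups, used) {
  structure(list(spec = spec, estimates = NULL,
                 theta = stats::setNames(rep(NA_real_, length(nm)), nm),
                 se = stats::setNames(rep(NA_real_, length(nm)), nm),
                 vcov = NULL, neg2ll = NA_real_, converged = FALSE,
                 n_restarts_used = used,
                 n_by_pattern = vapply(groups, function(g) g$n, numeric(1),
                                       USE.NAMES = FALSE) |>
                   stats::setNames(vapply(groups, function(g) g$pattern, character(1))),
                 engine = "cov"),
            class = "sem_fit")
}

# Central finite-difference Hessian, step 1e-4 on each working coordinate.
fd_hessian <- function(fn, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- fn(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h)
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(k), j, h)
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) -
           fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h^2)
    }
  }
  H
}

#' @export
coef.sem_fit <- function(object, ...) {
  if (is.null(object$estimates)) return(NULL)
  unlist(object$estimates)
}

#' @export
vcov.sem_fit <- function(object, ...) object$vcov

#' @export
logLik.sem_fit <- function(object, ...) {
  structure(-object$neg2ll / 2, df = length(object$theta), class = "logLik")
}

#' @export
print.sem_fit <- function(x, digits = 4, ...) {
  free <- c(if (x$spec$free_maternal) "maternal", if (x$spec$free_fetal) "fetal")
  cat("SEM fit (free paths:", if (length(free)) paste(free, collapse = ", ")
      else "none", ")\n")
  if (!x$converged) cat("  ** did not converge **\n")
  if (!is.null(x$estimates)) {
    est <- unlist(x$estimates)
    cat(sprintf("  m = %.*f (SE %.*f), f = %.*f (SE %.*f)\n",
                digits, est["m"], digits, x$se["m"],
                digits, est["f"], digits, x$se["f"]))
    cat(sprintf("  -2 log L = %.*f; restarts used: %d\n", digits, x$neg2ll,
                x$n_restarts_used))
  }
  invisible(x)
}
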