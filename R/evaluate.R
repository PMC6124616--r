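#' Run one Monte-Carlo scenario
#'
#' Simulates \code{config$n_replicates} independent replicates of the
#' scenario, and per replicate fits the requested model variants and
#' computes the requested tests: Wald tests of each free path from the full
#' SEM, likelihood-ratio tests of each path (full versus single-path
#' models), the 2-degrees-of-freedom omnibus test (full versus null), and
#' the two unconditional linear-model comparators.  Aggregates rejection
#' rates at \code{alpha}, per-path mean estimates, bias with a 95\%
#' confidence interval, mean reported standard errors, and the replicate
#' convergence rate (non-converged replicates are excluded from aggregation
#' and counted).
#'
#' @param config A [scenario_config]; replicate r is seeded with
#'   \code{config$seed + r}, so results are deterministic given the config.
#' @param tests Character subset of
#'   \code{c("wald", "lrt", "two_df", "lm")}; fewer tests mean fewer model
#'   fits per replicate.
#' @param alpha Significance level for rejection rates.
#' @return A \code{"scenario_result"}: list with \code{config},
#'   \code{truth}, \code{rates} (named rejection rates), \code{paths}
#'   (per-path mean estimate, bias, bias CI, mean SE, empirical SD),
#'   \code{n_converged}, \code{convergence_rate}, \code{flagged}.
#' @examples
#' \donttest{
#' res <- run_scenario(scenario_config(n_families = 2000, n_replicates = 20,
#'                                     v_fetal = 0.01, seed = 3),
#'                     tests = "wald")
#' res$rates
#' }
#' @export
run_scenario <- function(config, tests = c("wald", "lrt", "two_df", "lm"),
                         alpha = 0.05) {
  stopifnot(inherits(config, "scenario_config"))
  tests <- match.arg(tests, several.ok = TRUE)
  tr <- scenario_truth(config)
  R <- config$n_replicates
  need_full <- TRUE
  need_null <- "two_df" %in% tests
  need_single <- "lrt" %in% tests
  rho_estimable <- config$missing_design != "iv"

  cols <- c("m_hat", "f_hat", "se_m", "se_f", "rho_hat",
            "p_wald_m", "p_wald_f", "p_lrt_m", "p_lrt_f", "p_two_df",
            "p_lm_fetal", "p_lm_maternal", "b_lm_fetal", "b_lm_maternal",
            "converged", "restarts")
  rec <- matrix(NA_real_, R, length(cols), dimnames = list(NULL, cols))

  for (r in seq_len(R)) {
    d <- simulate_dyads(config, replicate = r, keep_truth = FALSE)
    groups <- group_summaries(d)
    full <- fit_sem(groups, model_spec(TRUE, TRUE))
    rec[r, "converged"] <- as.numeric(full$converged)
    rec[r, "restarts"] <- full$n_restarts_used
    if (full$converged) {
      rec[r, "m_hat"] <- full$theta["m"]; rec[r, "f_hat"] <- full$theta["f"]
      rec[r, "se_m"] <- full$se["m"]; rec[r, "se_f"] <- full$se["f"]
      if (rho_estimable) rec[r, "rho_hat"] <- full$theta["rho"]
      if ("wald" %in% tests) {
        rec[r, "p_wald_m"] <- wald_test(full, "maternal")$p_value
        rec[r, "p_wald_f"] <- wald_test(full, "fetal")$p_value
      }
      if (need_single) {
        fet <- fit_sem(groups, model_spec(FALSE, TRUE))
        mat <- fit_sem(groups, model_spec(TRUE, FALSE))
        if (fet$converged) rec[r, "p_lrt_m"] <- lrt(full, fet)$p_value
        if (mat$converged) rec[r, "p_lrt_f"] <- lrt(full, mat)$p_value
      }
      if (need_null) {
        null <- fit_sem(groups, model_spec(FALSE, FALSE))
        if (null$converged) rec[r, "p_two_df"] <- lrt(full, null)$p_value
      }
    }
    if ("lm" %in% tests) {
      lmres <- linear_model_effects(d)
      rec[r, "b_lm_fetal"] <- lmres$beta[lmres$effect == "fetal"]
      rec[r, "p_lm_fetal"] <- lmres$p[lmres$effect == "fetal"]
      rec[r, "b_lm_maternal"] <- lmres$beta[lmres$effect == "maternal"]
      rec[r, "p_lm_maternal"] <- lmres$p[lmres$effect == "maternal"]
    }
  }

  conv <- rec[, "converged"] == 1
  rate <- function(p) mean(p[conv] < alpha, na.rm = TRUE)
  rates <- c(wald_m = if ("wald" %in% tests) rate(rec[, "p_wald_m"]),
             wald_f = if ("wald" %in% tests) rate(rec[, "p_wald_f"]),
             lrt_m = if (need_single) rate(rec[, "p_lrt_m"]),
             lrt_f = if (need_single) rate(rec[, "p_lrt_f"]),
             two_df = if (need_null) rate(rec[, "p_two_df"]),
             lm_fetal = if ("lm" %in% tests) mean(rec[, "p_lm_fetal"] < alpha),
             lm_maternal = if ("lm" %in% tests) mean(rec[, "p_lm_maternal"] < alpha))

  path_stats <- function(est, se, truth) {
    est <- est[conv]; se <- se[conv]
    bias <- mean(est) - truth
    mc_se <- stats::sd(est) / sqrt(length(est))
    c(mean_estimate = mean(est), bias = bias,
      bias_ci_lo = bias - 1.96 * mc_se, bias_ci_hi = bias + 1.96 * mc_se,
      mean_se = mean(se), sd_estimate = stats::sd(est))
  }
  paths <- rbind(maternal = path_stats(rec[, "m_hat"], rec[, "se_m"], tr$m),
                 fetal = path_stats(rec[, "f_hat"], rec[, "se_f"], tr$f))
  if ("lm" %in% tests)
    paths <- rbind(paths,
                   lm_fetal = path_stats(rec[, "b_lm_fetal"],
                                         rep(NA_real_, R), tr$f),
                   lm_maternal = path_stats(rec[, "b_lm_maternal"],
                                            rep(NA_real_, R), tr$m))

  n_conv <- sum(conv)
  structure(list(config = config, truth = tr, alpha = alpha,
                 rates = rates, paths = paths,
                 mean_rho = if (rho_estimable) mean(rec[conv, "rho_hat"]) else NA_real_,
                 replicates = rec,
                 n_converged = n_conv, convergence_rate = n_conv / R,
                 flagged = (n_conv / R) < 0.9),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, digits = 3, ...) {
  cat("Scenario result (", x$config$n_replicates, "replicates,",
      x$n_converged, "converged", if (x$flagged) "** <90% convergence **",
      ")\n")
  cat("rejection rates at alpha =", x$alpha, ":\n")
  print(round(x$rates, digits))
  cat("path estimates:\n")
  print(round(x$paths, max(digits, 4)))
  invisible(x)
}

#' Run a grid of scenarios
#'
#' Expands the supplied settings into their Cartesian product and runs each
#' resulting scenario, mirroring the study grids (effect sizes by allele
#' frequency by sign; measurement-error R-squared levels; missingness
#' designs).
#'
#' @param ... Named [scenario_config] arguments, each a vector of values to
#'   cross (e.g. \code{v_fetal = c(0, 2e-4, 4e-4), p = c(0.5, 0.9)}).
#' @param tests,alpha Passed to [run_scenario].
#' @param verbose Print per-scenario progress lines?
#' @return List of class \code{"scenario_grid"}: \code{results} (one
#'   [run_scenario] result per grid point) and \code{table} (the
#'   [format_results_table] summary).
#' @export
run_grid <- function(..., tests = c("wald", "lrt", "two_df", "lm"),
                     alpha = 0.05, verbose = FALSE) {
  settings <- list(...)
  stopifnot(length(settings) > 0, !is.null(names(settings)),
            all(nzchar(names(settings))))
  grid <- expand.grid(settings, stringsAsFactors = FALSE)
  results <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- do.call(scenario_config, as.list(grid[i, , drop = FALSE]))
    if (verbose)
      message(sprintf("scenario %d/%d: V_O=%g V_M=%g p=%g R2=(%g,%g) design=%s",
                      i, nrow(grid), cfg$v_fetal, cfg$v_maternal, cfg$p,
                      cfg$r2_own, cfg$r2_offspring, cfg$missing_design))
    results[[i]] <- run_scenario(cfg, tests = tests, alpha = alpha)
    if (verbose && results[[i]]$flagged)
      message("  flagged: convergence rate ",
              round(results[[i]]$convergence_rate, 3))
  }
  structure(list(results = results, table = format_results_table(results)),
            class = "scenario_grid")
}

#' Tabulate scenario results
#'
#' Produces a long-format summary table with one row per scenario and path
#' (fetal and maternal sections): scenario descriptors (measurement-error
#' R-squared for each phenotype, effect sizes, allele frequency, missingness
#' design), then mean estimate, mean standard error and power for the Wald
#' test of that path, plus omnibus and comparator rates where computed.
#'
#' @param results A list of [run_scenario] results (or a
#'   \code{"scenario_grid"}).
#' @return A data frame; write it with [write_results] and re-read it with
#'   \code{read.delim} for a lossless round trip.
#' @export
format_results_table <- function(results) {
  if (inherits(results, "scenario_grid")) results <- results$results
  if (inherits(results, "scenario_result")) results <- list(results)
  stopifnot(length(results) > 0)
  rows <- list()
  for (res in results) {
    cfg <- res$config
    for (path in c("fetal", "maternal")) {
      wald <- res$rates[if (path == "fetal") "wald_f" else "wald_m"]
      lmrate <- res$rates[if (path == "fetal") "lm_fetal" else "lm_maternal"]
      rows[[length(rows) + 1L]] <- data.frame(
        path = path,
        r2_bw = cfg$r2_own, r2_bwo = cfg$r2_offspring,
        v_fetal = cfg$v_fetal, v_maternal = cfg$v_maternal, p = cfg$p,
        missing_design = cfg$missing_design,
        discretized = cfg$discretize_offspring,
        n_families = cfg$n_families, n_replicates = cfg$n_replicates,
        mean_estimate = unname(res$paths[path, "mean_estimate"]),
        mean_se = unname(res$paths[path, "mean_se"]),
        power = unname(wald),
        bias = unname(res$paths[path, "bias"]),
        bias_ci_lo = unname(res$paths[path, "bias_ci_lo"]),
        bias_ci_hi = unname(res$paths[path, "bias_ci_hi"]),
        power_two_df = if ("two_df" %in% names(res$rates))
          unname(res$rates["two_df"]) else NA_real_,
        power_lm = if (!is.null(lmrate) && !is.na(lmrate))
          unname(lmrate) else NA_real_,
        convergence_rate = res$convergence_rate,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
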