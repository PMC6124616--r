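#' Simulation scenario configuration
#'
#' Describes one Monte-Carlo scenario for the mother-offspring dyad
#' generator: the genetic architecture, the shared-confounder loading,
#' phenotype degradation (classical measurement error, unit rounding) and the
#' missingness design.  Defaults are the study conditions used throughout:
#' 30 000 dyads per replicate, allele frequency 0.5, confounder loading 0.5
#' on both phenotypes, clean complete data.
#'
#' Effect sizes are given as signed fractions of phenotypic variance
#' explained (e.g. \code{v_fetal = 4e-4} for 0.04\%); the working path
#' coefficient is the signed square root, so a negative fraction encodes an
#' allele that decreases the phenotype.
#'
#' @param n_families Number of mother-offspring dyads per replicate.
#' @param p Effect-allele frequency, in (0, 1).
#' @param v_fetal Signed fraction of phenotypic variance explained by the
#'   fetal path (own genotype on own phenotype).
#' @param v_maternal Signed fraction explained by the maternal path (mother's
#'   genotype on offspring phenotype).
#' @param beta_u Loading of the shared standard-normal confounder on each
#'   phenotype (the same loading applies to both, so the true residual
#'   covariance is \code{beta_u^2}).
#' @param r2_own,r2_offspring Classical measurement-error severity for each
#'   phenotype, expressed as the R-squared of the degraded measure regressed
#'   on the true one; 1 means no error.
#' @param discretize_offspring Round the offspring phenotype to the nearest
#'   unit on its standardized scale (emulating pound-rounded birthweight
#'   reports, which leave about six distinct values)?
#' @param missing_design One of \code{"complete"}, \code{"i"} (half the
#'   sample own-phenotype-only), \code{"ii"} (half offspring-only),
#'   \code{"iii"} (half complete, quarter own-only, quarter offspring-only),
#'   \code{"iv"} (half own-only, half offspring-only: nobody has both, so
#'   the residual covariance is not estimable).
#' @param n_replicates Number of Monte-Carlo replicates for [run_scenario].
#' @param seed Integer seed; replicate r uses \code{seed + r}.
#' @return A \code{"scenario_config"} object.
#' @examples
#' scenario_config(v_fetal = 4e-4, n_replicates = 100, seed = 1)
#' @export
scenario_config <- function(n_families = 30000, p = 0.5,
                            v_fetal = 0, v_maternal = 0, beta_u = 0.5,
                            r2_own = 1, r2_offspring = 1,
                            discretize_offspring = FALSE,
                            missing_design = c("complete", "i", "ii", "iii", "iv"),
                            n_replicates = 1000, seed = 1L) {
  missing_design <- match.arg(missing_design)
  stopifnot(n_families >= 2, p > 0, p < 1,
            abs(v_fetal) <= 1, abs(v_maternal) <= 1,
            r2_own > 0, r2_own <= 1, r2_offspring > 0, r2_offspring <= 1,
            n_replicates >= 1)
  cfg <- structure(list(n_families = as.integer(n_families), p = p,
                        v_fetal = v_fetal, v_maternal = v_maternal,
                        beta_u = beta_u, r2_own = r2_own,
                        r2_offspring = r2_offspring,
                        discretize_offspring = isTRUE(discretize_offspring),
                        missing_design = missing_design,
                        n_replicates = as.integer(n_replicates),
                        seed = as.integer(seed)),
                   class = "scenario_config")
  tr <- scenario_truth(cfg)
  if (tr$var_e <= 0)
    stop("infeasible scenario: residual variance 1 - (m^2+f^2+mf) - beta_u^2 <= 0")
  cfg
}

#' True parameter values implied by a scenario
#'
#' Converts the variance-fraction scenario labels to working path
#' coefficients (signed square roots) and the residual variances that make
#' both phenotypes unit-variance asymptotically.
#'
#' @param config A [scenario_config].
#' @return List with elements \code{m}, \code{f}, \code{rho} (=
#'   \code{beta_u^2}), \code{var_e}, \code{var_eo}.
#' @export
scenario_truth <- function(config) {
  m <- sign(config$v_maternal) * sqrt(abs(config$v_maternal))
  f <- sign(config$v_fetal) * sqrt(abs(config$v_fetal))
  ve <- 1 - (m^2 + f^2 + m * f) - config$beta_u^2
  list(m = m, f = f, rho = config$beta_u^2, var_e = ve, var_eo = ve)
}

#' Simulate genotypes for mother-offspring dyads
#'
#' Draws grand-maternal genotypes from Hardy-Weinberg equilibrium at a single
#' biallelic locus and propagates them through two generations of autosomal
#' Mendelian transmission: the observed individual receives one allele
#' transmitted uniformly at random from their mother and one from an
#' independent Hardy-Weinberg father, and likewise for their offspring.
#' Fathers are drawn and discarded.  All three dosages are standardized to
#' mean 0, variance 1 (centered at \code{2p}, scaled by \code{sqrt(2p(1-p))}).
#'
#' @param n Number of dyads.
#' @param p Effect-allele frequency.
#' @param seed Optional integer seed; \code{NULL} uses the current RNG
#'   stream.
#' @return List of numeric vectors \code{g_g} (grand-maternal, i.e. the
#'   genotype of the individual's mother), \code{snp} (the individual) and
#'   \code{g_o} (their offspring).
#' @export
simulate_genotypes <- function(n, p, seed = NULL) {
  stopifnot(p > 0, p < 1)
  if (!is.null(seed)) set.seed(seed)
  g_g <- stats::rbinom(n, 1L, p) + stats::rbinom(n, 1L, p)
  snp <- stats::rbinom(n, 1L, g_g / 2) + stats::rbinom(n, 1L, p)
  g_o <- stats::rbinom(n, 1L, snp / 2) + stats::rbinom(n, 1L, p)
  s <- sqrt(2 * p * (1 - p))
  list(g_g = (g_g - 2 * p) / s, snp = (snp - 2 * p) / s,
       g_o = (g_o - 2 * p) / s)
}

#' Simulate phenotypes for mother-offspring dyads
#'
#' Generates the individual's own phenotype and their offspring's phenotype
#' from standardized genotypes under the additive model
#' \deqn{BW = m G_G + f SNP + \beta_U U + \epsilon,\quad
#'       BW_O = m SNP + f G_O + \beta_U U + \epsilon_O,}
#' with \eqn{U} a standard-normal confounder shared within family and
#' residual variances chosen so both phenotypes have unit variance
#' asymptotically.
#'
#' @param genotypes List from [simulate_genotypes].
#' @param config A [scenario_config] (only the effect-size and confounder
#'   fields are used here).
#' @param keep_truth Retain the hidden truth columns (\code{g_g}, \code{g_o},
#'   \code{u}) for oracle checks?
#' @return A family dataset: data frame with columns \code{family_id},
#'   \code{bw}, \code{bw_offspring}, \code{dosage}, \code{pattern} (and the
#'   truth columns if requested).
#' @export
simulate_phenotypes <- function(genotypes, config, keep_truth = TRUE) {
  tr <- scenario_truth(config)
  n <- length(genotypes$snp)
  u <- stats::rnorm(n)
  sde <- sqrt(tr$var_e)
  bw  <- tr$m * genotypes$g_g + tr$f * genotypes$snp +
    config$beta_u * u + stats::rnorm(n, 0, sde)
  bwo <- tr$m * genotypes$snp + tr$f * genotypes$g_o +
    config$beta_u * u + stats::rnorm(n, 0, sde)
  d <- data.frame(family_id = seq_len(n), bw = bw, bw_offspring = bwo,
                  dosage = genotypes$snp, pattern = "both",
                  stringsAsFactors = FALSE)
  if (keep_truth) {
    d$g_g <- genotypes$g_g; d$g_o <- genotypes$g_o; d$u <- u
  }
  d
}

#' Add classical measurement error
#'
#' Degrades a measurement with additive independent Gaussian noise
#' calibrated so that the regression of degraded on true values has a target
#' R-squared: the noise variance is \code{var(values) * (1 - r2) / r2}.
#'
#' @param values Numeric vector (NAs passed through).
#' @param r2 Target R-squared in (0, 1]; 1 returns the input unchanged.
#' @param seed Optional integer seed.
#' @return Degraded numeric vector.
#' @export
add_classical_error <- function(values, r2, seed = NULL) {
  if (!is.numeric(r2) || length(r2) != 1L || r2 <= 0 || r2 > 1)
    stop("r2 must be a scalar in (0, 1]")
  if (r2 == 1) return(values)
  if (!is.null(seed)) set.seed(seed)
  delta <- stats::var(values, na.rm = TRUE) * (1 - r2) / r2
  values + stats::rnorm(length(values), 0, sqrt(delta))
}

#' Round a phenotype to the nearest unit
#'
#' Emulates coarse self-report (e.g. birthweight recalled to the nearest
#' pound) by rounding each value to the nearest integer on its current
#' scale; on a unit-variance scale this leaves roughly six occupied
#' categories.
#'
#' @param values Numeric vector.
#' @return Rounded vector (idempotent).
#' @export
discretize_offspring <- function(values) round(values)

#' Apply a missingness design
#'
#' Masks phenotypes completely at random according to one of the study
#' designs: \code{"i"} half the families keep both phenotypes and half keep
#' only their own; \code{"ii"} half keep both and half keep only their
#' offspring's; \code{"iii"} half keep both, a quarter each keep one;
#' \code{"iv"} half keep only their own and half only their offspring's, so
#' no family retains both.  Assignment is by index blocks after a random
#' shuffle drawn from the current RNG stream.
#'
#' @param data A family dataset (all patterns \code{"both"}).
#' @param design \code{"complete"} or one of \code{"i"}..\code{"iv"}.
#' @param seed Optional integer seed for the shuffle.
#' @return The dataset with phenotypes masked and pattern labels updated.
#' @export
apply_missingness <- function(data, design = c("complete", "i", "ii", "iii", "iv"),
                              seed = NULL) {
  design <- match.arg(design)
  if (design == "complete") return(data)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  half <- floor(n / 2); quarter <- floor(n / 4)
  ord <- sample.int(n)
  own_only <- offspring_only <- integer(0)
  if (design == "i") {
    own_only <- ord[seq_len(half)]
  } else if (design == "ii") {
    offspring_only <- ord[seq_len(half)]
  } else if (design == "iii") {
    own_only <- ord[seq_len(quarter)]
    offspring_only <- ord[quarter + seq_len(quarter)]
  } else { # iv: nobody keeps both
    own_only <- ord[seq_len(half)]
    offspring_only <- ord[(half + 1):n]
  }
  data$bw_offspring[own_only] <- NA_real_
  data$bw[offspring_only] <- NA_real_
  data$pattern[own_only] <- "own_only"
  data$pattern[offspring_only] <- "offspring_only"
  data
}

#' Simulate one complete replicate of a scenario
#'
#' Runs the full generating pipeline for one replicate: Mendelian genotypes,
#' phenotypes with shared confounding, classical measurement error,
#' optional unit rounding of the offspring phenotype, and the missingness
#' design.  All randomness flows from a single seed, so identical seeds
#' reproduce identical datasets.
#'
#' @param config A [scenario_config].
#' @param replicate Replicate index; the RNG is seeded with
#'   \code{config$seed + replicate}.
#' @param keep_truth Retain hidden truth columns?
#' @return A family dataset.
#' @examples
#' d <- simulate_dyads(scenario_config(n_families = 500, seed = 7))
#' table(d$pattern)
#' @export
simulate_dyads <- function(config, replicate = 0L, keep_truth = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + as.integer(replicate))
  g <- simulate_genotypes(config$n_families, config$p)
  d <- simulate_phenotypes(g, config, keep_truth = keep_truth)
  d$bw <- add_classical_error(d$bw, config$r2_own)
  d$bw_offspring <- add_classical_error(d$bw_offspring, config$r2_offspring)
  if (config$discretize_offspring)
    d$bw_offspring <- discretize_offspring(d$bw_offspring)
  apply_missingness(d, config$missing_design)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "Scenario: n=%d, p=%.2f, V_fetal=%.4g, V_maternal=%.4g, beta_u=%.2f\n",
    x$n_families, x$p, x$v_fetal, x$v_maternal, x$beta_u))
  cat(sprintf("  R2 own=%.2f, R2 offspring=%.2f, discretize=%s, design=%s\n",
              x$r2_own, x$r2_offspring, x$discretize_offspring,
              x$missing_design))
  cat(sprintf("  replicates=%d, seed=%d\n", x$n_replicates, x$seed))
  invisible(x)
}

# Validate/coerce a family dataset; infer pattern labels when absent.
as_family_dataset <- function(data) {
  data <- as.data.frame(data)
  need <- c("bw", "bw_offspring", "dosage")
  if (!all(need %in% names(data)))
    stop("family dataset requires columns bw, bw_offspring, dosage")
  if (anyNA(data$dosage)) stop("dosage must never be missing")
  pat <- ifelse(!is.na(data$bw) & !is.na(data$bw_offspring), "both",
                ifelse(!is.na(data$bw), "own_only", "offspring_only"))
  if (any(is.na(data$bw) & is.na(data$bw_offspring)))
    stop("records with both phenotypes missing are not allowed")
  if (is.null(data$pattern)) data$pattern <- pat
  else if (!identical(as.character(data$pattern), pat))
    stop("pattern labels inconsistent with phenotype missingness")
  data
}
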