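#' Unconditional linear-model comparators
#'
#' Fits the two simple regressions typically used in genetic studies of a
#' perinatal phenotype: the individual's own phenotype on their dosage (the
#' usual "fetal effect" estimate) and the offspring's phenotype on the same
#' dosage (the usual "maternal effect" estimate), each on its available-case
#' subset.  Because the two regressions ignore the correlated other path,
#' each slope is biased by half the other true effect: the expected
#' fetal-comparator slope is \eqn{f + m/2} and the maternal-comparator slope
#' \eqn{m + f/2}.
#'
#' @param data A family dataset.
#' @return Data frame with one row per comparator (\code{fetal},
#'   \code{maternal}): \code{beta}, \code{se}, \code{p}, \code{n}.
#' @export
linear_model_effects <- function(data) {
  data <- as_family_dataset(data)
  one <- function(y) {
    keep <- !is.na(y)
    if (sum(keep) < 3) stop("need at least 3 complete pairs per regression")
    x <- data$dosage[keep]
    if (stats::var(x) == 0) stop("constant genotype: regression undefined")
    fit <- stats::lm(y[keep] ~ x)
    s <- summary(fit)$coefficients["x", ]
    c(beta = unname(s["Estimate"]), se = unname(s["Std. Error"]),
      p = unname(s["Pr(>|t|)"]), n = sum(keep))
  }
  out <- rbind(fetal = one(data$bw), maternal = one(data$bw_offspring))
  data.frame(effect = rownames(out), out, row.names = NULL)
}

#' Heterogeneity between two effect estimates
#'
#' Fixed-effect (inverse-variance) heterogeneity of two estimates of the
#' same quantity, e.g. an SEM estimate versus a conditional-regression
#' estimate of the same maternal effect: Cochran's
#' \eqn{Q = \sum w_i (b_i - \bar b)^2} with \eqn{w_i = 1/se_i^2},
#' \eqn{I^2 = \max(0, (Q - 1)/Q) \times 100\%}, and a chi-square p-value on
#' one degree of freedom.
#'
#' @param b1,se1 First estimate and its standard error.
#' @param b2,se2 Second estimate and its standard error.
#' @return List with \code{Q}, \code{I2} (percent), \code{p}.
#' @examples
#' heterogeneity_i2(0.05, 0.02, -0.01, 0.02)
#' @export
heterogeneity_i2 <- function(b1, se1, b2, se2) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive")
  w <- c(1 / se1^2, 1 / se2^2)
  b <- c(b1, b2)
  bbar <- sum(w * b) / sum(w)
  q <- sum(w * (b - bbar)^2)
  list(Q = q, I2 = max(0, (q - 1) / q) * 100,
       p = stats::pchisq(q, 1, lower.tail = FALSE))
}

#' Build a group summary from unconditional GWAS summary statistics
#'
#' Reconstructs the two-variable sufficient statistics of a cohort from the
#' summary statistics of an unconditional regression (effect-allele
#' frequency, slope, phenotype variance, sample size), so that cohorts
#' unable to share raw data can be fitted jointly with other groups sharing
#' the same path parameters.  The dosage variance is the Hardy-Weinberg
#' value \eqn{2\,eaf(1-eaf)} and the phenotype-dosage covariance is
#' \code{beta} times that variance.  A \code{fetal_arm} cohort contributes
#' an own-phenotype-only group, a \code{maternal_arm} cohort an
#' offspring-phenotype-only group.
#'
#' @param eaf Effect-allele frequency, in (0, 1).
#' @param beta Regression slope of the (standardized) phenotype on dosage.
#' @param pheno_var Variance of the phenotype.
#' @param n Cohort sample size.
#' @param which \code{"fetal_arm"} (phenotype is the genotyped individual's
#'   own) or \code{"maternal_arm"} (phenotype is their offspring's).
#' @return A \code{"group_summary"}.
#' @examples
#' summary_stats_to_group(eaf = 0.5, beta = 0.02, pheno_var = 1, n = 10000,
#'                        which = "fetal_arm")
#' @export
summary_stats_to_group <- function(eaf, beta, pheno_var, n,
                                   which = c("fetal_arm", "maternal_arm")) {
  which <- match.arg(which)
  if (eaf <= 0 || eaf >= 1) stop("eaf must be in (0, 1)")
  if (pheno_var <= 0) stop("pheno_var must be positive")
  if (n < 3) stop("n must be at least 3")
  v_snp <- 2 * eaf * (1 - eaf)
  cv <- beta * v_snp
  r <- cv / sqrt(pheno_var * v_snp)
  if (abs(r) >= 1)
    stop("implied phenotype-dosage correlation is not below 1 in magnitude")
  pattern <- if (which == "fetal_arm") "own_only" else "offspring_only"
  cov <- matrix(c(pheno_var, cv, cv, v_snp), 2, 2)
  group_summary(pattern, n, mean = c(0, 2 * eaf), cov = cov)
}
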