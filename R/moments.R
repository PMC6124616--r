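#' @rdname implied_moments
#' @export
OBSERVATION_PATTERNS <- c("both", "own_only", "offspring_only")

#' Observed variables for an observation pattern
#'
#' The model distinguishes three observation patterns: individuals with both
#' phenotypes (\code{"both"}), individuals reporting only their own phenotype
#' (\code{"own_only"}) and mothers reporting only their offspring's phenotype
#' (\code{"offspring_only"}).  The genotype is always observed.
#'
#' @param pattern One of \code{"both"}, \code{"own_only"},
#'   \code{"offspring_only"}.
#' @return Character vector of observed variable names, in model order.
#' @export
pattern_vars <- function(pattern) {
  switch(match.arg(pattern, OBSERVATION_PATTERNS),
         both           = c("bw", "bw_offspring", "snp"),
         own_only       = c("bw", "snp"),
         offspring_only = c("bw_offspring", "snp"))
}

# Model-implied 3x3 covariance and mean for (bw, bw_offspring, snp), by path
# tracing through the latent grand-maternal and offspring genotypes with
# transmission paths fixed at 1/2:
#   Var(BW)        = phi (m^2 + f^2 + m f) + var_e
#   Var(BW_O)      = phi (m^2 + f^2 + m f) + var_eo
#   Var(SNP)       = phi
#   Cov(BW, SNP)   = phi (f + m/2)
#   Cov(BW_O, SNP) = phi (m + f/2)
#   Cov(BW, BW_O)  = phi ((m^2 + f^2)/2 + (5/4) m f) + rho
implied_cov_full <- function(p) {
  m <- p$m; f <- p$f; phi <- p$phi
  rho <- if (is.na(p$rho)) 0 else p$rho
  gvar <- phi * (m^2 + f^2 + m * f)
  v_bw  <- gvar + p$var_e
  v_bwo <- gvar + p$var_eo
  c_bw_snp  <- phi * (f + m / 2)
  c_bwo_snp <- phi * (m + f / 2)
  c_bw_bwo  <- phi * ((m^2 + f^2) / 2 + 1.25 * m * f) + rho
  matrix(c(v_bw,     c_bw_bwo, c_bw_snp,
           c_bw_bwo, v_bwo,    c_bwo_snp,
           c_bw_snp, c_bwo_snp, phi),
         3, 3, dimnames = list(VAR_NAMES, VAR_NAMES))
}

VAR_NAMES <- c("bw", "bw_offspring", "snp")

implied_mean_full <- function(p) {
  c(bw = p$mu_bw, bw_offspring = p$mu_bwo, snp = p$mu_snp)
}

#' Model-implied moments for an observation pattern
#'
#' Computes the mean vector and covariance matrix of the observed variables
#' implied by the path model, for individuals with a given observation
#' pattern.  Reduced patterns return the corresponding submatrix and
#' subvector of the full three-variable moments.
#'
#' @param params A [path_model_params] object.
#' @param pattern Observation pattern (see [pattern_vars]).
#' @return An object of class \code{"implied_moments"}: a list with elements
#'   \code{mean} (named vector) and \code{cov} (named square matrix).
#' @examples
#' implied_moments(path_model_params(m = 0, f = 0.02))$cov
#' @export
implied_moments <- function(params, pattern = "both") {
  stopifnot(inherits(params, "path_model_params"))
  validate_params(params)
  vars <- pattern_vars(pattern)
  sigma <- implied_cov_full(params)[vars, vars]
  if (inherits(try(chol(sigma), silent = TRUE), "try-error"))
    invalid_params("implied covariance matrix is not positive definite")
  structure(list(mean = implied_mean_full(params)[vars], cov = sigma,
                 pattern = pattern),
            class = "implied_moments")
}

#' @export
print.implied_moments <- function(x, digits = 4, ...) {
  cat("Implied moments (pattern:", x$pattern, ")\nmean:\n")
  print(round(x$mean, digits))
  cat("cov:\n")
  print(round(x$cov, digits))
  invisible(x)
}
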