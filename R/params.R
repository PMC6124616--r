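#' Parameters of the maternal/fetal path model
#'
#' Container for the free parameters of the mother-offspring structural
#' equation model with latent relative genotypes.  The observed variables are
#' the individual's own phenotype (\code{bw}), their offspring's phenotype
#' (\code{bw_offspring}) and the individual's allele dosage (\code{snp}); the
#' grand-maternal and offspring genotypes are latent, connected to the
#' observed dosage by Mendelian transmission paths fixed at 1/2.
#'
#' @param m Maternal path coefficient: effect of the mother's genotype on her
#'   offspring's phenotype (phenotype SD units per genotype SD when dosages
#'   are standardized).
#' @param f Fetal path coefficient: effect of an individual's own genotype on
#'   their own phenotype (same units).
#' @param phi Variance of a genotype variable (\eqn{\Phi}); approximately 1
#'   for standardized dosages, \eqn{2p(1-p)} for raw biallelic dosages.
#' @param var_e Residual variance of the individual's own phenotype.
#' @param var_eo Residual variance of the offspring phenotype.
#' @param rho Covariance between the two phenotype residuals, absorbing
#'   shared genetic and environmental similarity between mother and
#'   offspring.  May be \code{NA} when structurally not estimable (no
#'   individual observed on both phenotypes).
#' @param mu_bw,mu_bwo,mu_snp Means of the three observed variables.
#' @param validate If \code{TRUE}, check the variance-parameter invariants.
#'
#' @return An object of class \code{"path_model_params"} (a named list).
#' @examples
#' path_model_params(m = -0.014, f = 0.02, rho = 0.25)
#' @export
path_model_params <- function(m = 0, f = 0, phi = 1, var_e = 1, var_eo = 1,
                              rho = 0, mu_bw = 0, mu_bwo = 0, mu_snp = 0,
                              validate = TRUE) {
  p <- structure(list(m = m, f = f, phi = phi, var_e = var_e,
                      var_eo = var_eo, rho = rho,
                      mu_bw = mu_bw, mu_bwo = mu_bwo, mu_snp = mu_snp),
                 class = "path_model_params")
  if (validate) validate_params(p)
  p
}

validate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L
  if (!all(vapply(p, num1, logical(1))))
    stop("all path model parameters must be numeric scalars", call. = FALSE)
  if (!is.na(p$phi) && p$phi <= 0) invalid_params("phi must be > 0")
  if (!is.na(p$var_e) && p$var_e <= 0) invalid_params("var_e must be > 0")
  if (!is.na(p$var_eo) && p$var_eo <= 0) invalid_params("var_eo must be > 0")
  if (!is.na(p$rho) && !is.na(p$var_e) && !is.na(p$var_eo) &&
      abs(p$rho) > sqrt(p$var_e * p$var_eo))
    invalid_params("|rho| must not exceed sqrt(var_e * var_eo)")
  invisible(p)
}

# Signal an invalid-parameter condition (subclass so optimizers can catch it
# without masking programming errors).
invalid_params <- function(msg) {
  stop(structure(class = c("dyadsem_invalid_params", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' @export
print.path_model_params <- function(x, digits = 4, ...) {
  cat("Path model parameters:\n")
  print(round(unlist(x), digits))
  invisible(x)
}
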