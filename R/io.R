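#' Read a family table
#'
#' Reads a tab-delimited family table with header columns \code{family_id},
#' \code{bw}, \code{bw_offspring}, \code{dosage} (empty cells are missing).
#' Observation-pattern labels are inferred from which phenotypes are
#' present; rows missing both phenotypes or missing the dosage are rejected.
#'
#' @param path Path to a TSV file.
#' @return A family dataset (data frame with a \code{pattern} column).
#' @export
load_family_table <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("family_id", "bw", "bw_offspring", "dosage")
  if (!all(need %in% names(d)))
    stop("malformed header: need columns ", paste(need, collapse = ", "))
  d$pattern <- NULL  # always re-infer from missingness
  as_family_dataset(d)
}

#' Write a family table
#'
#' @param data A family dataset.
#' @param path Output TSV path.
#' @param truth Keep hidden truth columns (\code{g_g}, \code{g_o},
#'   \code{u}) if present?
#' @return \code{path}, invisibly.
#' @export
write_family_table <- function(data, path, truth = FALSE) {
  data <- as_family_dataset(data)
  if (!truth) data <- data[, setdiff(names(data), c("g_g", "g_o", "u"))]
  utils::write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results table as TSV
#'
#' @param results A data frame (e.g. from [format_results_table]).
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read covariance summaries
#'
#' Serializes a list of group summaries to a small YAML or JSON document
#' (selected by file extension) holding, per group, the pattern, sample
#' size, mean vector and lower triangle of the covariance matrix.
#'
#' @param groups List of group summaries.
#' @param path Output path ending in \code{.yaml}, \code{.yml} or
#'   \code{.json}.
#' @return \code{path} (writer) or the list of group summaries (reader).
#' @export
write_group_summaries <- function(groups, path) {
  if (inherits(groups, "group_summary")) groups <- list(groups)
  doc <- lapply(groups, function(g) {
    k <- length(g$mean)
    list(pattern = g$pattern, n = g$n, mean = as.numeric(g$mean),
         cov_lower = as.numeric(g$cov[lower.tri(g$cov, diag = TRUE)]),
         k = k)
  })
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(doc, path, precision = 15)
  else if (grepl("\\.json$", path))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  else stop("unsupported extension (use .yaml/.yml/.json): ", path)
  invisible(path)
}

#' @rdname write_group_summaries
#' @export
read_group_summaries <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported extension (use .yaml/.yml/.json): ", path)
  if (is.data.frame(doc)) doc <- split(doc, seq_len(nrow(doc)))
  lapply(doc, function(g) {
    if (is.data.frame(g)) g <- as.list(g)
    k <- as.integer(g$k)
    cv <- matrix(0, k, k)
    cv[lower.tri(cv, diag = TRUE)] <- unlist(g$cov_lower)
    cv <- cv + t(cv) - diag(diag(cv))
    group_summary(as.character(g$pattern), as.numeric(g$n),
                  unlist(g$mean), cv)
  })
}

#' Clean self-reported birthweight records
#'
#' Applies the standard plausibility rules for self-reported birthweight in
#' a population biobank: multiple births are excluded; when an individual
#' reported a weight at both a baseline and a follow-up visit, reports
#' differing by more than 0.5 kg are discarded and otherwise the baseline
#' value is kept; and weights below 2.5 kg or above 4.5 kg are discarded as
#' implausible for live term births.  The same rules are applied to the
#' individual's own reports and to their reports of their offspring's
#' birthweight.  Every exclusion is counted by the rule that fired.
#'
#' @param records Data frame with columns \code{id},
#'   \code{own_bw_baseline}, \code{own_bw_followup},
#'   \code{offspring_bw_baseline}, \code{offspring_bw_followup} (follow-up
#'   columns optional), \code{multiple_birth} (logical), \code{sex}
#'   (optional).  Weights in kg; \code{NA} where not reported.
#' @return List with \code{records} (columns \code{id}, \code{bw},
#'   \code{bw_offspring}, \code{sex}), \code{exclusions} (named counts:
#'   record-level \code{malformed}, \code{multiple_birth},
#'   \code{no_valid_phenotype}; measure-level \code{own_discordant},
#'   \code{own_out_of_range}, \code{offspring_discordant},
#'   \code{offspring_out_of_range}), and \code{n_in}, \code{n_kept}.
#' @export
clean_birthweight_reports <- function(records) {
  records <- as.data.frame(records)
  if (!"id" %in% names(records)) stop("records require an id column")
  for (col in c("own_bw_followup", "offspring_bw_baseline",
                "offspring_bw_followup"))
    if (is.null(records[[col]])) records[[col]] <- NA_real_
  if (is.null(records$own_bw_baseline)) records$own_bw_baseline <- NA_real_
  if (is.null(records$multiple_birth)) records$multiple_birth <- FALSE
  if (is.null(records$sex)) records$sex <- NA
  n_in <- nrow(records)
  excl <- c(malformed = 0, multiple_birth = 0, no_valid_phenotype = 0,
            own_discordant = 0, own_out_of_range = 0,
            offspring_discordant = 0, offspring_out_of_range = 0)

  wcols <- c("own_bw_baseline", "own_bw_followup",
             "offspring_bw_baseline", "offspring_bw_followup")
  bad <- rep(FALSE, n_in)
  for (col in wcols) {
    v <- suppressWarnings(as.numeric(records[[col]]))
    bad <- bad | (!is.na(records[[col]]) & is.na(v)) | (!is.na(v) & v <= 0)
    records[[col]] <- v
  }
  excl["malformed"] <- sum(bad)
  records <- records[!bad, , drop = FALSE]

  mult <- isTRUE_vec(records$multiple_birth)
  excl["multiple_birth"] <- sum(mult)
  records <- records[!mult, , drop = FALSE]

  resolve <- function(base, follow, label) {
    discordant <- !is.na(base) & !is.na(follow) & abs(base - follow) > 0.5
    excl[paste0(label, "_discordant")] <<- sum(discordant)
    value <- ifelse(is.na(base), follow, base)  # baseline preferred
    value[discordant] <- NA_real_
    out <- !is.na(value) & (value < 2.5 | value > 4.5)
    excl[paste0(label, "_out_of_range")] <<- sum(out)
    value[out] <- NA_real_
    value
  }
  bw <- resolve(records$own_bw_baseline, records$own_bw_followup, "own")
  bwo <- resolve(records$offspring_bw_baseline, records$offspring_bw_followup,
                 "offspring")

  empty <- is.na(bw) & is.na(bwo)
  excl["no_valid_phenotype"] <- sum(empty)
  out <- data.frame(id = records$id[!empty], bw = bw[!empty],
                    bw_offspring = bwo[!empty], sex = records$sex[!empty],
                    stringsAsFactors = FALSE)
  list(records = out, exclusions = excl, n_in = n_in, n_kept = nrow(out))
}

isTRUE_vec <- function(x) !is.na(x) & (x == TRUE | x == 1 | x == "TRUE")

#' Covariate-adjusted z-scores
#'
#' Residualizes a phenotype on supplied covariates (e.g. sex for an
#' individual's own birthweight) via ordinary least squares, then centers
#' and scales the residuals to mean 0, SD 1.  Missing phenotype values stay
#' missing; rows with missing covariates are dropped from the fit but their
#' residuals are still formed when possible.
#'
#' @param values Numeric phenotype vector.
#' @param covariates Optional data frame (or vector) of covariates.
#' @return Numeric vector of z-scores, same length as \code{values}.
#' @export
standardize_phenotypes <- function(values, covariates = NULL) {
  if (sum(!is.na(values)) < 2) stop("need at least 2 non-missing values")
  res <- values
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(.y = values, covariates)
    fit <- stats::lm(.y ~ ., data = df, na.action = stats::na.exclude)
    res <- stats::residuals(fit)
  }
  s <- stats::sd(res, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("zero variance after adjustment")
  as.numeric(scale(res))
}
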