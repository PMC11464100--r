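# CSV round-tripping for cohort, registry and mean-risk-factor tables.
# Documented headers:
#   cohort:   cohort_id, sex, entry_age, exit_age, event, smoking, sbp,
#             total_chol, hdl_chol, diabetes
#   registry: region, sex, age_lo, age_hi, cvd_mortality_rate,
#             noncvd_mortality_rate, multiplier_total_to_fatal,
#             prior_cvd_correction
#   means:    region, sex, age_lo, age_hi, sbp, total_chol, hdl_chol,
#             smoking, diabetes
#   profiles: sex, age, smoking, sbp, total_chol, hdl_chol, diabetes

#' Read a cohort CSV
#' @param path CSV file with the documented cohort header.
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cohort_id", "sex", "entry_age", "exit_age", "event", "smoking",
           "sbp", "total_chol", "hdl_chol", "diabetes")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("cohort file '", path, "' is missing columns: ",
         paste(miss, collapse = ", "))
  bad <- setdiff(unique(d$event), c(.endpoints, "censored"))
  if (length(bad))
    stop("cohort file '", path, "' has unknown event codes: ",
         paste(bad, collapse = ", "))
  d
}

#' Read a registry CSV
#' @param path CSV file with the documented registry header.
#' @export
read_registry <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  tryCatch(.check_registry(d), error = function(e)
    stop("registry file '", path, "': ", conditionMessage(e)))
  d
}

#' Read a mean-risk-factor CSV
#' @param path CSV file with the documented means header.
#' @export
read_means <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  tryCatch(.check_means(d), error = function(e)
    stop("means file '", path, "': ", conditionMessage(e)))
  d
}

#' Read individual risk-factor profiles from CSV
#' @param path CSV with columns \code{sex, age, smoking, sbp, total_chol,
#'   hdl_chol} and optionally \code{diabetes}.
#' @return List of \code{\link{risk_profile}}s (input order preserved).
#' @export
read_profiles <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sex", "age", "smoking", "sbp", "total_chol", "hdl_chol")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("profile file '", path, "' is missing columns: ",
         paste(miss, collapse = ", "))
  if (is.null(d$diabetes)) d$diabetes <- 0
  lapply(seq_len(nrow(d)), function(i)
    risk_profile(d$sex[i], d$age[i], d$smoking[i], d$sbp[i],
                 d$total_chol[i], d$hdl_chol[i], d$diabetes[i]))
}
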