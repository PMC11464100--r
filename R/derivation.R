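# Derivation of the cause-specific models: Cox proportional hazards with age
# as the time axis (left truncation), stratified by cohort, with
# predictor-by-entry-age interactions, fitted by survival::coxph (Efron tie
# handling, appropriate for event times discretised to whole years of age).

#' Fit one sex-specific cause-specific endpoint model
#'
#' Cause-specific Cox fit on cohort records: the competing event is treated
#' as censoring at exit, risk sets are defined by attained age with delayed
#' entry (\code{Surv(entry_age, exit_age, status)}), the baseline is
#' stratified by cohort, and every predictor except age gets an interaction
#' with centered entry age \code{(entry_age - 60)/5}. Covariates enter on
#' the model's per-unit scales (SBP per 20 mmHg, TC per 1 mmol/L, HDL per
#' 0.5 mmol/L, binaries as-is).
#'
#' @param records Cohort data frame with columns \code{cohort_id, sex,
#'   entry_age, exit_age, event, smoking, sbp, total_chol, hdl_chol,
#'   diabetes}; \code{event} one of \code{cvd_event, noncvd_death,
#'   censored}.
#' @param endpoint Endpoint to fit; the other event type must also be
#'   present in the data (it defines the competing risk).
#' @param sex Sex stratum to fit.
#' @param ties Tie-handling method passed to \code{survival::coxph};
#'   Efron (default) is the appropriate choice for the many ties produced
#'   by yearly age discretisation.
#' @return Object of class \code{endpoint_fit}: \code{beta_main} and
#'   \code{gamma_age} (log HRs, named as in \code{\link{endpoint_model}}),
#'   standard errors, event count and the underlying \code{coxph} fit.
#' @export
fit_endpoint_models <- function(records, endpoint, sex,
                                ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  endpoint <- match.arg(endpoint, .endpoints)
  sex <- match.arg(sex, .sexes)
  req <- c("cohort_id", "sex", "entry_age", "exit_age", "event", "smoking",
           "sbp", "total_chol", "hdl_chol", "diabetes")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("cohort records are missing columns: ", paste(miss, collapse = ", "))
  if (any(records$exit_age <= records$entry_age))
    stop("exit_age must exceed entry_age for every record")
  if (!all(.endpoints %in% records$event))
    stop("both event types must be present in the derivation data")
  d <- records[records$sex == sex, , drop = FALSE]
  if (!nrow(d)) stop("no records for sex '", sex, "'")
  z <- (d$entry_age - 60) / 5
  df <- data.frame(
    entry_age = d$entry_age, exit_age = d$exit_age,
    status = as.integer(d$event == endpoint),
    cohort_id = d$cohort_id,
    age = z,
    smoking = d$smoking,
    sbp = (d$sbp - 120) / 20,
    total_chol = d$total_chol - 6,
    hdl_chol = (d$hdl_chol - 1.3) / 0.5,
    diabetes = d$diabetes)
  covs <- c("smoking", "sbp", "total_chol", "hdl_chol", "diabetes")
  for (v in covs) df[[paste0(v, ".x.age")]] <- df[[v]] * z
  terms <- c("age", covs, paste0(covs, ".x.age"))
  n_events <- sum(df$status)
  if (n_events < 2L * length(terms))
    stop("too few events (", n_events, ") for ", length(terms),
         " parameters; need at least 2 events per parameter")
  fml <- stats::as.formula(paste(
    "survival::Surv(entry_age, exit_age, status) ~",
    paste(terms, collapse = " + "), "+ survival::strata(cohort_id)"))
  fit <- survival::coxph(fml, data = df, ties = ties)
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)))
    stop("Cox fit did not converge (non-finite coefficients; possible ",
         "separation). Gradient norm: ",
         format(sqrt(sum(survival::coxph.detail(fit)$score^2))))
  se <- sqrt(diag(stats::vcov(fit)))
  main <- beta[c("age", covs)]
  inter <- beta[paste0(covs, ".x.age")]
  names(inter) <- covs
  structure(
    list(endpoint = endpoint, sex = sex,
         beta_main = main, gamma_age = inter,
         se_main = stats::setNames(se[c("age", covs)], c("age", covs)),
         se_gamma = stats::setNames(se[paste0(covs, ".x.age")], covs),
         n = nrow(df), n_events = n_events, fit = fit),
    class = "endpoint_fit")
}

#' @export
print.endpoint_fit <- function(x, ...) {
  cat(sprintf("<endpoint_fit> %s, %s: %d records, %d events\n",
              x$endpoint, x$sex, x$n, x$n_events))
  ci <- function(b, s) sprintf("%.2f (%.2f, %.2f)", exp(b),
                               exp(b - 1.96 * s), exp(b + 1.96 * s))
  tab <- data.frame(
    `HR (95% CI)` = ci(x$beta_main, x$se_main),
    `age interaction` = c("", ci(x$gamma_age, x$se_gamma)),
    row.names = names(x$beta_main), check.names = FALSE)
  print(tab)
  invisible(x)
}

#' Combine four fitted models and a registry baseline into a bundle
#'
#' The cohort-stratified baselines of the Cox fits are discarded; the
#' bundle's baseline survival is instead derived from low-risk-region
#' registry incidence (\code{\link{set_baseline_from_incidence}}), which
#' yields smooth baselines across the whole 35-100 age range even when no
#' single cohort covers it.
#'
#' @param fits List of four \code{endpoint_fit}s covering both endpoints
#'   and sexes.
#' @param registry,means Low-risk-region registry and mean-risk-factor
#'   tables supplying the baseline.
#' @param meta Metadata list stored in the bundle.
#' @return A \code{\link{model_bundle}} (un-recalibrated; pass it to
#'   \code{\link{recalibrate_bundle}} for regional scales).
#' @export
export_bundle <- function(fits, registry, means, meta = list()) {
  keys <- vapply(fits, function(f) {
    stopifnot(inherits(f, "endpoint_fit"))
    paste(f$endpoint, f$sex, sep = ".")
  }, character(1))
  need <- as.vector(outer(.endpoints, .sexes, paste, sep = "."))
  missing <- setdiff(need, keys)
  if (length(missing))
    stop("fits are missing endpoint/sex combinations: ",
         paste(missing, collapse = ", "))
  names(fits) <- keys
  flat <- rep(0.99, 66)
  models <- lapply(fits[need], function(f)
    endpoint_model(f$endpoint, f$sex, f$beta_main, f$gamma_age, flat))
  b <- model_bundle(models, meta = meta)
  set_baseline_from_incidence(b, registry, means)
}
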