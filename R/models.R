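# Endpoint models: log hazard ratios per stated unit, age-interaction log HRs,
# centering constants and per-age baseline 1-year survival for one endpoint
# (cvd_event or noncvd_death) and one sex.

.predictors <- c("age", "smoking", "sbp", "total_chol", "hdl_chol", "diabetes")

# per-unit scaling applied before the coefficients: age per 5 y, SBP per
# 20 mmHg, TC per 1 mmol/L, HDL per 0.5 mmol/L, binaries as-is
.centering <- c(age = 60, smoking = 0, sbp = 120, total_chol = 6,
                hdl_chol = 1.3, diabetes = 0)
.unit      <- c(age = 5, smoking = 1, sbp = 20, total_chol = 1,
                hdl_chol = 0.5, diabetes = 1)

.endpoints <- c("cvd_event", "noncvd_death")
.sexes <- c("male", "female")
.regions <- c("low", "moderate", "high", "very_high")

#' Construct an endpoint model
#'
#' An endpoint model holds the log hazard ratios (per stated unit) of one
#' cause-specific proportional-hazards model, the log age-interaction hazard
#' ratios (per 5 years of centered age), the centering constants, and the
#' baseline 1-year event-free survival \eqn{S_0(a)} at every integer attained
#' age 35-100 for the reference individual (all predictors at their centering
#' values: age 60, SBP 120 mmHg, total cholesterol 6 mmol/L, HDL 1.3 mmol/L,
#' non-smoking, non-diabetic).
#'
#' @param endpoint "cvd_event" or "noncvd_death".
#' @param sex "male" or "female".
#' @param beta_main Named numeric vector of log HRs per unit; names among
#'   \code{age, smoking, sbp, total_chol, hdl_chol, diabetes}.
#' @param gamma_age Named numeric vector of log age-interaction HRs (per 5
#'   years); every name must also appear in \code{beta_main}. The age main
#'   effect itself takes no interaction.
#' @param baseline_surv Numeric vector of length 66 (ages 35-100, optionally
#'   named by age), values in (0, 1\].
#' @return Object of class \code{endpoint_model}.
#' @export
endpoint_model <- function(endpoint, sex, beta_main, gamma_age, baseline_surv) {
  endpoint <- match.arg(endpoint, .endpoints)
  sex <- match.arg(sex, .sexes)
  if (is.null(names(beta_main)) || !all(names(beta_main) %in% .predictors))
    stop("beta_main must be named with predictors among: ",
         paste(.predictors, collapse = ", "))
  bad <- setdiff(names(gamma_age), names(beta_main))
  if (length(bad))
    stop("gamma_age predictors absent from beta_main: ",
         paste(bad, collapse = ", "))
  if ("age" %in% names(gamma_age))
    stop("the age main effect takes no age interaction")
  if (length(baseline_surv) != 66L)
    stop("baseline_surv must cover integer ages 35..100 (length 66)")
  if (any(!is.finite(baseline_surv)) ||
      any(baseline_surv <= 0) || any(baseline_surv > 1))
    stop("baseline_surv values must lie in (0, 1]")
  baseline_surv <- as.numeric(baseline_surv)
  names(baseline_surv) <- as.character(35:100)
  structure(
    list(endpoint = endpoint, sex = sex,
         beta_main = beta_main[order(match(names(beta_main), .predictors))],
         gamma_age = gamma_age[order(match(names(gamma_age), .predictors))],
         centering = .centering, unit = .unit,
         baseline_surv = baseline_surv),
    class = "endpoint_model")
}

#' @export
print.endpoint_model <- function(x, ...) {
  cat(sprintf("<endpoint_model> %s, %s\n", x$endpoint, x$sex))
  hr <- exp(x$beta_main)
  gi <- exp(x$gamma_age)[names(x$beta_main)]
  tab <- data.frame(HR = round(hr, 3),
                    age_interaction = round(gi, 3),
                    row.names = names(x$beta_main))
  print(tab)
  cat(sprintf("baseline 1-y survival: S0(60) = %.5f over ages 35-100\n",
              x$baseline_surv[["60"]]))
  invisible(x)
}

#' Bundle the four endpoint models with optional recalibration scales
#'
#' @param models List of four \code{endpoint_model}s covering both endpoints
#'   for both sexes.
#' @param recalibration \code{NULL} or a data.frame with columns
#'   \code{region, sex, endpoint, scale1, scale2}: rescaling of 1-year risks
#'   on the cloglog scale per risk region (see
#'   \code{\link{apply_recalibration}}). When present it must cover both
#'   endpoints and sexes for every declared region.
#' @param meta Named list of free-form metadata (version, region labels...).
#' @return Object of class \code{model_bundle}.
#' @export
model_bundle <- function(models, recalibration = NULL, meta = list()) {
  keys <- vapply(models, function(m) {
    stopifnot(inherits(m, "endpoint_model"))
    paste(m$endpoint, m$sex, sep = ".")
  }, character(1))
  need <- as.vector(outer(.endpoints, .sexes, paste, sep = "."))
  missing <- setdiff(need, keys)
  if (length(missing))
    stop("bundle is missing endpoint/sex combinations: ",
         paste(missing, collapse = ", "))
  names(models) <- keys
  if (!is.null(recalibration)) {
    recalibration <- as.data.frame(recalibration)
    req <- c("region", "sex", "endpoint", "scale1", "scale2")
    if (!all(req %in% names(recalibration)))
      stop("recalibration needs columns: ", paste(req, collapse = ", "))
    if (any(recalibration$scale2 <= 0))
      stop("recalibration slope (scale2) must be positive")
    for (r in unique(recalibration$region)) {
      sub <- recalibration[recalibration$region == r, ]
      have <- paste(sub$endpoint, sub$sex, sep = ".")
      if (!all(need %in% have))
        stop("recalibration for region '", r,
             "' must cover both endpoints and sexes")
    }
  }
  structure(list(models = models[need], recalibration = recalibration,
                 meta = meta),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat("<model_bundle> endpoints: cvd_event, noncvd_death; sexes: male, female\n")
  if (!is.null(x$recalibration))
    cat("recalibrated regions:",
        paste(unique(x$recalibration$region), collapse = ", "), "\n")
  if (length(x$meta))
    cat("meta:", paste(names(x$meta), unlist(lapply(x$meta, paste, collapse = "/")),
                       sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' Extract one endpoint model from a bundle
#' @param bundle A \code{model_bundle}.
#' @param endpoint,sex Selectors.
#' @export
get_model <- function(bundle, endpoint, sex) {
  stopifnot(inherits(bundle, "model_bundle"))
  endpoint <- match.arg(endpoint, .endpoints)
  sex <- match.arg(sex, .sexes)
  bundle$models[[paste(endpoint, sex, sep = ".")]]
}

#' Extract recalibration scales for one region/sex/endpoint
#'
#' @inheritParams get_model
#' @param region Risk-region label declared in the bundle.
#' @return A \code{recal_scales} object (see \code{\link{recal_scales}}).
#' @export
get_scales <- function(bundle, region, endpoint, sex) {
  stopifnot(inherits(bundle, "model_bundle"))
  rc <- bundle$recalibration
  if (is.null(rc))
    stop("bundle carries no recalibration scales")
  row <- rc[rc$region == region & rc$sex == sex & rc$endpoint == endpoint, ]
  if (nrow(row) != 1L)
    stop("no recalibration scales for region '", region, "', ", sex, ", ",
         endpoint, "; declared regions: ",
         paste(unique(rc$region), collapse = ", "))
  recal_scales(row$scale1, row$scale2, region = region, sex = sex,
               endpoint = endpoint)
}

# centered, unit-scaled covariate vector for the non-age predictors
.scaled_covariates <- function(profile) {
  x <- c(smoking = profile$smoking, sbp = profile$sbp,
         total_chol = profile$total_chol, hdl_chol = profile$hdl_chol,
         diabetes = profile$diabetes)
  (x - .centering[names(x)]) / .unit[names(x)]
}

#' Linear predictor of a cause-specific model at an attained age
#'
#' Computes the log hazard ratio of the individual relative to the reference
#' individual:
#' \deqn{\mathrm{LP}(a) = \beta_{age} z(a) + \sum_j (\beta_j + \gamma_j z(a))
#'       \,(x_j - c_j)/u_j,}
#' where \eqn{z(a) = (a - 60)/5} is the centered, per-5-year-scaled age,
#' \eqn{c_j} the centering constants and \eqn{u_j} the per-unit scalings.
#' Under the default attained-age convention \eqn{z} is evaluated at the
#' attained age of each 1-year window, so 1-year risks are functions of the
#' attained age only; the alternative entry-age convention freezes \eqn{z}
#' at the profile's entry age.
#'
#' @param profile A \code{\link{risk_profile}} of the same sex as the model.
#' @param model An \code{\link{endpoint_model}}.
#' @param attained_age Age in years, 35-100.
#' @param age_convention "attained" (default) or "entry".
#' @return Log hazard ratio (0 for the reference individual).
#' @export
linear_predictor <- function(profile, model, attained_age,
                             age_convention = c("attained", "entry")) {
  age_convention <- match.arg(age_convention)
  stopifnot(inherits(profile, "cvd_profile"), inherits(model, "endpoint_model"))
  if (profile$sex != model$sex)
    stop("profile sex ('", profile$sex, "') does not match model sex ('",
         model$sex, "')")
  if (any(attained_age < 35 | attained_age > 100))
    stop("attained_age must lie in [35, 100]")
  z <- if (age_convention == "attained") (attained_age - 60) / 5
       else (profile$age - 60) / 5
  x <- .scaled_covariates(profile)
  beta <- model$beta_main
  gamma <- structure(numeric(length(x)), names = names(x))
  gamma[names(model$gamma_age)] <- model$gamma_age
  b_age <- if ("age" %in% names(beta)) beta[["age"]] else 0
  covar <- beta[names(x)]
  covar[is.na(covar)] <- 0
  unname(b_age * z + sum(covar * x) + z * sum(gamma * x))
}

#' Conditional 1-year risk of an endpoint at an attained age
#'
#' \eqn{q(a) = 1 - S_0(\lfloor a \rfloor)^{\exp(\mathrm{LP}(a))}}: the
#' probability of the endpoint within the 1-year window starting at the
#' attained age, conditional on being event-free at its start. When
#' recalibration scales are supplied the risk is rescaled on the cloglog
#' scale via \code{\link{apply_recalibration}}.
#'
#' @inheritParams linear_predictor
#' @param scales Optional \code{recal_scales}.
#' @return Probability in \[0, 1).
#' @export
one_year_risk <- function(profile, model, attained_age, scales = NULL,
                          age_convention = c("attained", "entry")) {
  a0 <- floor(attained_age)
  key <- as.character(a0)
  s0 <- unname(model$baseline_surv[key])
  if (any(is.na(s0)))
    stop("baseline survival undefined at age ",
         paste(key[is.na(s0)], collapse = ", "))
  lp <- linear_predictor(profile, model, attained_age, age_convention)
  q <- 1 - s0 ^ exp(lp)
  if (!is.null(scales)) q <- apply_recalibration(q, scales)
  q
}
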