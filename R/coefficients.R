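# Coefficient sets of the packaged default bundle.

#' Published hazard-ratio coefficients of the CVD-event models
#'
#' The sex-specific hazard ratios of the LIFE-CVD2 CVD-event models (fatal
#' plus non-fatal CVD), stored as log HRs per stated unit: age per 5 years,
#' current smoking vs. never/former, SBP per 20 mmHg, total cholesterol per
#' 1 mmol/L, HDL cholesterol per 0.5 mmol/L, history of diabetes; the
#' age-interaction terms are per 5 years of centered age. Age is centred at
#' 60 years, SBP at 120 mmHg, total cholesterol at 6 mmol/L and HDL at
#' 1.3 mmol/L. The diabetes coefficient is carried for recalibration
#' against population statistics that include diabetics and is not used in
#' clinical prediction.
#'
#' @return List with elements \code{male} and \code{female}, each a list of
#'   \code{beta_main} and \code{gamma_age} (named log-HR vectors).
#' @export
published_coefficients <- function() {
  list(
    male = list(
      beta_main = log(c(age = 1.10, smoking = 1.90, sbp = 1.34,
                        total_chol = 1.16, hdl_chol = 0.76,
                        diabetes = 1.94)),
      gamma_age = log(c(smoking = 0.94, sbp = 0.96, total_chol = 0.97,
                        hdl_chol = 1.04, diabetes = 0.91))),
    female = list(
      beta_main = log(c(age = 1.13, smoking = 2.27, sbp = 1.40,
                        total_chol = 1.11, hdl_chol = 0.78,
                        diabetes = 2.35)),
      gamma_age = log(c(smoking = 0.90, sbp = 0.95, total_chol = 0.97,
                        hdl_chol = 1.04, diabetes = 0.89))))
}

#' Synthetic coefficients of the non-CVD mortality models
#'
#' The published non-CVD mortality coefficient tables are not redistributed
#' here; the packaged default bundle instead carries this synthetic,
#' clearly-labelled coefficient set with epidemiologically plausible
#' magnitudes (strong smoking effect, weak blood-pressure and cholesterol
#' effects, protective HDL, strong diabetes effect, effects attenuating
#' with age). Replace them via \code{\link{model_bundle}} /
#' \code{\link{load_model_bundle}} when fitted or published values are
#' available.
#'
#' @return Same structure as \code{\link{published_coefficients}}.
#' @export
synthetic_noncvd_coefficients <- function() {
  list(
    male = list(
      beta_main = log(c(age = 1.10, smoking = 2.00, sbp = 1.05,
                        total_chol = 0.95, hdl_chol = 0.88,
                        diabetes = 1.90)),
      gamma_age = log(c(smoking = 0.95, sbp = 0.99, total_chol = 1.00,
                        hdl_chol = 1.02, diabetes = 0.93))),
    female = list(
      beta_main = log(c(age = 1.12, smoking = 2.10, sbp = 1.06,
                        total_chol = 0.94, hdl_chol = 0.86,
                        diabetes = 2.00)),
      gamma_age = log(c(smoking = 0.94, sbp = 0.99, total_chol = 1.00,
                        hdl_chol = 1.02, diabetes = 0.92))))
}

.bundle_cache <- new.env(parent = emptyenv())

#' The packaged default model bundle
#'
#' Assembles the complete prediction bundle deterministically in code:
#' the published CVD-event coefficients and the synthetic non-CVD mortality
#' coefficients (\code{\link{synthetic_noncvd_coefficients}}), an
#' un-calibrated baseline survival derived from the synthetic low-risk
#' region registry via \code{\link{set_baseline_from_incidence}}, and
#' recalibration scales fitted to all four synthetic regional registries
#' (\code{\link{generate_registry}}). The synthetic registries stand in for
#' the WHO/NCD-RisC inputs of the published regional models, which are not
#' redistributable; absolute risk levels are therefore illustrative while
#' the relative-risk structure of the CVD models is the published one.
#'
#' @param scn Scenario defining the registry conditions (defaults to
#'   \code{scenario()}); the bundle construction itself is deterministic
#'   (no random draws).
#' @return A recalibrated \code{\link{model_bundle}} declaring regions
#'   \code{low, moderate, high, very_high}.
#' @export
default_bundle <- function(scn = scenario()) {
  key <- paste0("bundle_", scn$seed)
  if (!is.null(.bundle_cache[[key]])) return(.bundle_cache[[key]])
  pub <- published_coefficients()
  ncv <- synthetic_noncvd_coefficients()
  flat <- rep(0.99, 66)  # placeholder, replaced by the registry baseline
  models <- list(
    endpoint_model("cvd_event", "male", pub$male$beta_main,
                   pub$male$gamma_age, flat),
    endpoint_model("cvd_event", "female", pub$female$beta_main,
                   pub$female$gamma_age, flat),
    endpoint_model("noncvd_death", "male", ncv$male$beta_main,
                   ncv$male$gamma_age, flat),
    endpoint_model("noncvd_death", "female", ncv$female$beta_main,
                   ncv$female$gamma_age, flat))
  b <- model_bundle(models,
                    meta = list(version = "0.1.0",
                                baseline = "synthetic low-risk registry",
                                noncvd_coefficients = "synthetic"))
  reg <- generate_registry(scn)
  low_reg <- reg$registry[reg$registry$region == "low", ]
  low_means <- reg$means[reg$means$region == "low", ]
  b <- set_baseline_from_incidence(b, low_reg, low_means)
  b <- recalibrate_bundle(b, reg$registry, reg$means)
  .bundle_cache[[key]] <- b
  b
}
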