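# Synthetic cohorts, registries and validation sets with known ground truth.
# Event times are simulated from discrete yearly cause-specific hazards with
# attained-age Gompertz baselines, so the life-table engine is the exact
# oracle for the generator.

#' Simulation scenario
#'
#' Defines the ground truth for the synthetic-data generators: sampling
#' distributions of the covariates (defaults mirror a large multi-cohort
#' derivation population: SBP 135 (SD 19) mmHg, total cholesterol 5.9 (1.1)
#' mmol/L, HDL 1.4 (0.4) mmol/L, 15\% current smokers, 4.7\% diabetes, 43\%
#' male, entry ages uniform 40-75), the true log hazard ratios and
#' age-interaction log HRs per endpoint and sex (defaults are the
#' coefficient sets of \code{\link{published_coefficients}} /
#' \code{\link{synthetic_noncvd_coefficients}}), Gompertz reference
#' baselines (yearly hazard at age 60 and log-slope per year of age), an
#' annual censoring probability and a maximum follow-up.
#'
#' @param seed Integer seed; every generator draws deterministically from it.
#' @param n Number of individuals.
#' @param male_fraction Probability of male sex.
#' @param entry_age Length-2 numeric, uniform bounds of the entry age.
#' @param means,sds Named numeric (\code{sbp, total_chol, hdl_chol}).
#' @param smoking_prev,diabetes_prev Prevalences in \[0, 1\].
#' @param models List keyed \code{"<endpoint>.<sex>"}, each with
#'   \code{beta_main} and \code{gamma_age} (log HRs per stated unit).
#' @param gompertz List keyed likewise, each \code{c(rate60, slope)}:
#'   yearly baseline hazard \code{rate60 * exp(slope * (age - 60))} at the
#'   reference covariates.
#' @param censor_rate Annual probability of loss to follow-up.
#' @param max_followup Administrative censoring, years after entry.
#' @param interaction_age Age convention used when simulating covariate
#'   effects; "entry" (default) matches the Cox derivation
#'   parameterisation, "attained" matches the prediction default.
#' @return Object of class \code{cvd_scenario}.
#' @export
scenario <- function(seed = 1L, n = 10000L, male_fraction = 0.43,
                     entry_age = c(40, 75),
                     means = c(sbp = 135, total_chol = 5.9, hdl_chol = 1.4),
                     sds = c(sbp = 19, total_chol = 1.1, hdl_chol = 0.4),
                     smoking_prev = 0.15, diabetes_prev = 0.047,
                     models = NULL, gompertz = NULL,
                     censor_rate = 0.02, max_followup = 15,
                     interaction_age = c("entry", "attained")) {
  interaction_age <- match.arg(interaction_age)
  if (is.null(models)) {
    models <- list()
    for (sx in .sexes) {
      models[[paste0("cvd_event.", sx)]] <- published_coefficients()[[sx]]
      models[[paste0("noncvd_death.", sx)]] <-
        synthetic_noncvd_coefficients()[[sx]]
    }
  }
  if (is.null(gompertz)) gompertz <- reference_gompertz()
  stopifnot(n >= 0, length(entry_age) == 2L, entry_age[1] >= 35,
            entry_age[2] <= 90, censor_rate >= 0, censor_rate < 1,
            max_followup > 0,
            all(vapply(gompertz, function(g) all(g > 0) || g[2] > -Inf,
                       logical(1))))
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 male_fraction = male_fraction, entry_age = entry_age,
                 means = means, sds = sds, smoking_prev = smoking_prev,
                 diabetes_prev = diabetes_prev, models = models,
                 gompertz = gompertz, censor_rate = censor_rate,
                 max_followup = max_followup,
                 interaction_age = interaction_age),
            class = "cvd_scenario")
}

#' Gompertz reference baselines of the default scenario
#'
#' Yearly cause-specific hazards at the reference covariates,
#' \code{rate60 * exp(slope * (age - 60))}. The values are chosen as
#' realistic low-risk-European orders of magnitude for a healthy reference
#' individual (non-smoking, SBP 120 mmHg, TC 6, HDL 1.3 mmol/L):
#' first-CVD-event incidence of roughly 0.6\% (men) / 0.35\% (women) per
#' year at age 60 doubling about every 8 years, and non-CVD mortality of
#' 0.8\% / 0.55\% per year at 60 doubling about every 7 years.
#'
#' @return List keyed \code{"<endpoint>.<sex>"} of \code{c(rate60, slope)}.
#' @export
reference_gompertz <- function() {
  list(
    "cvd_event.male"      = c(rate60 = 0.0060, slope = 0.085),
    "cvd_event.female"    = c(rate60 = 0.0035, slope = 0.090),
    "noncvd_death.male"   = c(rate60 = 0.0080, slope = 0.100),
    "noncvd_death.female" = c(rate60 = 0.0055, slope = 0.100))
}

# yearly baseline hazard of one scenario endpoint at attained ages
.gompertz_hazard <- function(scn, key, age) {
  g <- scn$gompertz[[key]]
  g[["rate60"]] * exp(g[["slope"]] * (age - 60))
}

# linear predictor from raw covariate columns under a scenario coefficient
# set; `z_age` is the centered/scaled age at which the age terms are taken
.scn_lp <- function(coefs, z_age, smoking, sbp, total_chol, hdl_chol,
                    diabetes) {
  b <- coefs$beta_main
  g <- coefs$gamma_age
  gg <- function(nm) if (nm %in% names(g)) g[[nm]] else 0
  x <- rbind(smoking = smoking,
             sbp = (sbp - 120) / 20,
             total_chol = total_chol - 6,
             hdl_chol = (hdl_chol - 1.3) / 0.5,
             diabetes = diabetes)
  bt <- vapply(rownames(x), function(nm) b[[nm]], numeric(1))
  gt <- vapply(rownames(x), gg, numeric(1))
  b_age <- if ("age" %in% names(b)) b[["age"]] else 0
  b_age * z_age + colSums(x * bt) + z_age * colSums(x * gt)
}

.draw_covariates <- function(scn) {
  n <- scn$n
  tc <- pmax(2, stats::rnorm(n, scn$means[["total_chol"]],
                             scn$sds[["total_chol"]]))
  hdl <- pmax(0.4, stats::rnorm(n, scn$means[["hdl_chol"]],
                                scn$sds[["hdl_chol"]]))
  # HDL is a component of total cholesterol; keep a physiological margin
  hdl <- pmin(hdl, tc - 0.5)
  data.frame(
    sex = ifelse(stats::runif(n) < scn$male_fraction, "male", "female"),
    entry_age = floor(stats::runif(n, scn$entry_age[1], scn$entry_age[2] + 1)),
    smoking = as.numeric(stats::runif(n) < scn$smoking_prev),
    sbp = pmax(70, stats::rnorm(n, scn$means[["sbp"]], scn$sds[["sbp"]])),
    total_chol = tc, hdl_chol = hdl,
    diabetes = as.numeric(stats::runif(n) < scn$diabetes_prev))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Covariates are drawn from the scenario distributions; event times from
#' discrete yearly cause-specific hazards (attained-age Gompertz baseline
#' times the scenario's proportional-hazards effects). Within a year a CVD
#' event takes precedence over non-CVD death, matching the life-table
#' composition; censoring is independent with the scenario's annual rate
#' plus administrative censoring at the maximum follow-up (or age 100).
#' Output is deterministic given the scenario seed.
#'
#' @param scn A \code{\link{scenario}}.
#' @param n_cohorts Number of cohort labels assigned round-robin (for
#'   stratified model derivation).
#' @return Data frame of cohort records: \code{cohort_id, sex, entry_age,
#'   exit_age, event} (one of \code{cvd_event, noncvd_death, censored}) and
#'   the predictor columns.
#' @export
generate_cohort <- function(scn, n_cohorts = 4L) {
  stopifnot(inherits(scn, "cvd_scenario"))
  if (scn$n <= 0) stop("scenario n must be positive")
  set.seed(scn$seed)
  cov <- .draw_covariates(scn)
  n <- scn$n
  hmax <- vapply(names(scn$gompertz), function(k)
    max(.gompertz_hazard(scn, k, 35:100)), numeric(1))
  if (any(-expm1(-hmax) >= 1)) stop("scenario implies yearly hazard >= 1")
  z_entry <- (cov$entry_age - 60) / 5

  mult <- matrix(NA_real_, n, 2,
                 dimnames = list(NULL, .endpoints))
  zage_b <- matrix(0, n, 2, dimnames = list(NULL, .endpoints))
  for (ep in .endpoints) for (sx in .sexes) {
    i <- cov$sex == sx
    if (!any(i)) next
    cf <- scn$models[[paste(ep, sx, sep = ".")]]
    if (scn$interaction_age == "entry") {
      mult[i, ep] <- exp(.scn_lp(cf, z_entry[i], cov$smoking[i], cov$sbp[i],
                                 cov$total_chol[i], cov$hdl_chol[i],
                                 cov$diabetes[i]))
    } else {
      # attained-age convention: covariate part recomputed each year below
      mult[i, ep] <- NA_real_
    }
  }

  alive <- rep(TRUE, n)
  exit_age <- cov$entry_age
  event <- rep("censored", n)
  year <- 0L
  while (any(alive) && year < scn$max_followup) {
    a <- cov$entry_age + year
    active <- alive & a < 100
    if (!any(active)) break
    idx <- which(active)
    qc <- qd <- numeric(length(idx))
    for (sx in .sexes) {
      j <- cov$sex[idx] == sx
      if (!any(j)) next
      jj <- idx[j]
      if (scn$interaction_age == "entry") {
        mc <- mult[jj, "cvd_event"]; md <- mult[jj, "noncvd_death"]
      } else {
        za <- (a[jj] - 60) / 5
        cfc <- scn$models[[paste0("cvd_event.", sx)]]
        cfd <- scn$models[[paste0("noncvd_death.", sx)]]
        mc <- exp(.scn_lp(cfc, za, cov$smoking[jj], cov$sbp[jj],
                          cov$total_chol[jj], cov$hdl_chol[jj],
                          cov$diabetes[jj]))
        md <- exp(.scn_lp(cfd, za, cov$smoking[jj], cov$sbp[jj],
                          cov$total_chol[jj], cov$hdl_chol[jj],
                          cov$diabetes[jj]))
      }
      qc[j] <- -expm1(-.gompertz_hazard(scn, paste0("cvd_event.", sx),
                                        a[jj]) * mc)
      qd[j] <- -expm1(-.gompertz_hazard(scn, paste0("noncvd_death.", sx),
                                        a[jj]) * md)
    }
    u1 <- stats::runif(length(idx))
    u2 <- stats::runif(length(idx))
    u3 <- stats::runif(length(idx))
    is_cvd <- u1 < qc
    is_death <- !is_cvd & u2 < qd
    is_cens <- !is_cvd & !is_death & u3 < scn$censor_rate
    done <- is_cvd | is_death | is_cens
    event[idx[is_cvd]] <- "cvd_event"
    event[idx[is_death]] <- "noncvd_death"
    exit_age[idx[done]] <- a[idx[done]] + 1
    alive[idx[done]] <- FALSE
    year <- year + 1L
  }
  exit_age[alive] <- pmin(cov$entry_age[alive] + year, 100)
  # subjects that hit the age ceiling before max follow-up
  still <- alive & (cov$entry_age + year >= 100)
  exit_age[still] <- 100

  data.frame(cohort_id = paste0("cohort_",
                                (seq_len(n) - 1L) %% n_cohorts + 1L),
             sex = cov$sex, entry_age = cov$entry_age, exit_age = exit_age,
             event = event, smoking = cov$smoking, sbp = cov$sbp,
             total_chol = cov$total_chol, hdl_chol = cov$hdl_chol,
             diabetes = cov$diabetes)
}

#' Generate synthetic registry and mean-risk-factor tables
#'
#' Computes 5-year age-group (35-39 ... 95-99) event rates in closed form
#' from the scenario's hazards evaluated at the group-mean covariates, then
#' scales the yearly hazards by a per-region factor. The CVD rate is stored
#' as a mortality rate together with the total-to-fatal multiplier that
#' recovers it, and the non-CVD rate with its prior-CVD correction, so that
#' \code{\link{observed_annual_risks}} reproduces the generating rates
#' exactly. Region hazard factors are relative to the low-risk region; the
#' defaults follow the roughly 1:1.5:2.5:4 gradient of standardised CVD
#' mortality across the four European risk regions, with a much flatter
#' gradient (1:1.15:1.35:1.6) for non-CVD mortality.
#'
#' @param scn A \code{\link{scenario}}.
#' @param region_factor_cvd,region_factor_noncvd Named per-region hazard
#'   multipliers.
#' @param multiplier Total-to-fatal CVD multiplier stored in the registry.
#' @param prior_cvd_correction Correction factor for prior-CVD presence in
#'   non-CVD mortality statistics.
#' @return List with data frames \code{registry} and \code{means}.
#' @export
generate_registry <- function(scn,
                              region_factor_cvd = c(low = 1, moderate = 1.5,
                                                    high = 2.5,
                                                    very_high = 4),
                              region_factor_noncvd = c(low = 1,
                                                       moderate = 1.15,
                                                       high = 1.35,
                                                       very_high = 1.6),
                              multiplier = 3, prior_cvd_correction = 0.95) {
  stopifnot(inherits(scn, "cvd_scenario"),
            identical(names(region_factor_cvd), names(region_factor_noncvd)))
  age_lo <- seq(35, 95, by = 5)
  age_hi <- age_lo + 4
  mid <- (age_lo + age_hi) / 2
  registry <- means <- list()
  for (r in names(region_factor_cvd)) for (sx in .sexes) {
    lp <- lapply(.endpoints, function(ep) {
      cf <- scn$models[[paste(ep, sx, sep = ".")]]
      # registries summarise attained-age incidence: attained-age convention
      .scn_lp(cf, (mid - 60) / 5, scn$smoking_prev,
              scn$means[["sbp"]], scn$means[["total_chol"]],
              scn$means[["hdl_chol"]], scn$diabetes_prev)
    })
    names(lp) <- .endpoints
    h_cvd <- .gompertz_hazard(scn, paste0("cvd_event.", sx), mid) *
      exp(lp$cvd_event) * region_factor_cvd[[r]]
    h_nc <- .gompertz_hazard(scn, paste0("noncvd_death.", sx), mid) *
      exp(lp$noncvd_death) * region_factor_noncvd[[r]]
    registry[[length(registry) + 1L]] <- data.frame(
      region = r, sex = sx, age_lo = age_lo, age_hi = age_hi,
      cvd_mortality_rate = h_cvd / multiplier,
      noncvd_mortality_rate = h_nc / prior_cvd_correction,
      multiplier_total_to_fatal = multiplier,
      prior_cvd_correction = prior_cvd_correction)
    means[[length(means) + 1L]] <- data.frame(
      region = r, sex = sx, age_lo = age_lo, age_hi = age_hi,
      sbp = scn$means[["sbp"]], total_chol = scn$means[["total_chol"]],
      hdl_chol = scn$means[["hdl_chol"]], smoking = scn$smoking_prev,
      diabetes = scn$diabetes_prev)
  }
  list(registry = do.call(rbind, registry), means = do.call(rbind, means))
}

#' Generate a validation set from a bundle's own hazards
#'
#' Draws covariate profiles from the scenario, computes each individual's
#' life table from the bundle (so predicted risks are exact by
#' construction), and simulates outcomes year by year from those same
#' annual risks with independent censoring. Calibration of the bundle on
#' this set is therefore perfect up to sampling error.
#'
#' @param scn A \code{\link{scenario}} (covariates, censoring, seed).
#' @param bundle A \code{\link{model_bundle}}.
#' @param region Optional region whose recalibration scales are applied.
#' @param horizon Risk horizon in years for the stored predictions.
#' @return Data frame: \code{sex, entry_age}, predictor columns,
#'   \code{predicted} (risk at the horizon), \code{time} (years from entry),
#'   \code{event} (0 censored, 1 CVD event, 2 competing death).
#' @export
generate_validation_set <- function(scn, bundle, region = NULL,
                                    horizon = 10) {
  stopifnot(inherits(scn, "cvd_scenario"), inherits(bundle, "model_bundle"))
  if (scn$n <= 0) stop("scenario n must be positive")
  set.seed(scn$seed + 1L)
  cov <- .draw_covariates(scn)
  n <- scn$n
  predicted <- numeric(n)
  time <- numeric(n)
  event <- integer(n)
  for (i in seq_len(n)) {
    p <- risk_profile(cov$sex[i], cov$entry_age[i], cov$smoking[i],
                      cov$sbp[i], cov$total_chol[i], cov$hdl_chol[i],
                      cov$diabetes[i])
    lt <- build_life_table(p, bundle, region, clinical = FALSE)
    k <- min(horizon, nrow(lt))
    predicted[i] <- sum(lt$uncond_cvd[seq_len(k)])
    t_i <- nrow(lt); ev <- 0L
    for (y in seq_len(nrow(lt))) {
      if (stats::runif(1) < lt$q_cvd[y]) { t_i <- y; ev <- 1L; break }
      if (stats::runif(1) < lt$q_death[y]) { t_i <- y; ev <- 2L; break }
      if (stats::runif(1) < scn$censor_rate) { t_i <- y; ev <- 0L; break }
      if (y >= scn$max_followup) { t_i <- y; ev <- 0L; break }
    }
    time[i] <- t_i
    event[i] <- ev
  }
  cbind(cov, data.frame(predicted = predicted, time = time, event = event))
}
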