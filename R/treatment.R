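# Lifetime treatment benefit: causal hazard ratios from trials and
# meta-analyses applied to the annual risks of the life table, with the gain
# in CVD-free life expectancy as the benefit measure.

#' Preventive intervention
#'
#' A constant (stable over all future life years) causal hazard ratio
#' applied to the annual CVD event risks and, optionally, to the annual
#' non-CVD death risks. \code{dose} multiplies the effect on the log-hazard
#' scale: the effective HR is \code{hr^dose} (e.g. \code{dose = 2} with the
#' per-10 mmHg HR encodes a 20 mmHg SBP reduction).
#'
#' Built-in effect sizes (see \code{\link{standard_interventions}}): HR 0.78
#' per 1 mmol/L LDL cholesterol reduction, HR 0.80 per 10 mmHg SBP
#' reduction, and smoking cessation with HR 0.60 on CVD events and 0.73 on
#' non-CVD mortality.
#'
#' @param label Short label.
#' @param hr_cvd Hazard ratio on annual CVD risks (> 0).
#' @param hr_noncvd Hazard ratio on annual non-CVD death risks (default 1).
#' @param dose Dose multiplicity (>= 0), applied to both HRs.
#' @export
intervention <- function(label, hr_cvd, hr_noncvd = 1, dose = 1) {
  stopifnot(hr_cvd > 0, hr_noncvd > 0, dose >= 0)
  structure(list(label = label, hr_cvd = hr_cvd, hr_noncvd = hr_noncvd,
                 dose = dose),
            class = "intervention")
}

#' @export
print.intervention <- function(x, ...) {
  cat(sprintf("<intervention> %s: HR_cvd %.3g, HR_noncvd %.3g, dose %.3g\n",
              x$label, x$hr_cvd, x$hr_noncvd, x$dose))
  invisible(x)
}

#' Standard preventive interventions
#'
#' @param sbp_reduction SBP reduction in mmHg for \code{sbp}.
#' @param ldl_reduction LDL cholesterol reduction in mmol/L for \code{ldl}.
#' @return Named list of \code{\link{intervention}}s: \code{sbp}, \code{ldl}
#'   and \code{quit_smoking}.
#' @export
standard_interventions <- function(sbp_reduction = 10, ldl_reduction = 1) {
  list(
    sbp = intervention("SBP lowering", hr_cvd = 0.80,
                       dose = sbp_reduction / 10),
    ldl = intervention("LDL-cholesterol lowering", hr_cvd = 0.78,
                       dose = ldl_reduction),
    quit_smoking = intervention("smoking cessation", hr_cvd = 0.60,
                                hr_noncvd = 0.73, dose = 1))
}

#' Apply an intervention hazard ratio to a life table
#'
#' Each conditional annual risk is rescaled on the hazard (power) scale,
#' \eqn{q' = 1-(1-q)^{HR^{dose}}} — exact under proportional hazards — and
#' the survival and cumulative columns are rebuilt. The HR is constant
#' across all ages.
#'
#' @param table A \code{life_table}.
#' @param iv An \code{\link{intervention}}.
#' @return The treated \code{life_table}.
#' @export
apply_intervention <- function(table, iv) {
  stopifnot(inherits(table, "life_table"), inherits(iv, "intervention"))
  e_cvd <- iv$hr_cvd ^ iv$dose
  e_death <- iv$hr_noncvd ^ iv$dose
  # an effective HR of exactly 1 must be the exact identity
  q_cvd <- if (e_cvd == 1) table$q_cvd else 1 - (1 - table$q_cvd) ^ e_cvd
  q_death <- if (e_death == 1) table$q_death
             else 1 - (1 - table$q_death) ^ e_death
  out <- life_table_from_hazards(attr(table, "start_age"), q_cvd, q_death)
  attr(out, "profile") <- attr(table, "profile")
  attr(out, "region") <- attr(table, "region")
  attr(out, "intervention") <- iv
  out
}

#' Gain in CVD-free life expectancy from an intervention
#'
#' Difference in median event-free survival age between the life table with
#' the intervention's causal HR applied and the untreated life table;
#' non-negative whenever both HRs are at most 1. If either arm's median is
#' censored at the age-100 model ceiling the gain is a lower bound and is
#' flagged via attribute \code{lower_bound = TRUE}.
#'
#' @inheritParams build_life_table
#' @param iv An \code{\link{intervention}}.
#' @return Gain in years with attribute \code{lower_bound}.
#' @export
gain_cvd_free_life_expectancy <- function(profile, bundle, region = NULL, iv,
                                          clinical = TRUE) {
  lt0 <- build_life_table(profile, bundle, region, clinical = clinical)
  lt1 <- apply_intervention(lt0, iv)
  le0 <- cvd_free_life_expectancy(lt0)
  le1 <- cvd_free_life_expectancy(lt1)
  structure(as.numeric(le1) - as.numeric(le0),
            lower_bound = isTRUE(attr(le0, "censored")) ||
                          isTRUE(attr(le1, "censored")))
}

#' Gain in CVD-free life expectancy from smoking cessation
#'
#' Applies the cessation hazard ratios (0.60 on CVD events, 0.73 on non-CVD
#' mortality) to a current smoker's life table. The smoking covariate stays
#' 1 in the linear predictor: the causal HR carries the whole effect.
#'
#' @inheritParams gain_cvd_free_life_expectancy
#' @export
smoking_cessation_benefit <- function(profile, bundle, region = NULL,
                                      clinical = TRUE) {
  stopifnot(inherits(profile, "cvd_profile"))
  if (profile$smoking < 1)
    stop("smoking cessation benefit is defined for current smokers only")
  gain_cvd_free_life_expectancy(
    profile, bundle, region, standard_interventions()$quit_smoking,
    clinical = clinical)
}

#' Benefit chart: gains over a grid of risk-factor levels
#'
#' Computes the gain in CVD-free life expectancy for every cell of a grid of
#' age, sex, smoking status, SBP and total cholesterol (HDL held fixed),
#' for one of three chart rules:
#' \describe{
#'   \item{\code{sbp_below_140}}{SBP reduction to below 140 mmHg: dose
#'     \code{max(0, (sbp-140)/10)} at HR 0.80 per 10 mmHg; cells already
#'     below 140 gain 0.}
#'   \item{\code{ldl_40pct}}{40\% LDL-cholesterol reduction, with LDL
#'     approximated as \code{total_chol - hdl_chol - 0.8} mmol/L (the proxy
#'     lives only in this chart layer): dose \code{0.4*LDL} at HR 0.78 per
#'     mmol/L.}
#'   \item{\code{quit_smoking}}{Smoking cessation HRs, applied to smoking
#'     cells only (gain 0 in non-smoking cells).}
#' }
#'
#' @param grid Data frame with columns \code{age, sex, smoking, sbp,
#'   total_chol} (and optionally \code{hdl_chol}, default 1.3).
#' @param bundle,region As in \code{\link{build_life_table}}.
#' @param rule Chart rule, see above.
#' @return The grid with a \code{gain} column (years).
#' @export
benefit_chart <- function(grid, bundle, region = NULL,
                          rule = c("sbp_below_140", "ldl_40pct",
                                   "quit_smoking")) {
  rule <- match.arg(rule)
  grid <- as.data.frame(grid)
  if (!nrow(grid)) stop("empty chart grid")
  req <- c("age", "sex", "smoking", "sbp", "total_chol")
  miss <- setdiff(req, names(grid))
  if (length(miss)) stop("grid is missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(grid$hdl_chol)) grid$hdl_chol <- 1.3
  grid$gain <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    p <- risk_profile(g$sex, g$age, smoking = g$smoking, sbp = g$sbp,
                      total_chol = g$total_chol, hdl_chol = g$hdl_chol)
    iv <- switch(rule,
      sbp_below_140 = intervention("SBP to <140", hr_cvd = 0.80,
                                   dose = max(0, (g$sbp - 140) / 10)),
      ldl_40pct = intervention("40% LDL reduction", hr_cvd = 0.78,
                               dose = 0.4 * max(0, g$total_chol -
                                                   g$hdl_chol - 0.8)),
      quit_smoking = if (g$smoking >= 1)
        standard_interventions()$quit_smoking
      else intervention("no change", hr_cvd = 1, dose = 0))
    as.numeric(gain_cvd_free_life_expectancy(p, bundle, region, iv))
  }, numeric(1))
  grid
}
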