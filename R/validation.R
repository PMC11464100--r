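# Model validation: discrimination by a competing-risk-corrected Harrell
# C-index and calibration in deciles of predicted risk with Aalen-Johansen
# observed cumulative incidence.

.event_factor <- function(event)
  factor(event, levels = 0:2, labels = c("censored", "cvd", "death"))

.check_validation_set <- function(set) {
  req <- c("predicted", "time", "event")
  miss <- setdiff(req, names(set))
  if (length(miss))
    stop("validation set is missing columns: ", paste(miss, collapse = ", "))
  if (any(set$predicted < 0 | set$predicted > 1))
    stop("predicted risks must lie in [0, 1]")
  if (any(set$time <= 0)) stop("follow-up times must be positive")
  if (!all(set$event %in% 0:2))
    stop("event must be coded 0 (censored), 1 (CVD event), 2 (competing death)")
  invisible(set)
}

#' Competing-risk-corrected Harrell C-index
#'
#' Concordance between predicted risks and observed outcomes up to a
#' horizon, with the Wolbers-style competing-risk correction: subjects
#' experiencing the competing event (non-CVD death) remain in the
#' comparison set as non-cases for the full horizon, since they are known
#' never to experience the CVD endpoint. A pair is admissible when one
#' member is a case (CVD event at \eqn{t \le} horizon) and the other is
#' either event-free longer than \eqn{t} (a later case, or censored after
#' \eqn{t}) or a competing-event subject; censored subjects cannot inform
#' pairs beyond their censoring time and are excluded from those. Tied
#' predictions count 1/2.
#'
#' @param set Validation data frame with columns \code{predicted} (risk at
#'   the horizon), \code{time} (years), \code{event} (0 censored, 1 CVD,
#'   2 competing death).
#' @param horizon Horizon in years.
#' @return Concordance in \[0, 1\].
#' @export
cindex_competing <- function(set, horizon = 10) {
  .check_validation_set(set)
  pred <- set$predicted
  time <- set$time
  event <- set$event
  case <- event == 1L & time <= horizon
  if (!any(case)) stop("no CVD events before the horizon; C is undefined")
  competing <- event == 2L & time <= horizon
  conc <- 0; ties <- 0; npairs <- 0
  for (i in which(case)) {
    # at-risk longer than the case, censored exactly at the case's event
    # time (standard Harrell convention: censoring follows events), or a
    # competing-event subject (never a case, full-horizon non-case)
    comp <- (time > time[i]) |
      (time == time[i] & event == 0L) |
      competing
    comp[i] <- FALSE
    m <- sum(comp)
    if (!m) next
    npairs <- npairs + m
    conc <- conc + sum(pred[i] > pred[comp])
    ties <- ties + sum(pred[i] == pred[comp])
  }
  if (!npairs) stop("no admissible pairs")
  (conc + 0.5 * ties) / npairs
}

#' Automatic validation horizon
#'
#' 10 years, or the latest full year at which at least 80\% of the
#' individuals are still under follow-up.
#'
#' @param set Validation data frame (see \code{\link{cindex_competing}}).
#' @export
validation_horizon <- function(set) {
  .check_validation_set(set)
  for (h in 10:1)
    if (mean(set$time >= h) >= 0.8) return(h)
  stop("fewer than 80% of individuals reach even 1 year of follow-up")
}

#' Calibration in deciles of predicted risk
#'
#' Groups the set into deciles of predicted risk and compares the mean
#' predicted risk with the observed cumulative incidence of CVD at the
#' horizon, estimated nonparametrically by the Aalen-Johansen estimator
#' with competing death treated as a competing event (not censoring); a
#' naive Kaplan-Meier would bias the observed incidence upward.
#'
#' @param set Validation data frame.
#' @param horizon Horizon in years; \code{NULL} applies
#'   \code{\link{validation_horizon}}.
#' @return Data frame with one row per decile: \code{decile, n, events,
#'   mean_predicted, observed}, plus attribute \code{horizon}.
#' @export
calibration_deciles <- function(set, horizon = NULL) {
  .check_validation_set(set)
  if (is.null(horizon)) horizon <- validation_horizon(set)
  breaks <- stats::quantile(set$predicted, probs = 0:10 / 10)
  if (anyDuplicated(breaks))
    stop("predicted risks are too concentrated; deciles collapse")
  dec <- cut(set$predicted, breaks, include.lowest = TRUE, labels = FALSE)
  out <- lapply(1:10, function(k) {
    s <- set[dec == k, , drop = FALSE]
    obs <- if (any(s$event != 0L)) {
      fit <- survival::survfit(
        survival::Surv(time, .event_factor(event)) ~ 1, data = s)
      sm <- summary(fit, times = horizon, extend = TRUE)
      sm$pstate[1, match("cvd", fit$states)]
    } else 0
    data.frame(decile = k, n = nrow(s),
               events = sum(s$event == 1L & s$time <= horizon),
               mean_predicted = mean(s$predicted), observed = obs)
  })
  out <- do.call(rbind, out)
  attr(out, "horizon") <- horizon
  out
}

#' Lifetime (age-scale) calibration
#'
#' Compares the model's lifetime risk curve with the observed cumulative
#' incidence of CVD computed with age as the timescale (left truncation at
#' entry age, Aalen-Johansen with competing death as a competing event).
#' The predicted curve is the life-table cumulative unconditional CVD risk
#' of a profile at the set's sex-specific mean covariates, starting at the
#' minimum entry age.
#'
#' @param set Validation data frame that additionally carries
#'   \code{sex, entry_age} and the predictor columns \code{smoking, sbp,
#'   total_chol, hdl_chol, diabetes}.
#' @param bundle,region As in \code{\link{build_life_table}}.
#' @return Data frame \code{sex, age, predicted, observed} over integer
#'   ages from entry to the last exit age.
#' @export
lifetime_calibration <- function(set, bundle, region = NULL) {
  .check_validation_set(set)
  req <- c("sex", "entry_age", "smoking", "sbp", "total_chol", "hdl_chol",
           "diabetes")
  miss <- setdiff(req, names(set))
  if (length(miss))
    stop("set is missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(set) || diff(range(set$entry_age)) < 0 ||
      !length(unique(set$entry_age)))
    stop("empty ages range")
  out <- list()
  for (sx in unique(set$sex)) {
    s <- set[set$sex == sx, , drop = FALSE]
    start <- floor(min(s$entry_age))
    end <- min(100, ceiling(max(s$entry_age + s$time)))
    if (end <= start) stop("empty ages range")
    p <- risk_profile(sx, min(max(start, 35), 90),
                      smoking = mean(s$smoking), sbp = mean(s$sbp),
                      total_chol = mean(s$total_chol),
                      hdl_chol = mean(s$hdl_chol),
                      diabetes = mean(s$diabetes))
    lt <- build_life_table(p, bundle, region, clinical = FALSE)
    ages <- (start + 1):end
    predicted <- vapply(ages, function(a) sum(lt$uncond_cvd[lt$age < a]),
                        numeric(1))
    fit <- survival::survfit(
      survival::Surv(entry_age, entry_age + time, .event_factor(event)) ~ 1,
      data = s)
    sm <- summary(fit, times = ages, extend = TRUE)
    observed <- sm$pstate[, match("cvd", fit$states)]
    out[[sx]] <- data.frame(sex = sx, age = ages, predicted = predicted,
                            observed = observed)
  }
  do.call(rbind, out)
}
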