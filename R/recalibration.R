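# Systematic recalibration of 1-year risks to registry incidence, following
# the SCORE2-style approach: registry mortality rates are converted to event
# incidence with multipliers, compared with model-predicted risks at
# age-group mean risk-factor levels, and the relation is summarised by an
# intercept/slope rescaling on the cloglog scale.

cloglog <- function(q) log(-log1p(-q))
inv_cloglog <- function(x) -expm1(-exp(x))

#' Recalibration scales on the cloglog scale
#'
#' \code{scale1} (intercept) and \code{scale2} (slope) rescale a 1-year risk
#' \eqn{q} as \eqn{q' = 1 - \exp(-\exp(scale1 + scale2\,\mathrm{cloglog}(q)))}
#' with \eqn{\mathrm{cloglog}(q) = \ln(-\ln(1-q))}. \code{(0, 1)} is the
#' identity; \code{(ln k, 1)} multiplies the yearly hazard by \eqn{k}.
#'
#' @param scale1 Intercept on the cloglog scale.
#' @param scale2 Slope on the cloglog scale; must be positive so rank order
#'   of risks is preserved.
#' @param region,sex,endpoint Optional labels.
#' @export
recal_scales <- function(scale1, scale2, region = NA_character_,
                         sex = NA_character_, endpoint = NA_character_) {
  stopifnot(is.finite(scale1), is.finite(scale2))
  if (scale2 <= 0) stop("scale2 must be positive")
  structure(list(scale1 = as.numeric(scale1), scale2 = as.numeric(scale2),
                 region = region, sex = sex, endpoint = endpoint),
            class = "recal_scales")
}

#' @export
print.recal_scales <- function(x, ...) {
  cat(sprintf("<recal_scales> scale1 = %.4f, scale2 = %.4f (%s, %s, %s)\n",
              x$scale1, x$scale2, x$region, x$sex, x$endpoint))
  invisible(x)
}

#' Rescale a 1-year risk with recalibration scales
#'
#' Strictly increasing in \code{q}; boundary values are mapped to
#' themselves (0 to 0, 1 to 1).
#'
#' @param q Probability (vectorised).
#' @param scales A \code{\link{recal_scales}} object.
#' @export
apply_recalibration <- function(q, scales) {
  stopifnot(inherits(scales, "recal_scales"))
  out <- q
  inside <- q > 0 & q < 1
  out[inside] <- inv_cloglog(scales$scale1 + scales$scale2 * cloglog(q[inside]))
  out[q <= 0] <- 0
  out[q >= 1] <- 1
  out
}

.check_registry <- function(registry) {
  req <- c("region", "sex", "age_lo", "age_hi", "cvd_mortality_rate",
           "noncvd_mortality_rate", "multiplier_total_to_fatal",
           "prior_cvd_correction")
  miss <- setdiff(req, names(registry))
  if (length(miss))
    stop("registry table is missing columns: ", paste(miss, collapse = ", "))
  if (any(registry$cvd_mortality_rate < 0) ||
      any(registry$noncvd_mortality_rate < 0))
    stop("registry mortality rates must be non-negative")
  if (any(registry$multiplier_total_to_fatal < 1))
    stop("total-to-fatal multipliers must be >= 1")
  ord <- order(registry$age_lo)
  if (any(diff(registry$age_lo[ord]) != diff(registry$age_hi[ord])))
    stop("age groups must be contiguous and non-overlapping")
  invisible(registry)
}

#' Registry observed annual risks per age group
#'
#' Converts registry cause-specific mortality rates to annual event
#' probabilities. For the CVD endpoint the mortality rate is scaled by the
#' total-to-fatal multiplier to approximate total (fatal + non-fatal) event
#' incidence; for non-CVD death the mortality rate is corrected for persons
#' with established CVD present in national mortality statistics. Rates
#' (events/person-year) become 1-year probabilities via
#' \eqn{q = 1 - e^{-rate}} (constant hazard within the year).
#'
#' @param registry Data frame with one row per 5-year age group and columns
#'   \code{region, sex, age_lo, age_hi, cvd_mortality_rate,
#'   noncvd_mortality_rate, multiplier_total_to_fatal, prior_cvd_correction}.
#' @param endpoint "cvd_event" or "noncvd_death".
#' @return Data frame \code{age_lo, age_hi, age_mid, q} (one row per group).
#' @export
observed_annual_risks <- function(registry, endpoint) {
  endpoint <- match.arg(endpoint, .endpoints)
  .check_registry(registry)
  rate <- if (endpoint == "cvd_event")
    registry$cvd_mortality_rate * registry$multiplier_total_to_fatal
  else
    registry$noncvd_mortality_rate * registry$prior_cvd_correction
  out <- data.frame(age_lo = registry$age_lo, age_hi = registry$age_hi,
                    age_mid = (registry$age_lo + registry$age_hi) / 2,
                    q = -expm1(-rate))
  out[order(out$age_lo), ]
}

.check_means <- function(means) {
  req <- c("region", "sex", "age_lo", "age_hi", "sbp", "total_chol",
           "hdl_chol", "smoking", "diabetes")
  miss <- setdiff(req, names(means))
  if (length(miss))
    stop("means table is missing columns: ", paste(miss, collapse = ", "))
  if (any(means$smoking < 0 | means$smoking > 1) ||
      any(means$diabetes < 0 | means$diabetes > 1))
    stop("prevalences must lie in [0, 1]")
  invisible(means)
}

# profile standing for a whole age group: fractional binaries carry the
# group prevalences; entry age is clamped into the 35-90 window because the
# attained-age convention reads age from the evaluation age, not the profile
.group_profile <- function(sex, age_mid, row) {
  risk_profile(sex, age = min(max(age_mid, 35), 90), smoking = row$smoking,
               sbp = row$sbp, total_chol = row$total_chol,
               hdl_chol = row$hdl_chol, diabetes = row$diabetes)
}

#' Model-predicted annual risks at age-group mean risk-factor levels
#'
#' Evaluates \code{\link{one_year_risk}} (un-recalibrated) at each group's
#' midpoint age with the group's mean covariates, prevalences entering the
#' binary predictors as fractional values.
#'
#' @param bundle An un-recalibrated \code{\link{model_bundle}} (its scales,
#'   if any, are ignored here).
#' @param means Data frame with columns \code{region, sex, age_lo, age_hi,
#'   sbp, total_chol, hdl_chol, smoking, diabetes}, one row per 5-year group.
#' @param endpoint,sex Selectors.
#' @return Data frame \code{age_lo, age_hi, age_mid, q}.
#' @export
predicted_group_risks <- function(bundle, means, endpoint, sex) {
  .check_means(means)
  model <- get_model(bundle, endpoint, sex)
  rows <- means[means$sex == sex, , drop = FALSE]
  if (!nrow(rows)) stop("no rows in the means table for sex '", sex, "'")
  rows <- rows[order(rows$age_lo), ]
  mid <- (rows$age_lo + rows$age_hi) / 2
  if (any(mid < 35 | mid > 100))
    stop("age-group midpoints must lie within 35..100")
  q <- vapply(seq_len(nrow(rows)), function(i) {
    p <- .group_profile(sex, mid[i], rows[i, ])
    one_year_risk(p, model, mid[i])
  }, numeric(1))
  data.frame(age_lo = rows$age_lo, age_hi = rows$age_hi, age_mid = mid, q = q)
}

#' Fit recalibration scales from observed and predicted group risks
#'
#' Ordinary least squares of \code{cloglog(observed)} on
#' \code{cloglog(predicted)} across age groups, unweighted. Identical
#' observed and predicted risks give the identity scales (0, 1); observed
#' risks whose yearly hazard is \eqn{k} times the predicted hazard give
#' \eqn{(\ln k, 1)}.
#'
#' @param observed,predicted Numeric probability vectors over the same age
#'   groups (or the data frames returned by
#'   \code{\link{observed_annual_risks}} /
#'   \code{\link{predicted_group_risks}}), all strictly in (0, 1), at least
#'   three groups.
#' @param ... Labels passed to \code{\link{recal_scales}}.
#' @export
fit_recalibration <- function(observed, predicted, ...) {
  if (is.data.frame(observed)) observed <- observed$q
  if (is.data.frame(predicted)) predicted <- predicted$q
  if (length(observed) != length(predicted))
    stop("observed and predicted must cover the same age groups")
  ok <- observed > 0 & observed < 1 & predicted > 0 & predicted < 1
  if (!all(ok))
    stop("all group risks must lie strictly in (0, 1)")
  if (length(observed) < 3L)
    stop("at least 3 age groups are required to fit recalibration scales")
  fit <- stats::lm(cloglog(observed) ~ cloglog(predicted))
  co <- stats::coef(fit)
  if (any(!is.finite(co)))
    stop("recalibration fit is degenerate (constant predicted risks?)")
  recal_scales(co[[1]], co[[2]], ...)
}

#' Derive the baseline survival from low-risk-region incidence
#'
#' Chooses the per-age baseline 1-year survival \eqn{S_0(a)} of one endpoint
#' model so that the model's predicted group risks at the region's mean
#' risk-factor levels reproduce the registry's observed annual risks exactly
#' at the group midpoints. At midpoint \eqn{m} the yearly baseline hazard is
#' \eqn{h(m) = -\ln(1-q_{obs}(m))\,e^{-\mathrm{LP}(m)}}; between midpoints
#' log hazards are interpolated with a monotone cubic (Fritsch-Carlson), and
#' beyond the outermost midpoints extended log-linearly (Gompertz-type
#' tails), yielding a smooth baseline over ages 35-100.
#'
#' @param registry,means Low-risk-region tables (see
#'   \code{\link{observed_annual_risks}} and
#'   \code{\link{predicted_group_risks}}).
#' @param model The \code{\link{endpoint_model}} supplying coefficients (its
#'   existing baseline is ignored).
#' @return Named numeric vector: baseline survival at integer ages 35..100.
#' @export
baseline_from_incidence <- function(registry, means, model) {
  obs <- observed_annual_risks(registry[registry$sex == model$sex, ,
                                        drop = FALSE], model$endpoint)
  .check_means(means)
  rows <- means[means$sex == model$sex, , drop = FALSE]
  rows <- rows[order(rows$age_lo), ]
  if (!identical(obs$age_lo, rows$age_lo))
    stop("registry and means tables must share the same age groups")
  mid <- obs$age_mid
  lp <- vapply(seq_along(mid), function(i) {
    p <- .group_profile(model$sex, mid[i], rows[i, ])
    linear_predictor(p, model, mid[i])
  }, numeric(1))
  h <- -log1p(-obs$q) * exp(-lp)
  if (any(h <= 0))
    stop("non-positive implied baseline hazard; registry risks must be > 0")
  logh <- log(h)
  nodes <- floor(mid)           # ages at which one_year_risk looks S0 up
  sf <- stats::splinefun(nodes, logh, method = "monoH.FC")
  ages <- 35:100
  out <- sf(ages)
  lo <- nodes[1]; hi <- nodes[length(nodes)]
  slope_lo <- (logh[2] - logh[1]) / (nodes[2] - nodes[1])
  k <- length(nodes)
  slope_hi <- (logh[k] - logh[k - 1]) / (nodes[k] - nodes[k - 1])
  out[ages < lo] <- logh[1] + slope_lo * (ages[ages < lo] - lo)
  out[ages > hi] <- logh[k] + slope_hi * (ages[ages > hi] - hi)
  s0 <- exp(-exp(out))
  names(s0) <- as.character(ages)
  s0
}

#' Set all four baselines of a bundle from low-region incidence
#'
#' @param bundle A \code{\link{model_bundle}}.
#' @param registry,means Tables restricted to (or containing) the low-risk
#'   region, with both sexes.
#' @return The bundle with every endpoint model's \code{baseline_surv}
#'   replaced by the registry-derived baseline.
#' @export
set_baseline_from_incidence <- function(bundle, registry, means) {
  for (ep in .endpoints) for (sx in .sexes) {
    m <- get_model(bundle, ep, sx)
    s0 <- baseline_from_incidence(registry, means, m)
    m$baseline_surv <- s0
    bundle$models[[paste(ep, sx, sep = ".")]] <- m
  }
  bundle
}

#' Recalibrate a bundle to every region present in registry tables
#'
#' For each region, sex and endpoint, fits \code{\link{fit_recalibration}}
#' of the registry's observed annual risks on the bundle's predicted group
#' risks at that region's mean covariates, and stores the resulting scales
#' in the bundle.
#'
#' @param bundle An un-recalibrated \code{\link{model_bundle}} whose baseline
#'   is already set (typically from the low-risk region via
#'   \code{\link{set_baseline_from_incidence}}).
#' @param registry,means Tables covering one or more regions and both sexes.
#' @return The bundle with its \code{recalibration} data frame filled.
#' @export
recalibrate_bundle <- function(bundle, registry, means) {
  regions <- unique(registry$region)
  out <- list()
  for (r in regions) for (sx in .sexes) for (ep in .endpoints) {
    reg <- registry[registry$region == r & registry$sex == sx, , drop = FALSE]
    mns <- means[means$region == r, , drop = FALSE]
    obs <- observed_annual_risks(reg, ep)
    prd <- predicted_group_risks(bundle, mns, ep, sx)
    sc <- fit_recalibration(obs, prd, region = r, sex = sx, endpoint = ep)
    out[[length(out) + 1L]] <- data.frame(
      region = r, sex = sx, endpoint = ep,
      scale1 = sc$scale1, scale2 = sc$scale2)
  }
  bundle$recalibration <- do.call(rbind, out)
  bundle$meta$regions <- regions
  bundle
}
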