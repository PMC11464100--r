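# Competing-risk life table: annual conditional CVD and non-CVD-death risks
# combined in 1-year windows across all future life years up to the model
# ceiling of age 100.

#' Assemble a life table from annual hazard schedules
#'
#' Low-level constructor used by \code{\link{build_life_table}} and directly
#' useful for testing against closed forms: given conditional 1-year risks of
#' a CVD event and of non-CVD death for every attained age from
#' \code{start_age} to 100, builds the joint bookkeeping
#' \deqn{S(a+1) = S(a)\,(1-q_{cvd}(a))\,(1-q_{death}(a)),}
#' with unconditional window risks \eqn{S(a) q_{cvd}(a)} and
#' \eqn{S(a)(1-q_{cvd}(a))\,q_{death}(a)} (a CVD event within a window
#' precludes the competing death in the same window), and their running sums.
#' Mass is conserved exactly: at every age
#' \eqn{S + \mathrm{cum\_cvd} + \mathrm{cum\_death} = 1}.
#'
#' @param start_age First (integer) attained age.
#' @param q_cvd,q_death Numeric vectors of conditional 1-year risks, one per
#'   age \code{start_age..100} (recycled if scalar).
#' @return A data frame of class \code{life_table} with columns \code{age,
#'   q_cvd, q_death, surv_in, uncond_cvd, cum_cvd, uncond_death, cum_death};
#'   \code{surv_in} is the probability of being alive and CVD-free at the
#'   start of each window.
#' @export
life_table_from_hazards <- function(start_age, q_cvd, q_death) {
  start_age <- as.integer(start_age)
  if (start_age < 35 || start_age > 100)
    stop("start_age must lie in 35..100")
  ages <- start_age:100
  n <- length(ages)
  q_cvd <- rep_len(as.numeric(q_cvd), n)
  q_death <- rep_len(as.numeric(q_death), n)
  if (any(q_cvd < 0 | q_cvd > 1 | q_death < 0 | q_death > 1))
    stop("annual risks must lie in [0, 1]")
  surv_in <- cumprod(c(1, (1 - q_cvd[-n]) * (1 - q_death[-n])))
  uncond_cvd <- surv_in * q_cvd
  uncond_death <- surv_in * (1 - q_cvd) * q_death
  out <- data.frame(age = ages, q_cvd = q_cvd, q_death = q_death,
                    surv_in = surv_in,
                    uncond_cvd = uncond_cvd,
                    cum_cvd = cumsum(uncond_cvd),
                    uncond_death = uncond_death,
                    cum_death = cumsum(uncond_death))
  class(out) <- c("life_table", "data.frame")
  attr(out, "start_age") <- start_age
  out
}

#' Build the competing-risk life table for one individual
#'
#' Evaluates the bundle's sex-specific CVD-event and non-CVD-death models
#' repetitively in 1-year windows from the individual's (floored) current age
#' to age 100, optionally rescaling each annual risk with the bundle's
#' recalibration scales for a risk region, and assembles the competing-risk
#' bookkeeping via \code{\link{life_table_from_hazards}}.
#'
#' @param profile A \code{\link{risk_profile}}.
#' @param bundle A \code{\link{model_bundle}}.
#' @param region Risk-region label; \code{NULL} uses the un-recalibrated
#'   risks. Requesting a region requires the bundle to carry scales for it.
#' @param clinical In clinical mode (default) diabetic individuals are
#'   refused: the diabetes coefficient exists only so that recalibration can
#'   use population statistics that include diabetics, and the model is not
#'   intended for clinical use in diabetes.
#' @param age_convention Passed to \code{\link{linear_predictor}}.
#' @return A \code{life_table}.
#' @examples
#' b <- default_bundle()
#' p <- risk_profile("female", 50, smoking = 1, sbp = 140,
#'                   total_chol = 5.5, hdl_chol = 1.3)
#' lt <- build_life_table(p, b, region = "moderate")
#' ten_year_risk(lt); lifetime_risk(lt); cvd_free_life_expectancy(lt)
#' @export
build_life_table <- function(profile, bundle, region = NULL, clinical = TRUE,
                             age_convention = c("attained", "entry")) {
  age_convention <- match.arg(age_convention)
  stopifnot(inherits(profile, "cvd_profile"), inherits(bundle, "model_bundle"))
  if (clinical && profile$diabetes >= 1)
    stop("diabetic individuals are outside the clinical scope of the model; ",
         "use clinical = FALSE only for population-level computations")
  sc_cvd <- sc_death <- NULL
  if (!is.null(region)) {
    sc_cvd <- get_scales(bundle, region, "cvd_event", profile$sex)
    sc_death <- get_scales(bundle, region, "noncvd_death", profile$sex)
  }
  ages <- floor(profile$age):100
  m_cvd <- get_model(bundle, "cvd_event", profile$sex)
  m_death <- get_model(bundle, "noncvd_death", profile$sex)
  q_cvd <- one_year_risk(profile, m_cvd, ages, sc_cvd, age_convention)
  q_death <- one_year_risk(profile, m_death, ages, sc_death, age_convention)
  lt <- life_table_from_hazards(ages[1], q_cvd, q_death)
  attr(lt, "profile") <- profile
  attr(lt, "region") <- if (is.null(region)) NA_character_ else region
  lt
}

#' Lifetime CVD risk up to a horizon age
#'
#' Cumulative unconditional probability of a first CVD event before the
#' horizon (default age 80): the sum of the life table's yearly
#' unconditional CVD risks over windows starting below the horizon. Defined
#' as 0 (with a warning) when the table starts at or beyond the horizon.
#'
#' @param table A \code{life_table}.
#' @param horizon_age Horizon in years, at most 100.
#' @export
lifetime_risk <- function(table, horizon_age = 80) {
  stopifnot(inherits(table, "life_table"), horizon_age <= 100)
  if (attr(table, "start_age") >= horizon_age) {
    warning("life table starts at or beyond the horizon age; lifetime risk ",
            "is defined as 0")
    return(0)
  }
  sum(table$uncond_cvd[table$age < horizon_age])
}

#' 10-year CVD risk
#'
#' Sum of the unconditional CVD risks over the first ten 1-year windows.
#'
#' @param table A \code{life_table} with at least ten rows.
#' @export
ten_year_risk <- function(table) {
  stopifnot(inherits(table, "life_table"))
  if (nrow(table) < 10L)
    stop("life table has fewer than 10 one-year windows")
  sum(table$uncond_cvd[1:10])
}

#' CVD-free life expectancy (median event-free survival age)
#'
#' The age at which the probability of being alive and CVD-event-free drops
#' below 0.5, read from the life table. Within the crossing year the age is
#' interpolated assuming a constant hazard (log-linear survival), matching
#' the rate-to-probability convention used throughout; if survival at age
#' 100 is still at least 0.5 the value is censored at the model ceiling and
#' returned as 100 with attribute \code{censored = TRUE}.
#'
#' @param table A \code{life_table} built to age 100.
#' @return Age in years, with attribute \code{censored}.
#' @export
cvd_free_life_expectancy <- function(table) {
  stopifnot(inherits(table, "life_table"))
  if (table$age[nrow(table)] != 100L)
    stop("life table must extend to age 100")
  s <- table$surv_in
  idx <- which(s < 0.5)
  if (!length(idx))
    return(structure(100, censored = TRUE))
  i <- idx[1]                       # first window start with surv < 0.5
  a_prev <- table$age[i - 1]; s_prev <- s[i - 1]; s_cur <- s[i]
  A <- a_prev + log(0.5 / s_prev) / log(s_cur / s_prev)
  structure(A, censored = FALSE)
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> ages %d-100 (%d one-year windows)",
              attr(x, "start_age"), nrow(x)))
  reg <- attr(x, "region")
  if (!is.null(reg) && !is.na(reg)) cat(", region:", reg)
  cat("\n")
  le <- cvd_free_life_expectancy(x)
  cat(sprintf("  10-y CVD risk %.1f%% | lifetime risk to 80 %.1f%% | CVD-free LE %.1f y%s\n",
              100 * ten_year_risk(x),
              100 * suppressWarnings(lifetime_risk(x)),
              as.numeric(le),
              if (isTRUE(attr(le, "censored"))) " (censored at 100)" else ""))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ... ", nrow(x) - 5, " more rows\n", sep = "")
  invisible(x)
}

#' Export a life table as tidy CSV
#'
#' One row per attained age with all bookkeeping columns, for plotting and
#' audit.
#'
#' @param table A \code{life_table}.
#' @param path Output file path.
#' @export
write_life_table <- function(table, path) {
  stopifnot(inherits(table, "life_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
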