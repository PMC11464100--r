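# Model-bundle JSON round trip.
#
# Schema: top level {meta, models, recalibration}; each model carries
# endpoint, sex, beta_main, gamma_age (log HRs per stated unit), centering
# constants and baseline_surv keyed by integer attained age "35".."100";
# recalibration rows carry region/sex/endpoint and the cloglog-scale
# intercept (scale1) and slope (scale2).

#' Write a model bundle to JSON
#'
#' Full double precision is retained so that
#' \code{load_model_bundle(save_model_bundle(b))} reproduces every field
#' bit-exactly.
#'
#' @param bundle A \code{\link{model_bundle}}.
#' @param path Output path.
#' @export
save_model_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  models <- lapply(bundle$models, function(m) {
    list(endpoint = m$endpoint, sex = m$sex,
         beta_main = as.list(m$beta_main),
         gamma_age = as.list(m$gamma_age),
         centering = as.list(m$centering[c("age", "sbp", "total_chol",
                                           "hdl_chol")]),
         baseline_surv = as.list(m$baseline_surv))
  })
  recal <- if (is.null(bundle$recalibration)) list() else
    lapply(seq_len(nrow(bundle$recalibration)), function(i)
      as.list(bundle$recalibration[i, ]))
  jsonlite::write_json(
    list(meta = bundle$meta, models = unname(models), recalibration = recal),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

.parse_named_numeric <- function(x, what, allowed = NULL) {
  v <- vapply(x, function(e) {
    if (!is.numeric(e) || length(e) != 1L)
      stop("field '", what, "' must contain scalar numbers")
    as.numeric(e)
  }, numeric(1))
  if (!is.null(allowed)) {
    bad <- setdiff(names(v), allowed)
    if (length(bad))
      stop("unknown predictor name(s) in '", what, "': ",
           paste(bad, collapse = ", "))
  }
  v
}

#' Read a model bundle from JSON
#'
#' Validates the schema (all four endpoint/sex models present, predictor
#' names known, centering constants equal to the model's published
#' centering, baseline survival covering ages 35-100 with values in (0,1\])
#' and reports the offending field on violation.
#'
#' @param path Path to a bundle JSON written by
#'   \code{\link{save_model_bundle}} (or conforming to its schema).
#' @return A \code{\link{model_bundle}}.
#' @export
load_model_bundle <- function(path) {
  raw <- jsonlite::read_json(path)
  if (is.null(raw$models))
    stop("bundle JSON has no 'models' field")
  models <- lapply(raw$models, function(m) {
    for (f in c("endpoint", "sex", "beta_main", "baseline_surv"))
      if (is.null(m[[f]]))
        stop("model entry is missing field '", f, "'")
    beta <- .parse_named_numeric(m$beta_main, "beta_main", .predictors)
    gamma <- .parse_named_numeric(m$gamma_age, "gamma_age", .predictors)
    cent <- .parse_named_numeric(m$centering, "centering")
    ref <- .centering[c("age", "sbp", "total_chol", "hdl_chol")]
    if (!isTRUE(all.equal(cent[names(ref)], ref, tolerance = 0)))
      stop("centering constants do not match the model definition ",
           "(age 60, SBP 120, TC 6, HDL 1.3)")
    s0 <- .parse_named_numeric(m$baseline_surv, "baseline_surv")
    miss <- setdiff(as.character(35:100), names(s0))
    if (length(miss))
      stop("baseline_surv is missing ages: ",
           paste(utils::head(miss, 5), collapse = ", "))
    endpoint_model(m$endpoint, m$sex, beta, gamma,
                   s0[as.character(35:100)])
  })
  recal <- NULL
  if (length(raw$recalibration)) {
    recal <- do.call(rbind, lapply(raw$recalibration, function(r) {
      for (f in c("region", "sex", "endpoint", "scale1", "scale2"))
        if (is.null(r[[f]]))
          stop("recalibration entry is missing field '", f, "'")
      data.frame(region = r$region, sex = r$sex, endpoint = r$endpoint,
                 scale1 = as.numeric(r$scale1),
                 scale2 = as.numeric(r$scale2))
    }))
  }
  meta <- lapply(raw$meta, function(x) if (is.list(x)) unlist(x) else x)
  model_bundle(models, recalibration = recal, meta = meta)
}
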