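#' Risk-factor profile for one individual
#'
#' Bundles the predictor values of the lifetime CVD risk model at the
#' individual's current age: sex, current smoking, systolic blood pressure,
#' total and HDL cholesterol, and diabetes status. Prediction entry is
#' restricted to ages 35-90 so that the life table (which runs to age 100)
#' always contains at least ten 1-year windows.
#'
#' Smoking and diabetes are accepted as fractional values in \[0, 1\] so that
#' group prevalences can be plugged in during recalibration; for individual
#' prediction they are ordinarily 0 or 1.
#'
#' @param sex "male" or "female".
#' @param age Current age in years (entry age for prediction), 35-90.
#' @param smoking Current smoking (vs. never/former), in \[0, 1\].
#' @param sbp Systolic blood pressure, mmHg.
#' @param total_chol Total cholesterol, mmol/L.
#' @param hdl_chol HDL cholesterol, mmol/L; must be below \code{total_chol}.
#' @param diabetes History of diabetes mellitus, in \[0, 1\]. The diabetes
#'   coefficient exists for recalibration against population statistics that
#'   include diabetics; clinical prediction refuses diabetic individuals
#'   (see \code{\link{build_life_table}}).
#' @return An object of class \code{cvd_profile}.
#' @examples
#' risk_profile("male", age = 50, smoking = 1, sbp = 140,
#'              total_chol = 5.5, hdl_chol = 1.3)
#' @export
risk_profile <- function(sex, age, smoking = 0, sbp = 120,
                         total_chol = 6, hdl_chol = 1.3, diabetes = 0) {
  sex <- match.arg(sex, c("male", "female"))
  stopifnot(is.numeric(age), length(age) == 1L, is.finite(age))
  if (age < 35 || age > 90)
    stop("entry age must be between 35 and 90 years (got ", age, ")")
  if (!is.finite(sbp) || sbp <= 0) stop("sbp must be positive")
  if (!is.finite(total_chol) || !is.finite(hdl_chol) ||
      hdl_chol <= 0 || total_chol <= hdl_chol)
    stop("cholesterol values must satisfy total_chol > hdl_chol > 0")
  if (smoking < 0 || smoking > 1) stop("smoking must lie in [0, 1]")
  if (diabetes < 0 || diabetes > 1) stop("diabetes must lie in [0, 1]")
  structure(
    list(sex = sex, age = as.numeric(age), smoking = as.numeric(smoking),
         sbp = as.numeric(sbp), total_chol = as.numeric(total_chol),
         hdl_chol = as.numeric(hdl_chol), diabetes = as.numeric(diabetes)),
    class = "cvd_profile")
}

#' @export
print.cvd_profile <- function(x, ...) {
  cat(sprintf(
    "<cvd_profile> %s, age %.1f | smoking %.2g | SBP %g mmHg | TC %g, HDL %g mmol/L | diabetes %.2g\n",
    x$sex, x$age, x$smoking, x$sbp, x$total_chol, x$hdl_chol, x$diabetes))
  invisible(x)
}
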