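# Linear predictor, 1-year risk and bundle serialisation.

test_that("linear predictor reproduces the published hazard ratios", {
  b <- flat_bundle()
  m_cvd_m <- get_model(b, "cvd_event", "male")
  m_cvd_f <- get_model(b, "cvd_event", "female")

  # male smoker at 60, everything else at centering: log 1.90
  p <- risk_profile("male", 60, smoking = 1)
  expect_equal(linear_predictor(p, m_cvd_m, 60), log(1.90))

  # female at 60 with SBP 140: one 20-mmHg unit, log 1.40
  p <- risk_profile("female", 60, sbp = 140)
  expect_equal(linear_predictor(p, m_cvd_f, 60), log(1.40))

  # reference individual: exactly zero for any sex
  expect_equal(linear_predictor(reference_profile("male"), m_cvd_m, 60), 0)
  expect_equal(linear_predictor(reference_profile("female"), m_cvd_f, 60), 0)

  # male smoker at attained age 70: the smoking contribution relative to
  # the reference individual is the main effect plus two 5-year
  # interaction steps, log(1.90) + 2 log(0.94); the age main effect itself
  # contributes 2 log(1.10)
  p <- risk_profile("male", 70, smoking = 1)
  ref70 <- linear_predictor(reference_profile("male"), m_cvd_m, 70)
  expect_equal(ref70, 2 * log(1.10))
  expect_equal(linear_predictor(p, m_cvd_m, 70) - ref70,
               log(1.90) + 2 * log(0.94))
})

test_that("smoking HR as a function of attained age follows 1.90 * 0.94^((a-60)/5)", {
  b <- flat_bundle()
  m <- get_model(b, "cvd_event", "male")
  smoker <- risk_profile("male", 60, smoking = 1)
  ref <- reference_profile("male")
  for (a in c(35, 47.5, 60, 72, 100)) {
    hr <- exp(linear_predictor(smoker, m, a) - linear_predictor(ref, m, a))
    expect_equal(hr, 1.90 * 0.94 ^ ((a - 60) / 5), tolerance = 1e-12)
  }
})

test_that("linear predictor is exactly linear in each continuous predictor", {
  b <- flat_bundle()
  m <- get_model(b, "cvd_event", "female")
  base <- linear_predictor(reference_profile("female"), m, 65)
  for (delta in list(c(sbp = 20), c(total_chol = 1), c(hdl_chol = 0.5))) {
    nm <- names(delta)
    args1 <- args2 <- list(sex = "female", age = 60, sbp = 120,
                           total_chol = 6, hdl_chol = 1.3)
    args1[[nm]] <- args1[[nm]] + delta
    args2[[nm]] <- args2[[nm]] + 2 * delta
    lp1 <- linear_predictor(do.call(risk_profile, args1), m, 65) - base
    lp2 <- linear_predictor(do.call(risk_profile, args2), m, 65) - base
    expect_equal(lp2, 2 * lp1, tolerance = 1e-12)
  }
})

test_that("entry-age convention freezes the age terms at entry", {
  b <- flat_bundle()
  m <- get_model(b, "cvd_event", "male")
  p <- risk_profile("male", 50, smoking = 1)
  lp_attained <- linear_predictor(p, m, 70)
  lp_entry <- linear_predictor(p, m, 70, age_convention = "entry")
  expect_equal(lp_entry, linear_predictor(p, m, 50))
  expect_false(isTRUE(all.equal(lp_attained, lp_entry)))
})

test_that("linear predictor enforces its contract", {
  b <- flat_bundle()
  m <- get_model(b, "cvd_event", "male")
  expect_error(linear_predictor(risk_profile("female", 60), m, 60),
               "sex")
  expect_error(linear_predictor(risk_profile("male", 60), m, 101),
               "35, 100")
  expect_error(risk_profile("male", 34), "35 and 90")
  expect_error(risk_profile("male", 91), "35 and 90")
  expect_error(risk_profile("male", 60, total_chol = 1, hdl_chol = 1.3),
               "total_chol > hdl_chol")
})

test_that("one-year risk follows the baseline-power closed form", {
  # q = 1 - S0^exp(LP) checked against direct computation over a grid
  for (s0 in c(0.9, 0.99, 0.999)) {
    # single-predictor model with unit log HR per 20 mmHg, so that
    # LP = (sbp - 120)/20 exactly
    m <- endpoint_model("cvd_event", "male", c(sbp = 1), numeric(0),
                        rep(s0, 66))
    expect_equal(one_year_risk(reference_profile("male"), m, 60), 1 - s0)
    for (lp in seq(-2, 2, by = 0.5)) {
      p <- risk_profile("male", 60, sbp = 120 + 20 * lp)
      expect_equal(one_year_risk(p, m, 60),
                   1 - exp(exp(lp) * log(s0)), tolerance = 1e-12)
    }
  }
  # S0 = 1: zero hazard regardless of LP
  b1 <- flat_bundle(1.0)
  m1 <- get_model(b1, "cvd_event", "male")
  expect_equal(one_year_risk(risk_profile("male", 60, smoking = 1,
                                          sbp = 180), m1, 60), 0)
})

test_that("one-year risk: S0 = 0.99 with doubled hazard gives 1 - 0.99^2", {
  b <- flat_bundle(0.99)
  m <- get_model(b, "cvd_event", "male")
  sbp <- 120 + 20 * log(2) / log(1.34)   # LP = log 2 at age 60
  p <- risk_profile("male", 60, sbp = sbp)
  expect_equal(one_year_risk(p, m, 60), 1 - 0.99^2, tolerance = 1e-12)
})

test_that("fractional binary predictors scale the log HR proportionally", {
  b <- flat_bundle()
  m <- get_model(b, "cvd_event", "female")
  p_half <- risk_profile("female", 60, smoking = 0.5)
  expect_equal(linear_predictor(p_half, m, 60), 0.5 * log(2.27))
})

test_that("model bundle JSON round-trips bit-exactly", {
  b <- default_bundle()
  path <- withr::local_tempfile(fileext = ".json")
  save_model_bundle(b, path)
  b2 <- load_model_bundle(path)
  for (k in names(b$models)) {
    expect_identical(b2$models[[k]]$beta_main, b$models[[k]]$beta_main)
    expect_identical(b2$models[[k]]$gamma_age, b$models[[k]]$gamma_age)
    expect_identical(b2$models[[k]]$baseline_surv,
                     b$models[[k]]$baseline_surv)
  }
  expect_equal(b2$recalibration$scale1, b$recalibration$scale1)
  expect_equal(b2$recalibration$scale2, b$recalibration$scale2)
  # and predictions agree exactly
  p <- risk_profile("female", 45, smoking = 1, sbp = 150,
                    total_chol = 6.5, hdl_chol = 1.1)
  expect_identical(build_life_table(p, b2, "high")$cum_cvd,
                   build_life_table(p, b, "high")$cum_cvd)
})

test_that("bundle loading reports schema violations by field", {
  b <- default_bundle()
  path <- withr::local_tempfile(fileext = ".json")
  save_model_bundle(b, path)
  raw <- jsonlite::read_json(path)

  mutate_and_expect <- function(raw, msg) {
    p2 <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(raw, p2, auto_unbox = TRUE, digits = NA)
    expect_error(load_model_bundle(p2), msg)
  }

  # missing one endpoint/sex combination
  broken <- raw; broken$models <- broken$models[-1]
  mutate_and_expect(broken, "missing endpoint/sex")

  # unknown predictor name is reported by name
  broken <- raw
  broken$models[[1]]$beta_main$ldl_direct <- 0.1
  mutate_and_expect(broken, "ldl_direct")

  # tampered centering constants
  broken <- raw
  broken$models[[1]]$centering$sbp <- 130
  mutate_and_expect(broken, "centering")

  # truncated baseline
  broken <- raw
  broken$models[[1]]$baseline_surv[["77"]] <- NULL
  mutate_and_expect(broken, "baseline_surv is missing ages")
})
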