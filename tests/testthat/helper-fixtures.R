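# Shared fixtures, all built in code.

# bundle with the packaged coefficient sets and a flat baseline survival,
# for closed-form checks where S0 must be a known constant
flat_bundle <- function(s0 = 0.99) {
  pub <- published_coefficients()
  ncv <- synthetic_noncvd_coefficients()
  flat <- rep(s0, 66)
  model_bundle(list(
    endpoint_model("cvd_event", "male", pub$male$beta_main,
                   pub$male$gamma_age, flat),
    endpoint_model("cvd_event", "female", pub$female$beta_main,
                   pub$female$gamma_age, flat),
    endpoint_model("noncvd_death", "male", ncv$male$beta_main,
                   ncv$male$gamma_age, flat),
    endpoint_model("noncvd_death", "female", ncv$female$beta_main,
                   ncv$female$gamma_age, flat)))
}

reference_profile <- function(sex = "male", age = 60)
  risk_profile(sex, age, smoking = 0, sbp = 120, total_chol = 6,
               hdl_chol = 1.3, diabetes = 0)

# discrete-time Monte-Carlo oracle for the life table: simulates n subjects
# through the same yearly hazard schedule (CVD takes precedence within a
# year) and returns empirical cumulative CVD incidence and survival per age
simulate_life_table <- function(start_age, q_cvd, q_death, n, seed) {
  set.seed(seed)
  ages <- start_age:100
  k <- length(ages)
  q_cvd <- rep_len(q_cvd, k)
  q_death <- rep_len(q_death, k)
  alive <- rep(TRUE, n)
  cum_cvd <- cum_death <- surv <- numeric(k)
  for (i in seq_len(k)) {
    surv[i] <- mean(alive)
    idx <- which(alive)
    if (length(idx)) {
      ev_cvd <- stats::runif(length(idx)) < q_cvd[i]
      ev_death <- !ev_cvd & stats::runif(length(idx)) < q_death[i]
      alive[idx[ev_cvd | ev_death]] <- FALSE
      cum_cvd[i] <- sum(ev_cvd)
      cum_death[i] <- sum(ev_death)
    }
  }
  data.frame(age = ages, surv_in = surv,
             cum_cvd = cumsum(cum_cvd) / n,
             cum_death = cumsum(cum_death) / n)
}
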