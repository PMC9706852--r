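surv_cohort <- function(n = 500, loghr = 0, seed = 1, cens_rate = 0.05,
                        base_rate = 0.08) {
  set.seed(seed)
  x <- stats::rnorm(n)
  t_ev <- stats::rexp(n, base_rate * exp(loghr * x))
  t_c <- stats::rexp(n, cens_rate)
  data.frame(id = sprintf("S%04d", seq_len(n)),
             time_years = pmin(t_ev, t_c),
             status = as.integer(t_ev <= t_c),
             cause = ifelse(t_ev <= t_c, "other", NA_character_),
             signature = x)
}

test_that("the Cox partial likelihood matches risk-set enumeration", {
  # tie-free 3-subject data, checked at the fitted coefficient
  co <- data.frame(id = c("a", "b", "c"),
                   time_years = c(1, 2, 3),
                   status = c(1L, 1L, 0L),
                   x = c(0.5, -0.2, 1.1))
  fit <- survival::coxph(survival::Surv(time_years, status) ~ x, data = co,
                         ties = "efron")
  b <- unname(stats::coef(fit))
  expect_equal(fit$loglik[2],
               oracle_cox_partial_loglik(co$time_years, co$status, co$x, b),
               tolerance = 1e-10)
  # and at an arbitrary coefficient via a one-iteration evaluation
  for (beta0 in c(-0.7, 0, 0.4)) {
    f0 <- survival::coxph(survival::Surv(time_years, status) ~ x, data = co,
                          init = beta0,
                          control = survival::coxph.control(iter.max = 0))
    expect_equal(f0$loglik[2],
                 oracle_cox_partial_loglik(co$time_years, co$status, co$x,
                                           beta0),
                 tolerance = 1e-10)
  }
})

test_that("all-cause Cox estimates recover a known hazard ratio", {
  est <- numeric(25)
  for (s in 1:25) {
    co <- surv_cohort(n = 800, loghr = log(2), seed = 40 + s)
    res <- cox_all_cause(co, co$signature, covariates = character(0))
    est[s] <- res$log_hr
  }
  expect_lt(abs(mean(est) - log(2)), 0.05)
})

test_that("hazard ratios are invariant to the time unit", {
  co <- surv_cohort(n = 400, loghr = log(1.5), seed = 50)
  r_years <- cox_all_cause(co, co$signature, covariates = character(0))
  co_days <- co
  co_days$time_years <- co$time_years * 365.25
  r_days <- cox_all_cause(co_days, co_days$signature,
                          covariates = character(0))
  expect_equal(r_years$hr, r_days$hr, tolerance = 1e-9)
})

test_that("degenerate survival inputs are rejected", {
  co <- surv_cohort(n = 100, seed = 51)
  co$status <- 0L
  co$cause <- NA_character_
  expect_error(cox_all_cause(co, co$signature, covariates = character(0)),
               "events")
  co2 <- surv_cohort(n = 100, seed = 52)
  co2$time_years[1] <- 0
  expect_error(cox_all_cause(co2, co2$signature, covariates = character(0)),
               "non-positive")
})

test_that("constant covariates are dropped before fitting and testing", {
  co <- surv_cohort(n = 300, loghr = log(2), seed = 53)
  co$bmi <- 25
  expect_message(
    res <- cox_all_cause(co, co$signature, covariates = "bmi"),
    "constant")
  expect_false("bmi" %in% res$ph_test$term)
})

test_that("the Schoenfeld test flags a reversing hazard and not a constant one", {
  # hazard ratio flips sign at the median follow-up: strong PH violation
  set.seed(54)
  n <- 1000
  x <- stats::rnorm(n)
  u <- stats::runif(n)
  rate1 <- 0.25 * exp(1 * x)
  t1 <- stats::rexp(n, rate1)
  t_flip <- stats::quantile(t1, 0.5)
  flip <- t1 > t_flip
  t2 <- t_flip + stats::rexp(n, 0.25 * exp(-1 * x))
  time <- ifelse(flip, t2, t1)
  co <- data.frame(time_years = time, status = 1L)
  fit <- survival::coxph(survival::Surv(time_years, status) ~ x, data = co)
  p <- schoenfeld_test(fit)
  expect_lt(p$p[p$term == "x"], 0.01)
})

test_that("spline fallback prefers the smooth only under curvature", {
  # strongly quadratic log hazard
  set.seed(55)
  n <- 1000
  x <- stats::rnorm(n)
  t_ev <- stats::rexp(n, 0.08 * exp(0.8 * x^2))
  co <- data.frame(time_years = pmin(t_ev, 15),
                   status = as.integer(t_ev <= 15))
  res <- spline_fallback(co, x, covariates = character(0))
  expect_true(res$spline_fallback_used)
  expect_lt(res$nonlinearity_p, 0.05)
  # spline log-likelihood dominates its nested linear fit
  expect_gte(res$spline_loglik, res$linear_loglik)

  # linear truth: smooth not preferred
  co2 <- surv_cohort(n = 800, loghr = log(1.5), seed = 56)
  res2 <- spline_fallback(co2, co2$signature, covariates = character(0))
  expect_gt(res2$nonlinearity_p, 0.01)
  expect_error(spline_fallback(co2, co2$signature,
                               covariates = character(0), df = 1), "df")
})

test_that("cause-specific fits equal all-cause fits on recoded data", {
  sim <- generate_cohort(sim_config(n_samples = 1500, seed = 57))
  z <- unname(sim$ground_truth$tobacco_burden)
  cr <- suppressWarnings(competing_risks(sim$cohort, z,
                                         covariates = c("age", "sex")))
  for (cs in names(cr)) {
    recoded <- sim$cohort
    recoded$status <- as.integer(sim$cohort$status == 1 &
                                   !is.na(sim$cohort$cause) &
                                   sim$cohort$cause == cs)
    direct <- cox_all_cause(recoded, z, covariates = c("age", "sex"),
                            min_events = 5)
    expect_identical(cr[[cs]]$log_hr, direct$log_hr)
    expect_identical(cr[[cs]]$ci95, direct$ci95)
  }
  # event partition: cause-specific counts sum to total deaths
  counts <- vapply(c("lung_cancer", "cvd", "other"), function(cs)
    sum(sim$cohort$status == 1 & sim$cohort$cause == cs, na.rm = TRUE),
    numeric(1))
  expect_equal(sum(counts), sum(sim$cohort$status))
})

test_that("a single observed cause reduces to the all-cause model", {
  co <- surv_cohort(n = 400, loghr = log(2), seed = 58)
  cr <- suppressWarnings(
    competing_risks(co, co$signature, covariates = character(0),
                    causes = "other"))
  all_cause <- cox_all_cause(co, co$signature, covariates = character(0))
  expect_identical(cr$other$log_hr, all_cause$log_hr)
  # a cause with no events is skipped with a warning
  expect_warning(
    out <- competing_risks(co, co$signature, covariates = character(0),
                           causes = "lung_cancer"),
    "skipped")
  expect_length(out, 0)
})

test_that("survival records read from CSV with cause-code mapping", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,time_years,status,cause_code",
               "S1,5.2,1,C34.1", "S2,8.0,0,", "S3,2.1,1,I21",
               "S4,6.3,1,J44"), path)
  df <- read_survival_records(path)
  expect_identical(df$cause, c("lung_cancer", NA, "cvd", "other"))
  writeLines(c("sample_id,time_years,status", "S1,-1,1"), path)
  expect_error(read_survival_records(path), "non-positive")
})
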