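test_that("noise-free exactly linear data are recovered to machine precision", {
  set.seed(41)
  n <- 16
  co <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:n), each = 3),
    visit_week = rep(c(0, 12, 24), n),
    visap = round(runif(3 * n, 30, 95)),
    age = rep(sample(18:35, n, TRUE), each = 3),
    sex = rep(rbinom(n, 1, 0.5), each = 3),
    bmi = rep(round(runif(n, 20, 27), 1), each = 3),
    csas = rep(round(runif(n, 50, 100)), each = 3),
    symptom_duration = rep(round(runif(n, 10, 200)), each = 3))
  co$t2_degenerative <- 20 - 0.05 * co$visap + 0.1 * co$age - 0.02 * co$bmi
  res <- suppressWarnings(fit_cross_sectional(co, "degenerative"))  # perfect fit
  est <- res$coefficients
  expect_equal(est$estimate[est$term == "visap"], -0.05, tolerance = 1e-10)
  expect_equal(est$estimate[est$term == "age"], 0.1, tolerance = 1e-10)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
})

test_that("a duplicated covariate raises a collinearity error", {
  co <- generate_cohort(cohort_spec(n_subjects = 30, seed = 4))
  co$csas <- co$bmi
  expect_error(fit_cross_sectional(co, "degenerative"), "collinear")
})

test_that("the pooled VISA-P slope is recovered at its generator truth", {
  co <- generate_cohort(cohort_spec(n_subjects = 500, missing_rate = 0, seed = 9))
  res <- fit_cross_sectional(co, "degenerative", robust = TRUE)
  v <- res$coefficients[res$coefficients$term == "visap", ]
  expect_true(v$ci_low <= -0.046 && -0.046 <= v$ci_high)
  expect_lt(v$p, 0.05)
})

test_that("insufficient data for the cross-sectional model is an error", {
  co <- generate_cohort(cohort_spec(n_subjects = 3, seed = 1))
  expect_error(fit_cross_sectional(co[1:6, ], "degenerative"), "insufficient")
})

test_that("baseline prediction reports R-squared 1 for an exact linear outcome", {
  co <- generate_cohort(cohort_spec(n_subjects = 40, missing_rate = 0, seed = 6))
  base <- co$visit_week == 0
  lin <- 10 + 2 * co$t2_degenerative[base]
  co$visap[co$visit_week == 24] <- lin
  res <- suppressWarnings(fit_baseline_prediction(co, "degenerative"))
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
  expect_lt(res$p_t2, 1e-10)
})

test_that("baseline prediction rejects degenerate inputs", {
  co <- generate_cohort(cohort_spec(n_subjects = 5, seed = 1))
  expect_error(fit_baseline_prediction(co, "degenerative"), "insufficient")
  co2 <- generate_cohort(cohort_spec(n_subjects = 30, seed = 1))
  co2$visap[co2$visit_week == 24] <- NA
  expect_error(fit_baseline_prediction(co2, "degenerative"), "final-visit")
})

test_that("GEE visit contrast covers the generating 24-week change", {
  co <- generate_cohort(cohort_spec(n_subjects = 60, seed = 1001))
  res <- fit_gee_longitudinal(co, "degenerative")
  ci <- res$contrasts[res$contrasts$contrast == "0_vs_24", ]
  expect_true(ci$ci_low <= -1.3 && -1.3 <= ci$ci_high)
})

test_that("the mixed change model recovers a known T2*-to-VISA-P coupling", {
  # construct the coupling in the modelled direction: VISA-P responds to
  # the subject's T2* trajectory with a known coefficient
  set.seed(19)
  n <- 200
  gamma <- -1.2                     # VISA-P points per msec of T2*
  t2 <- rep(rnorm(n, 14.2, 3), each = 3) +
    rep(c(0, -0.7, -1.3), n) + rnorm(3 * n, 0, 1)
  co <- data.frame(
    subject_id = rep(sprintf("S%03d", 1:n), each = 3),
    visit_week = rep(c(0, 12, 24), n),
    t2_degenerative = t2,
    age = rep(sample(18:35, n, TRUE), each = 3),
    sex = rep(rbinom(n, 1, 0.7), each = 3),
    bmi = rep(round(rnorm(n, 23.5, 2), 1), each = 3),
    csas = rep(round(runif(n, 50, 100)), each = 3),
    symptom_duration = rep(round(runif(n, 10, 200)), each = 3))
  co$visap <- 75 + gamma * co$t2_degenerative + 0.2 * co$age +
    rep(rnorm(n, 0, 5), each = 3) + rnorm(3 * n, 0, 3)
  res <- fit_change_association(co, "degenerative")
  eff <- res$main_effect
  expect_true(eff$ci_low <= gamma && gamma <= eff$ci_high)
  expect_equal(eff$estimate, gamma, tolerance = 0.25)
})

test_that("single-visit cohorts cannot fit longitudinal models", {
  co <- generate_cohort(cohort_spec(n_subjects = 30, seed = 3))
  base <- co[co$visit_week == 0, ]
  expect_error(fit_change_association(base, "degenerative"), "single visit")
  expect_error(fit_gee_longitudinal(base, "degenerative"), "three-visit")
})
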