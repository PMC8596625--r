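test_that("with balanced complete data and no covariates, GEE contrasts equal mean differences", {
  co <- generate_cohort(cohort_spec(n_subjects = 40, missing_rate = 0, seed = 5))
  res <- fit_gee_longitudinal(co, "degenerative", covariates = FALSE)
  mns <- tapply(co$t2_degenerative, co$visit_week, mean)
  expect_equal(res$contrasts$estimate,
               unname(c(mns[2] - mns[1], mns[3] - mns[2], mns[3] - mns[1])),
               tolerance = 1e-8)
})

test_that("independence working correlation reproduces OLS with cluster-robust errors", {
  co <- generate_cohort(cohort_spec(n_subjects = 50, seed = 8))
  dat <- co[!is.na(co$t2_degenerative), ]
  dat$visit <- factor(dat$visit_week)
  form <- t2_degenerative ~ visit + age + bmi
  g <- gee_gaussian(form, dat, id = "subject_id", corstr = "independence")
  f <- stats::lm(form, data = dat)
  expect_equal(g$coefficients, coef(f), tolerance = 1e-10)
  V <- sandwich::vcovCL(f, cluster = dat$subject_id, type = "HC0",
                        cadjust = FALSE)
  expect_equal(g$vcov_robust, V, tolerance = 1e-8)
})

test_that("exchangeable GEE recovers the within-subject correlation", {
  set.seed(31)
  n <- 300
  b <- rnorm(n, 0, 2)                     # ICC = 4 / (4 + 1) = 0.8
  dat <- data.frame(subject_id = rep(1:n, each = 3),
                    y = rep(b, each = 3) + rnorm(3 * n),
                    x = rnorm(3 * n))
  g <- gee_gaussian(y ~ x, dat, id = "subject_id")
  expect_equal(g$rho, 0.8, tolerance = 0.05)
  expect_true(g$converged)
})

test_that("estimates are invariant to subject ordering", {
  co <- generate_cohort(cohort_spec(n_subjects = 40, seed = 12))
  perm <- co[sample(nrow(co)), ]
  a <- fit_gee_longitudinal(co, "degenerative")
  b <- fit_gee_longitudinal(perm, "degenerative")
  expect_equal(a$coefficients$estimate, b$coefficients$estimate,
               tolerance = 1e-8)
  expect_equal(a$contrasts$p, b$contrasts$p, tolerance = 1e-8)
})

test_that("rank-deficient designs fail naming the collinear terms", {
  co <- generate_cohort(cohort_spec(n_subjects = 30, seed = 2))
  co$dup <- co$age
  expect_error(gee_gaussian(t2_degenerative ~ age + dup, co, id = "subject_id"),
               "collinear.*dup")
})

test_that("Bonferroni flags fire exactly when unadjusted p < 0.05 / 3", {
  co <- generate_cohort(cohort_spec(n_subjects = 60, seed = 77))
  res <- fit_gee_longitudinal(co, "degenerative")
  expect_identical(res$contrasts$significant, res$contrasts$p < 0.05 / 3)
  expect_equal(res$contrasts$p_bonferroni, pmin(1, 3 * res$contrasts$p))
  expect_equal(nrow(res$contrasts), 3L)
})

test_that("the arm-by-visit interaction test is reported when requested", {
  co <- generate_cohort(cohort_spec(n_subjects = 60, seed = 13))
  res <- fit_gee_longitudinal(co, "degenerative", interaction = TRUE)
  it <- res$interaction_test
  expect_equal(it$df, 2L)
  expect_true(it$p >= 0 && it$p <= 1)
})
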