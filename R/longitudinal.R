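# The statistical layer linking compartment-mean T2* to symptom severity:
# pooled cross-sectional regression, baseline outcome prediction, the
# population-averaged GEE visit contrasts with Bonferroni correction, the
# random-intercept change model, and the LOCF sensitivity analysis.
# All models adjust for the predefined confounders age, sex, BMI, CSAS and
# symptom duration; confidence intervals are Wald with normal quantiles.

t2_column <- function(compartment) {
  compartment <- match.arg(compartment,
                           c("degenerative", "interface", "aligned_collagen"))
  c(degenerative = "t2_degenerative", interface = "t2_interface",
    aligned_collagen = "t2_aligned")[[compartment]]
}

covariate_terms <- function() c("age", "sex", "bmi", "symptom_duration", "csas")

model_result <- function(kind, coefficients, contrasts = NULL,
                         n_obs = NA_integer_, n_subjects = NA_integer_,
                         extra = list()) {
  structure(c(list(kind = kind, coefficients = coefficients,
                   contrasts = contrasts, n_obs = n_obs,
                   n_subjects = n_subjects), extra),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s (n_obs = %d, n_subjects = %d)\n",
              x$kind, x$n_obs, x$n_subjects))
  print(x$coefficients, row.names = FALSE, digits = 4)
  if (!is.null(x$contrasts)) {
    cat("contrasts (Bonferroni-adjusted over", nrow(x$contrasts), "comparisons):\n")
    print(x$contrasts, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

coef_table <- function(est, se, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = names(est), estimate = unname(est),
             std_error = unname(se),
             ci_low = unname(est - z * se), ci_high = unname(est + z * se),
             p = unname(2 * stats::pnorm(-abs(est / se))),
             stringsAsFactors = FALSE)
}

check_collinearity <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("design is rank deficient; collinear terms: %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Cross-sectional association of compartment T2* with VISA-P
#'
#' Pooled multiple linear regression of compartment-mean T2* on the VISA-P
#' score plus the predefined confounders, with observations from all visits
#' pooled.  By default plain OLS (matching the reporting of the pooled
#' scatter analysis); `robust = TRUE` replaces the covariance with a
#' cluster-robust (by subject) sandwich estimate.
#'
#' @param cohort Long-format cohort table (see [generate_cohort()]).
#' @param compartment `"degenerative"`, `"interface"` or
#'   `"aligned_collagen"`.
#' @param robust Use subject-clustered sandwich standard errors.
#' @param conf_level Confidence level for Wald intervals.
#' @return A `model_result` with one row per term (the `visap` row is the
#'   slope in msec per VISA-P point).
#' @export
fit_cross_sectional <- function(cohort, compartment = "degenerative",
                                robust = FALSE, conf_level = 0.95) {
  ycol <- t2_column(compartment)
  vars <- c(ycol, "visap", covariate_terms(), "subject_id")
  dat <- cohort[stats::complete.cases(cohort[, setdiff(vars, "subject_id")]), vars]
  if (nrow(dat) < 10L)
    stop(sprintf("insufficient data: %d complete rows (need >= 10)", nrow(dat)),
         call. = FALSE)
  form <- stats::as.formula(paste(ycol, "~ visap +",
                                  paste(covariate_terms(), collapse = " + ")))
  check_collinearity(stats::model.matrix(form, dat))
  fit <- stats::lm(form, data = dat)
  V <- if (robust) sandwich::vcovCL(fit, cluster = dat$subject_id)
       else stats::vcov(fit)
  tab <- coef_table(stats::coef(fit), sqrt(diag(V)), conf_level)
  model_result(kind = paste0("cross_sectional_", compartment),
               coefficients = tab, n_obs = nrow(dat),
               n_subjects = length(unique(dat$subject_id)),
               extra = list(r_squared = summary(fit)$r.squared,
                            robust = robust, lm_fit = fit))
}

#' Baseline T2* as a predictor of 24-week clinical outcome
#'
#' Adjusted linear model of the final-visit VISA-P score on baseline
#' compartment-mean T2* and the predefined confounders, one row per
#' subject.  Reports the model R-squared and the p-value of the T2* term.
#'
#' @inheritParams fit_cross_sectional
#' @return A `model_result`; `r_squared` and `p_t2` in its extras.
#' @export
fit_baseline_prediction <- function(cohort, compartment = "degenerative",
                                    conf_level = 0.95) {
  ycol <- t2_column(compartment)
  wk <- sort(unique(cohort$visit_week))
  base <- cohort[cohort$visit_week == wk[1], ]
  last <- cohort[cohort$visit_week == wk[length(wk)], c("subject_id", "visap")]
  names(last)[2] <- "visap_final"
  if (all(is.na(last$visap_final)))
    stop("no final-visit outcome available for any subject", call. = FALSE)
  dat <- merge(base, last, by = "subject_id")
  vars <- c("visap_final", ycol, covariate_terms())
  dat <- dat[stats::complete.cases(dat[, vars]), ]
  if (nrow(dat) < 10L)
    stop(sprintf("insufficient data: %d complete subjects (need >= 10)", nrow(dat)),
         call. = FALSE)
  form <- stats::as.formula(paste("visap_final ~", ycol, "+",
                                  paste(covariate_terms(), collapse = " + ")))
  check_collinearity(stats::model.matrix(form, dat))
  fit <- stats::lm(form, data = dat)
  tab <- coef_table(stats::coef(fit), sqrt(diag(stats::vcov(fit))), conf_level)
  model_result(kind = paste0("baseline_prediction_", compartment),
               coefficients = tab, n_obs = nrow(dat), n_subjects = nrow(dat),
               extra = list(r_squared = summary(fit)$r.squared,
                            p_t2 = tab$p[tab$term == ycol]))
}

#' Population-averaged longitudinal T2* model (GEE)
#'
#' Fits [gee_gaussian()] with visit as a categorical factor and the
#' predefined confounders, exchangeable working correlation and robust
#' standard errors, then forms the three planned visit contrasts
#' (baseline vs 12 weeks, 12 vs 24 weeks, baseline vs 24 weeks), each
#' reported with a Wald 95% CI and flagged significant when its
#' unadjusted p-value falls below 0.05/3 (Bonferroni over the three
#' comparisons).  With `interaction = TRUE` the model adds arm-by-visit
#' terms and reports their joint Wald test (the between-arm time-course
#' comparison).
#'
#' @inheritParams fit_cross_sectional
#' @param covariates Adjust for the predefined confounders (default TRUE;
#'   disable for the closed-form balanced-data reduction).
#' @param interaction Add arm x visit interaction terms.
#' @param alpha Familywise significance level before Bonferroni division.
#' @return A `model_result` whose `contrasts` table has columns
#'   `contrast`, `estimate`, `ci_low`, `ci_high`, `p`, `p_bonferroni`,
#'   `significant`; interaction results (when requested) in extras.
#' @export
fit_gee_longitudinal <- function(cohort, compartment = "degenerative",
                                 covariates = TRUE, interaction = FALSE,
                                 conf_level = 0.95, alpha = 0.05) {
  ycol <- t2_column(compartment)
  dat <- cohort[!is.na(cohort[[ycol]]), ]
  visits <- sort(unique(cohort$visit_week))
  if (length(visits) != 3L)
    stop("the planned visit contrasts require a three-visit schedule", call. = FALSE)
  nv_per_subj <- table(dat$subject_id)
  if (sum(nv_per_subj >= 2L) < 10L)
    stop("need >= 10 subjects observed at >= 2 visits", call. = FALSE)
  dat$visit <- factor(dat$visit_week, levels = visits)
  rhs <- "visit"
  if (interaction) {
    dat$arm <- factor(dat$arm)
    rhs <- "arm * visit"
  }
  if (covariates) rhs <- paste(rhs, "+", paste(covariate_terms(), collapse = " + "))
  form <- stats::as.formula(paste(ycol, "~", rhs))
  fit <- gee_gaussian(form, dat, id = "subject_id", corstr = "exchangeable")

  cn <- names(fit$coefficients)
  v12 <- as.numeric(cn == paste0("visit", visits[2]))
  v24 <- as.numeric(cn == paste0("visit", visits[3]))
  cons <- rbind(`0_vs_12` = v12, `12_vs_24` = v24 - v12, `0_vs_24` = v24)
  rows <- t(apply(cons, 1, function(cv) gee_contrast(fit, cv, conf_level)))
  m <- nrow(rows)
  contrasts <- data.frame(contrast = rownames(rows),
                          estimate = rows[, "estimate"],
                          ci_low = rows[, "ci_low"], ci_high = rows[, "ci_high"],
                          p = rows[, "p"],
                          p_bonferroni = pmin(1, m * rows[, "p"]),
                          significant = rows[, "p"] < alpha / m,
                          stringsAsFactors = FALSE)
  rownames(contrasts) <- NULL
  tab <- coef_table(fit$coefficients, sqrt(diag(fit$vcov_robust)), conf_level)
  extra <- list(gee_fit = fit, rho = fit$rho)
  if (interaction) {
    int_terms <- grep(":", cn, value = TRUE)
    extra$interaction_test <- gee_wald_joint(fit, int_terms)
  }
  model_result(kind = paste0("gee_longitudinal_", compartment),
               coefficients = tab, contrasts = contrasts,
               n_obs = fit$n_obs, n_subjects = fit$n_clusters, extra = extra)
}

#' Association of T2* with VISA-P across visits (mixed model)
#'
#' Subject-level random-intercept linear model of the VISA-P score on
#' compartment-mean T2* and the predefined confounders across all visits,
#' fitted with `lme4::lmer`.  The T2* main effect is reported with a Wald
#' normal-quantile 95% CI (no small-sample df correction).
#'
#' @inheritParams fit_cross_sectional
#' @return A `model_result`; the compartment T2* row is the main effect.
#' @export
fit_change_association <- function(cohort, compartment = "degenerative",
                                   conf_level = 0.95) {
  ycol <- t2_column(compartment)
  vars <- c("visap", ycol, covariate_terms(), "subject_id")
  dat <- cohort[stats::complete.cases(cohort[, setdiff(vars, "subject_id")]),
                vars]
  nv <- table(dat$subject_id)
  if (max(nv) < 2L)
    stop("all subjects have a single visit; a longitudinal model is not identified",
         call. = FALSE)
  if (sum(nv >= 2L) < 10L)
    stop("need >= 10 subjects observed at >= 2 visits", call. = FALSE)
  form <- stats::as.formula(paste("visap ~", ycol, "+",
                                  paste(covariate_terms(), collapse = " + "),
                                  "+ (1 | subject_id)"))
  fit <- lme4::lmer(form, data = dat, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  tab <- coef_table(est, se, conf_level)
  model_result(kind = paste0("change_association_", compartment),
               coefficients = tab, n_obs = nrow(dat),
               n_subjects = length(nv),
               extra = list(main_effect = tab[tab$term == ycol, ],
                            lmer_fit = fit))
}

#' Last observation carried forward (LOCF) imputation
#'
#' Replaces each missing T2* or VISA-P value by the subject's most recent
#' preceding observed value, visit order within subject.  A missing
#' baseline stays missing (there is nothing to carry).  Idempotent, and a
#' complete table is returned unchanged.  The fraction of imputed
#' scan observations is attached as `attr(, "imputed_fraction")`.
#'
#' @param cohort Long-format cohort table.
#' @param columns Columns to carry forward; defaults to the three T2*
#'   columns and `visap`.
#' @return The table with carried-forward values.
#' @export
apply_locf <- function(cohort,
                       columns = c("t2_degenerative", "t2_interface",
                                   "t2_aligned", "visap")) {
  columns <- intersect(columns, names(cohort))
  out <- cohort[order(cohort$subject_id, cohort$visit_week), ]
  n_missing <- sum(is.na(out[, columns]))
  for (col in columns) {
    out[[col]] <- stats::ave(out[[col]], out$subject_id, FUN = function(v) {
      for (k in seq_along(v)[-1]) if (is.na(v[k])) v[k] <- v[k - 1]
      v
    })
  }
  if ("scan_missing" %in% names(out) && "t2_degenerative" %in% columns)
    out$scan_missing <- out$scan_missing & is.na(out$t2_degenerative)
  n_after <- sum(is.na(out[, columns]))
  attr(out, "imputed_fraction") <-
    if (n_missing == 0) 0 else (n_missing - n_after) / length(as.matrix(out[, columns]))
  rownames(out) <- NULL
  out
}

#' Does missingness exceed the LOCF sensitivity trigger?
#'
#' The sensitivity analysis is performed when missing observations exceed
#' 5% of the scheduled total (e.g. 21 missing of 195 scheduled
#' acquisitions, a fraction of about 11%, fires the trigger).
#'
#' @param n_missing Number of missing observations, or a cohort table
#'   (missing scans counted from the degenerative T2* column).
#' @param n_total Scheduled total (ignored when a table is given).
#' @param threshold Trigger fraction, default 0.05.
#' @return List with `fraction`, `threshold`, `triggered`.
#' @export
locf_trigger <- function(n_missing, n_total = NULL, threshold = 0.05) {
  if (is.data.frame(n_missing)) {
    tab <- n_missing
    n_total <- nrow(tab)
    n_missing <- sum(is.na(tab$t2_degenerative))
  }
  fraction <- n_missing / n_total
  list(fraction = fraction, threshold = threshold,
       triggered = fraction > threshold)
}
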