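# Generalized estimating equations for Gaussian outcomes with identity
# link: iterative generalized least squares under an exchangeable (or
# independence) working correlation, with the Liang-Zeger robust
# (sandwich) covariance.  Point estimates are population-averaged and,
# with balanced complete data and no covariates, reduce exactly to
# per-group sample means.

#' Fit a Gaussian identity-link GEE
#'
#' Estimates regression coefficients by iteratively reweighted generalized
#' least squares with an exchangeable working correlation (scalar moment
#' estimators for the dispersion and the within-cluster correlation), and
#' reports both the model-based and the robust sandwich covariance.
#' Rows with missing values are dropped (complete-case).  Estimates are
#' invariant to cluster ordering.
#'
#' @param formula Model formula.
#' @param data Data frame in long format.
#' @param id Name of the cluster (subject) identifier column.
#' @param corstr Working correlation: `"exchangeable"` (default) or
#'   `"independence"`.
#' @param maxit,tol Iteration controls for the coefficient update.
#' @return A `gee_fit` list: `coefficients`, `vcov_robust`, `vcov_naive`,
#'   `rho`, `dispersion`, `n_obs`, `n_clusters`, `converged`, `formula`.
#' @export
gee_gaussian <- function(formula, data, id,
                         corstr = c("exchangeable", "independence"),
                         maxit = 50L, tol = 1e-10) {
  corstr <- match.arg(corstr)
  if (!id %in% names(data)) stop(sprintf("id column '%s' not found", id), call. = FALSE)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  mf <- mf[keep, , drop = FALSE]
  cl <- as.character(data[[id]][keep])
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("not enough complete observations for the model", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop(sprintf("design is rank deficient; collinear terms: %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  clusters <- split(seq_len(n), cl)
  n_clusters <- length(clusters)
  max_ni <- max(lengths(clusters))

  beta <- qr.coef(qrX, y)
  rho <- 0
  phi <- NA_real_
  converged <- FALSE
  for (it in seq_len(maxit)) {
    r <- y - as.numeric(X %*% beta)
    phi <- sum(r^2) / (n - p)
    if (corstr == "exchangeable" && max_ni > 1L) {
      num <- 0; npairs <- 0
      for (ix in clusters) {
        ri <- r[ix]; ni <- length(ri)
        if (ni > 1L) {
          num <- num + (sum(ri)^2 - sum(ri^2)) / 2
          npairs <- npairs + ni * (ni - 1) / 2
        }
      }
      rho <- num / ((npairs - p) * phi)
      rho <- max(min(rho, 0.999), -1 / (max_ni - 1) + 1e-6)
    }
    A <- matrix(0, p, p); b <- numeric(p)
    for (ix in clusters) {
      Xi <- X[ix, , drop = FALSE]; yi <- y[ix]; ni <- length(ix)
      # R^{-1} = [I - rho/(1+(ni-1)rho) J] / (1-rho), for exchangeable R
      if (corstr == "exchangeable" && ni > 1L) {
        c1 <- 1 / (1 - rho)
        c2 <- rho / ((1 - rho) * (1 + (ni - 1) * rho))
        XtRi <- c1 * t(Xi) - c2 * tcrossprod(colSums(Xi), rep(1, ni))
      } else {
        XtRi <- t(Xi)
      }
      A <- A + XtRi %*% Xi
      b <- b + as.numeric(XtRi %*% yi)
    }
    beta_new <- solve(A, b)
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
    if (corstr == "independence") { converged <- TRUE; break }
  }

  # sandwich: B^{-1} (sum_i Xi' Vi^{-1} ri ri' Vi^{-1} Xi) B^{-1},
  # Vi = phi * Ri, so the phi factors cancel in B^{-1} M B^{-1}
  r <- y - as.numeric(X %*% beta)
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ix in clusters) {
    Xi <- X[ix, , drop = FALSE]; ri <- r[ix]; ni <- length(ix)
    if (corstr == "exchangeable" && ni > 1L) {
      c1 <- 1 / (1 - rho)
      c2 <- rho / ((1 - rho) * (1 + (ni - 1) * rho))
      XtRi <- c1 * t(Xi) - c2 * tcrossprod(colSums(Xi), rep(1, ni))
    } else {
      XtRi <- t(Xi)
    }
    B <- B + XtRi %*% Xi
    u <- as.numeric(XtRi %*% ri)
    M <- M + tcrossprod(u)
  }
  Binv <- solve(B)
  vcov_robust <- Binv %*% M %*% Binv
  vcov_naive <- phi * Binv
  dimnames(vcov_robust) <- dimnames(vcov_naive) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, vcov_robust = vcov_robust,
                 vcov_naive = vcov_naive, rho = rho, dispersion = phi,
                 n_obs = n, n_clusters = n_clusters, converged = converged,
                 corstr = corstr, formula = formula),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("<gee_fit> %s working correlation (rho = %.3f), %d obs in %d clusters\n",
              x$corstr, x$rho, x$n_obs, x$n_clusters))
  se <- sqrt(diag(x$vcov_robust))
  print(cbind(estimate = x$coefficients, robust_se = se,
              z = x$coefficients / se))
  invisible(x)
}

# Wald estimate/CI/p for a linear combination c'beta under the robust
# covariance; normal quantiles.
gee_contrast <- function(fit, cvec, conf_level = 0.95) {
  est <- sum(cvec * fit$coefficients)
  se <- sqrt(as.numeric(t(cvec) %*% fit$vcov_robust %*% cvec))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * stats::pnorm(-abs(est / se))
  c(estimate = est, se = se, ci_low = est - z * se, ci_high = est + z * se, p = p)
}

# Joint Wald chi-square test of several coefficients (robust covariance).
gee_wald_joint <- function(fit, terms) {
  idx <- match(terms, names(fit$coefficients))
  if (anyNA(idx)) stop("unknown coefficients in joint test", call. = FALSE)
  b <- fit$coefficients[idx]
  V <- fit$vcov_robust[idx, idx, drop = FALSE]
  W <- as.numeric(t(b) %*% solve(V) %*% b)
  list(statistic = W, df = length(idx),
       p = stats::pchisq(W, df = length(idx), lower.tail = FALSE))
}
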