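#' Huber robust linear regression by iteratively reweighted least squares
#'
#' M-estimation with Huber's loss: quadratic for standardized residuals
#' within `k` robust scale units, linear beyond, so gross outliers are
#' downweighted rather than dominating the fit. The algorithm initializes at
#' ordinary least squares and iterates: residuals, robust scale
#' `s = median(|r|) / 0.6745` (the MAD about zero, consistent for the
#' Gaussian sigma and re-estimated every iteration), Huber weights
#' `w_i = min(1, k / |r_i / s|)`, weighted least-squares update — until the
#' largest coefficient change falls below `tol`. Standard errors come from
#' the standard M-estimator asymptotic covariance with the usual
#' small-sample correction factor; coefficient tests use the normal
#' reference (`z = b/SE`, two-sided).
#'
#' Model fit is summarized by the variance-based R-squared,
#' `1 - SS_res / SS_tot` with `SS_tot` taken about the mean of the observed
#' response, and its adjusted form
#' `1 - (SS_res / SS_tot) * (n - 1) / (n - p - 1)` where `p` counts
#' predictors excluding the intercept — directly comparable to the classical
#' R-squared of the companion OLS fit.
#'
#' @param formula Model formula.
#' @param data Data frame with no missing cells in the modeled variables.
#' @param k Huber tuning constant; the default 1.345 gives 95% efficiency
#'   under Gaussian errors.
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change.
#' @param max_iter Maximum IRLS iterations; non-convergence returns the fit
#'   with `converged = FALSE` and a warning.
#' @return An object of class `huber_fit`: coefficients, standard errors,
#'   z and p values, robust `scale`, per-observation `weights` in (0, 1],
#'   `r2_variance`, `r2_adjusted`, residuals, and bookkeeping fields.
#' @seealso [fit_ols()] for the companion least-squares fit, [tidy()] and
#'   [glance()] for tabular summaries.
#' @export
#' @examples
#' d <- data.frame(x = 1:20)
#' d$y <- 1 + 2 * d$x
#' coef(fit_huber(y ~ x, d))
fit_huber <- function(formula, data, k = 1.345, tol = 1e-8, max_iter = 200) {
  stopifnot(k > 0, tol > 0, max_iter >= 1)
  mf <- model.frame(formula, data, na.action = stats::na.fail)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  check_full_rank(X)
  n <- nrow(X)
  p_all <- ncol(X)
  if (n <= p_all) abort("need more observations than coefficients")

  b <- qr.coef(qr(X), y)
  converged <- FALSE
  iter <- 0L
  w <- rep(1, n)
  s <- NA_real_
  # scale below this is numerical noise from an interpolating fit
  s_floor <- 1e-10 * max(1, median(abs(y - median(y))))
  repeat {
    iter <- iter + 1L
    r <- y - drop(X %*% b)
    s <- median(abs(r)) / 0.6745
    if (s < s_floor) { # interpolating fit: nothing left to reweight
      s <- 0
      w <- rep(1, n)
      converged <- TRUE
      break
    }
    u <- r / s
    w <- pmin(1, k / abs(u))
    b_new <- qr.coef(qr(X * sqrt(w)), y * sqrt(w))
    delta <- max(abs(b_new - b))
    b <- b_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warn(paste0("IRLS did not converge in ", max_iter, " iterations"))
  }

  r <- y - drop(X %*% b)
  s <- median(abs(r)) / 0.6745  # final-scale restatement so the stored
  if (s < s_floor) s <- 0 else w <- pmin(1, k / abs(r / s))
  se <- setNames(huber_se(X, r, s, k), names(b))
  z <- ifelse(se > 0, b / se, NA_real_)
  p <- 2 * pnorm(-abs(z))

  has_int <- as.logical(attr(terms(mf), "intercept"))
  p_pred <- p_all - as.integer(has_int)
  ss_res <- sum(r^2)
  ss_tot <- sum((y - mean(y))^2)

  structure(list(
    coefficients = b, std_error = se, z = z, p_value = p,
    scale = s, weights = w, iterations = iter, converged = converged,
    residuals = r, fitted = drop(X %*% b), y = y, X = X,
    k = k, n = n, p = p_pred,
    r2_variance = r2_from_ss(ss_res, ss_tot, n, p_pred, adjusted = FALSE),
    r2_adjusted = r2_from_ss(ss_res, ss_tot, n, p_pred, adjusted = TRUE),
    formula = formula
  ), class = "huber_fit")
}

# standard M-estimator asymptotic covariance (Huber proposal, as used for
# rlm-style fits): var(b) = K^2 * s^2 * [sum psi^2/(n-p')] / mean(psi')^2 *
# (X'X)^{-1}, with K the usual correction for the variance of psi'
huber_se <- function(X, r, s, k) {
  n <- nrow(X); p_all <- ncol(X)
  if (is.na(s) || s == 0) return(rep(0, p_all))
  u <- r / s
  psi <- pmax(-k, pmin(k, u))
  psip <- as.numeric(abs(u) <= k)
  m1 <- mean(psip)
  K <- 1 + p_all / n * var(psip) / m1^2
  stddev <- K * sqrt(s^2 * sum(psi^2) / (n - p_all)) / m1
  XtX_inv <- chol2inv(chol(crossprod(X)))
  sqrt(diag(XtX_inv)) * stddev
}

# variance-based R2: SStot about the response mean for robust and classical
# fits alike; adjusted form multiplies the residual ratio by (n-1)/(n-p-1),
# p excluding the intercept
r2_from_ss <- function(ss_res, ss_tot, n, p, adjusted) {
  if (ss_tot == 0) abort("SS_tot is zero: response has no variance")
  ratio <- ss_res / ss_tot
  if (adjusted) 1 - ratio * (n - 1) / (n - p - 1) else 1 - ratio
}

#' Variance-based R-squared of a robust fit
#'
#' @param fit A [fit_huber()] result.
#' @param adjusted Return the complexity-penalized form?
#' @return A single numeric value (at most 1; negative values are possible
#'   for fits worse than the mean-only model).
#' @export
variance_r2 <- function(fit, adjusted = FALSE) {
  stopifnot(inherits(fit, "huber_fit"))
  if (adjusted) fit$r2_adjusted else fit$r2_variance
}

#' Coefficient tests for a robust fit
#'
#' `z = b / SE` against the standard normal, two-sided. A zero standard
#' error (interpolating fit) yields `NA` test columns.
#'
#' @param fit A [fit_huber()] result.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
coefficient_tests <- function(fit) {
  stopifnot(inherits(fit, "huber_fit"))
  tibble(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    std.error = unname(fit$std_error),
    statistic = unname(fit$z),
    p.value = unname(fit$p_value)
  )
}

#' Ordinary least-squares companion fit
#'
#' Classical linear model used to validate the stability of each robust
#' fit: same formula, normal-equations solution via [stats::lm()], classical
#' standard errors and R-squared, plus leverage for outlier diagnostics.
#'
#' @inheritParams fit_huber
#' @return An object of class `ols_fit` wrapping the `lm` fit.
#' @export
fit_ols <- function(formula, data) {
  mf <- model.frame(formula, data, na.action = stats::na.fail)
  X <- model.matrix(attr(mf, "terms"), mf)
  check_full_rank(X)
  fit <- lm(formula, data)
  structure(list(lm = fit, formula = formula, n = nrow(X),
                 p = ncol(X) - as.integer(attr(terms(mf), "intercept") > 0)),
            class = "ols_fit")
}

#' Cook's distance diagnostics
#'
#' Per-observation Cook's distance of an OLS fit,
#' `D_i = r_i^2 h_i / (p' s^2 (1 - h_i)^2)` with `p'` the number of
#' estimated coefficients, flagged against the conventional `4/n` cutoff.
#' Observations with leverage 1 have undefined distance and are reported as
#' `NA`.
#'
#' @param fit A [fit_ols()] result.
#' @return A tibble with columns `observation`, `cooks_d`, `leverage`,
#'   `flagged`.
#' @export
cooks_flags <- function(fit) {
  stopifnot(inherits(fit, "ols_fit"))
  h <- hatvalues(fit$lm)
  d <- cooks.distance(fit$lm)
  d[h >= 1 - 1e-12] <- NA_real_
  n <- fit$n
  tibble(
    observation = seq_len(n),
    cooks_d = as.numeric(d),
    leverage = as.numeric(h),
    flagged = !is.na(d) & d > 4 / n
  )
}

check_full_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  invisible(X)
}

#' @export
coef.huber_fit <- function(object, ...) object$coefficients

#' @export
residuals.huber_fit <- function(object, ...) object$residuals

#' @export
fitted.huber_fit <- function(object, ...) object$fitted

#' @export
print.huber_fit <- function(x, ...) {
  cat("Huber robust linear model (IRLS, k =", x$k, ")\n")
  cat("  formula:", deparse(x$formula), "\n")
  cat(sprintf("  n = %d, iterations = %d, converged = %s, scale = %.4g\n",
              x$n, x$iterations, x$converged, x$scale))
  print(coefficient_tests(x))
  cat(sprintf("  variance-based R2 = %.4f (adjusted %.4f)\n",
              x$r2_variance, x$r2_adjusted))
  invisible(x)
}

#' @export
tidy.huber_fit <- function(x, ...) coefficient_tests(x)

#' @export
glance.huber_fit <- function(x, ...) {
  tibble(
    r2_variance = x$r2_variance, r2_adjusted = x$r2_adjusted,
    scale = x$scale, iterations = x$iterations, converged = x$converged,
    nobs = x$n
  )
}

#' @export
tidy.ols_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.ols_fit <- function(x, ...) {
  s <- summary(x$lm)
  tibble(r2 = s$r.squared, r2_adjusted = s$adj.r.squared,
         sigma = s$sigma, nobs = x$n)
}

#' @export
coef.ols_fit <- function(object, ...) coef(object$lm)

#' @export
residuals.ols_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
print.ols_fit <- function(x, ...) {
  cat("OLS companion fit\n  formula:", deparse(x$formula), "\n")
  print(tidy(x))
  invisible(x)
}
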