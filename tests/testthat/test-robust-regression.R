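ols_closed_form <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

test_that("a noiseless line is interpolated exactly with unit weights", {
  d <- data.frame(x = 1:20)
  d$y <- 1 + 2 * d$x
  f <- fit_huber(y ~ x, d)
  expect_equal(unname(coef(f)), c(1, 2), tolerance = 1e-10)
  expect_true(all(f$weights == 1))
  expect_equal(f$r2_variance, 1)
  expect_equal(f$r2_adjusted, 1)
  expect_true(all(is.na(coefficient_tests(f)$p.value)))  # SE = 0: undefined
})

test_that("a huge tuning constant reduces the fit to closed-form OLS", {
  withr::with_seed(8, {
    for (i in 1:5) {
      n <- 60
      d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
      d$y <- 0.5 - d$x1 + 2 * d$x2 + rnorm(n, 0, 1.5)
      f <- fit_huber(y ~ x1 + x2 + x3, d, k = 1e6)
      X <- cbind(1, d$x1, d$x2, d$x3)
      expect_equal(unname(coef(f)), ols_closed_form(X, d$y), tolerance = 1e-8)
      o <- fit_ols(y ~ x1 + x2 + x3, d)
      expect_equal(unname(coef(f)), unname(coef(o)), tolerance = 1e-8)
    }
  })
})

test_that("a gross outlier is downweighted and its pull on the slope halved", {
  withr::with_seed(3, {
    n <- 40
    d <- data.frame(x = seq(0, 4, length.out = n))
    d$y <- 2 + d$x + rnorm(n, 0, 0.1)
    clean <- coef(fit_ols(y ~ x, d))
    d$y[n] <- d$y[n] + 30  # gross outlier at the right edge
    hub <- fit_huber(y ~ x, d)
    ols <- fit_ols(y ~ x, d)
    expect_lt(hub$weights[n], 1)
    expect_true(all(hub$weights[-n] > hub$weights[n]))
    shift_ols <- abs(coef(ols)[2] - clean[2])
    shift_hub <- abs(coef(hub)[2] - clean[2])
    expect_lt(shift_hub, 0.5 * shift_ols)
  })
})

test_that("final weights obey the Huber law w = min(1, k/|r/s|) exactly", {
  withr::with_seed(14, {
    n <- 80
    d <- data.frame(x = rnorm(n))
    d$y <- d$x + rt(n, df = 2)  # heavy tails: some weights < 1
    f <- fit_huber(y ~ x, d)
    s <- median(abs(f$residuals)) / 0.6745
    expect_equal(f$weights, pmin(1, f$k / abs(f$residuals / s)),
                 tolerance = 1e-12)
    expect_true(any(f$weights < 1))
    expect_true(all(f$weights > 0 & f$weights <= 1))
    expect_true(f$converged)
  })
})

test_that("coefficients agree with an independent rlm implementation", {
  withr::with_seed(26, {
    n <- 100
    d <- data.frame(x1 = rnorm(n), x2 = runif(n))
    d$y <- 1 + 0.8 * d$x1 - 1.2 * d$x2 + rnorm(n)
    d$y[1:3] <- d$y[1:3] + c(12, -9, 15)
    f <- fit_huber(y ~ x1 + x2, d)
    m <- MASS::rlm(y ~ x1 + x2, d, scale.est = "MAD", acc = 1e-10, maxit = 200)
    expect_equal(unname(coef(f)), unname(coef(m)), tolerance = 1e-6)
    expect_equal(unname(f$std_error), unname(sqrt(diag(vcov(m)))),
                 tolerance = 1e-4)
  })
})

test_that("rescaling a predictor rescales its coefficient, not z or R2", {
  withr::with_seed(5, {
    n <- 60
    d <- data.frame(x = rnorm(n), w = rnorm(n))
    d$y <- d$x - d$w + rt(n, 3)
    f1 <- fit_huber(y ~ x + w, d)
    d2 <- d; d2$x <- d$x * 10
    f2 <- fit_huber(y ~ x + w, d2)
    expect_equal(unname(coef(f2)["x"]), unname(coef(f1)["x"]) / 10,
                 tolerance = 1e-6)
    expect_equal(f2$z, f1$z, tolerance = 1e-6)
    expect_equal(f2$r2_variance, f1$r2_variance, tolerance = 1e-9)
  })
})

test_that("coefficient tests follow the standard normal reference", {
  withr::with_seed(6, {
    d <- data.frame(x = rnorm(50)); d$y <- rnorm(50)
    f <- fit_huber(y ~ x, d)
    ct <- coefficient_tests(f)
    expect_equal(ct$p.value, 2 * pnorm(-abs(ct$statistic)), tolerance = 1e-12)
    # symmetry and the 1.96 <-> 0.05 anchor
    expect_equal(2 * pnorm(-abs(1.96)), 0.05, tolerance = 1e-3)
    expect_equal(2 * pnorm(-abs(-1.96)), 2 * pnorm(-abs(1.96)))
  })
})

test_that("variance-based R2 follows its printed arithmetic", {
  # orthogonal construction pinning SSres/SStot exactly at 0.8 with
  # n = 35 and p = 4 predictors
  withr::with_seed(44, {
    n <- 35
    Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 5), n))))
    x <- Q[, 2:5]
    u <- Q[, 6]
    y <- sqrt(0.2) * x[, 1] + sqrt(0.8) * u
    d <- data.frame(y = y, x1 = x[, 1], x2 = x[, 2], x3 = x[, 3], x4 = x[, 4])
    f <- fit_huber(y ~ x1 + x2 + x3 + x4, d, k = 1e6)
    expect_equal(variance_r2(f), 0.2, tolerance = 1e-9)
    expect_equal(variance_r2(f, adjusted = TRUE), 1 - 0.8 * 34 / 30,
                 tolerance = 1e-9)
  })
  # intercept-only model explains nothing
  d0 <- data.frame(y = c(1, 2, 3, 5, 8))
  f0 <- fit_huber(y ~ 1, d0, k = 1e6)
  expect_equal(variance_r2(f0), 0, tolerance = 1e-9)
})

test_that("rank-deficient designs abort naming the collinear column", {
  d <- data.frame(x = 1:10, z = 2 * (1:10), y = rnorm(10))
  expect_error(fit_huber(y ~ x + z, d), "z")
  expect_error(fit_ols(y ~ x + z, d), "z")
})

test_that("Cook's distance matches a leave-one-out refit oracle", {
  withr::with_seed(9, {
    n <- 30
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d$y <- 1 + d$x1 + 0.5 * d$x2 + rnorm(n)
    d$y[n] <- d$y[n] + 8; d$x1[n] <- 4  # one influential point
    ols <- fit_ols(y ~ x1 + x2, d)
    ck <- cooks_flags(ols)

    X <- cbind(1, d$x1, d$x2)
    b <- ols_closed_form(X, d$y)
    s2 <- sum((d$y - X %*% b)^2) / (n - 3)
    oracle <- vapply(seq_len(n), function(i) {
      bi <- ols_closed_form(X[-i, ], d$y[-i])
      sum((X %*% b - X %*% bi)^2) / (3 * s2)
    }, numeric(1))
    expect_equal(ck$cooks_d, oracle, tolerance = 1e-8)
    expect_true(ck$flagged[n])
    expect_true(all(ck$cooks_d >= 0))
  })
})

test_that("a duplicated balanced design with bounded errors has no flags", {
  d <- data.frame(x = rep(seq(-2, 2, 1), 6))
  d$y <- d$x + rep(c(0.2, -0.2), 15)  # every standardized residual ~ 1
  ck <- cooks_flags(fit_ols(y ~ x, d))
  expect_false(any(ck$flagged))
  expect_true(all(ck$cooks_d < 4 / nrow(d)))
})

test_that("robust fits tame residual asymmetry and influence under contamination", {
  # the robust model's own residual account winsorizes the outliers
  # (weight-scaled residuals, bounded by the psi function), so its skewness
  # and the influence of any single point drop relative to plain OLS
  skew <- function(r) mean(((r - mean(r)) / sd(r))^3)
  withr::with_seed(77, {
    for (i in 1:5) {
      n <- 80
      d <- data.frame(x = rnorm(n))
      d$y <- d$x + rnorm(n, 0, 0.5)
      d$y[1:6] <- d$y[1:6] + rexp(6, rate = 0.2)  # one-sided contamination
      hub <- fit_huber(y ~ x, d)
      ols <- fit_ols(y ~ x, d)
      expect_lte(abs(skew(hub$weights * residuals(hub))),
                 abs(skew(residuals(ols))) + 1e-9)
      wfit <- lm(y ~ x, d, weights = hub$weights)
      expect_lte(max(cooks.distance(wfit)), max(cooks.distance(ols$lm)))
    }
  })
})

test_that("tidy and glance return the broom-shaped tables", {
  d <- data.frame(x = rnorm(30)); d$y <- d$x + rnorm(30)
  f <- fit_huber(y ~ x, d)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  gl <- glance(f)
  expect_true(all(c("r2_variance", "r2_adjusted", "scale", "converged",
                    "nobs") %in% names(gl)))
  expect_identical(gl$nobs, 30L)
})
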