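# brute-force Holm stepdown: sort, max-cummax of scaled p, monotone cap
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# two-sided Fisher p for a 2x2 table by direct hypergeometric summation
fisher_2x2_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

test_that("the printed sex-comparability chi-square reproduces with Yates correction", {
  tab <- matrix(c(25, 10, 19, 20), 2, byrow = TRUE)
  res <- chi_square(tab, yates = TRUE)
  expect_equal(res$statistic, 3.060, tolerance = 5e-4)
  expect_identical(unname(res$df), 1L)
  expect_equal(res$p_value, 0.080, tolerance = 5e-3)
})

test_that("chi-square degenerates and orders correctly", {
  sym <- matrix(5, 2, 2)
  res <- chi_square(sym)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  withr::with_seed(18, {
    for (i in 1:10) {
      tab <- matrix(rpois(4, 15) + 1, 2, 2)
      corr <- chi_square(tab, yates = TRUE)$statistic
      raw <- chi_square(tab, yates = FALSE)$statistic
      expect_lte(corr, raw + 1e-12)
    }
  })
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margins")
  expect_error(chi_square(matrix(1:6, 2)), "2x2")
})

test_that("Fisher's exact test matches the hypergeometric-sum oracle", {
  tab <- matrix(c(1, 9, 11, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact(tab), fisher_2x2_oracle(tab), tolerance = 1e-9)

  withr::with_seed(23, {
    for (i in 1:10) {
      tab <- matrix(rpois(4, 6), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact(tab), fisher_2x2_oracle(tab), tolerance = 1e-9)
    }
  })

  ident <- matrix(c(4, 6, 4, 6), 2, byrow = TRUE)
  expect_equal(fisher_exact(ident), 1)
  tab23 <- matrix(c(3, 5, 2, 4, 1, 6), 2)
  expect_equal(fisher_exact(tab23), fisher_exact(tab23[2:1, ]))
  expect_error(fisher_exact(matrix(1, 2, 6)), "k > 5")
})

test_that("Holm adjustment equals the brute-force stepdown on random vectors", {
  expect_equal(p.adjust(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  withr::with_seed(29, {
    for (i in 1:20) {
      m <- sample(2:7, 1)
      p <- runif(m)^2
      adj <- p.adjust(p, "holm")
      expect_equal(adj, holm_oracle(p), tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-15))
      expect_equal(min(adj), min(1, min(p) * m), tolerance = 1e-12)  # Bonferroni floor
      expect_true(all(diff(adj[order(p)]) >= -1e-15))  # stepdown monotone
    }
  })
})

test_that("GG epsilon is near 1 under compound symmetry and matches car", {
  make_long <- function(ns, k, sds, seed) {
    withr::with_seed(seed, {
      subj <- rep(sprintf("s%02d", 1:(2 * ns)), each = k)
      grp <- rep(c("stress", "control"), each = ns * k)
      base <- rep(rnorm(2 * ns, sd = 1), each = k)
      val <- base + rnorm(2 * ns * k) * sds[rep(1:k, 2 * ns)]
      tibble::tibble(participant_id = subj, group = grp,
                     timepoint = paste0("T", rep(1:k, 2 * ns)), value = val)
    })
  }
  cs <- make_long(30, 4, sds = rep(1, 4), seed = 101)
  res <- rm_anova(cs)
  eps <- res$epsilon[res$effect == "timepoint"]
  expect_gt(eps, 0.85)
  expect_lte(eps, 1)

  # heteroscedastic case: epsilon drops below 1 and equals car's value
  het <- make_long(20, 4, sds = c(0.5, 1, 2, 4), seed = 102)
  res2 <- rm_anova(het)
  wide <- tidyr::pivot_wider(het, id_cols = c(participant_id, group),
                             names_from = timepoint, values_from = value)
  mlm <- lm(as.matrix(wide[, -(1:2)]) ~ group, data = wide)
  av <- summary(car::Anova(mlm, idata = data.frame(time = factor(paste0("T", 1:4))),
                           idesign = ~time, type = 3), multivariate = FALSE)
  car_eps <- unname(av$pval.adjustments["time", "GG eps"])
  expect_equal(res2$epsilon[res2$effect == "timepoint"], car_eps,
               tolerance = 1e-8)
  expect_gte(res2$epsilon[res2$effect == "timepoint"], 1 / 3)

  # uncorrected run leaves integer degrees of freedom
  res3 <- rm_anova(het, correction = "none")
  expect_equal(res3$df_num[res3$effect == "timepoint"], 3)
})

test_that("epsilon stays within its bounds on random covariance draws", {
  withr::with_seed(55, {
    for (i in 1:8) {
      k <- sample(3:6, 1); ns <- 12
      sds <- runif(k, 0.3, 3)
      subj <- rep(sprintf("s%02d", 1:(2 * ns)), each = k)
      grp <- rep(c("a", "b"), each = ns * k)
      val <- rnorm(2 * ns * k) * sds[rep(1:k, 2 * ns)] +
        rep(rnorm(2 * ns), each = k)
      d <- tibble::tibble(participant_id = subj, group = grp,
                          timepoint = paste0("T", rep(1:k, 2 * ns)), value = val)
      eps <- rm_anova(d)$epsilon[2]
      expect_gte(eps, 1 / (k - 1))
      expect_lte(eps, 1)
    }
  })
})

test_that("constant data degrade gracefully instead of erroring", {
  d <- tidyr::expand_grid(participant_id = sprintf("s%d", 1:8),
                          timepoint = paste0("T", 1:3))
  d$group <- rep(c("a", "b"), each = 12)
  d$value <- 1
  res <- rm_anova(d)
  expect_true(all(res$F == 0))
  expect_true(all(res$p == 1))
})

test_that("incomplete panels are rejected", {
  d <- tibble::tibble(participant_id = c("a", "a", "b"), group = "g1",
                      timepoint = c("T1", "T2", "T1"), value = 1:3)
  expect_error(rm_anova(d), "complete")
})

test_that("per-timepoint t-tests carry Holm correction and pooled-SD Cohen's d", {
  withr::with_seed(66, {
    d <- tidyr::expand_grid(participant_id = sprintf("s%02d", 1:40),
                            timepoint = c("T1", "T2", "T3"))
    d$group <- rep(c("stress", "control"), each = 60)
    d$value <- rnorm(120)
    # plant a separation at T3 only
    d$value[d$group == "stress" & d$timepoint == "T3"] <-
      d$value[d$group == "stress" & d$timepoint == "T3"] + 3
    res <- posthoc_pairwise(d)
    expect_identical(nrow(res), 3L)
    expect_true(all(res$p_holm >= res$p_raw - 1e-15))
    expect_lt(res$p_holm[res$timepoint == "T3"], 0.05)
    expect_gt(abs(res$d[res$timepoint == "T3"]), 1)

    # equal group means: d near 0, p large
    d2 <- d[d$timepoint != "T3", ]
    res2 <- posthoc_pairwise(d2)
    expect_true(all(abs(res2$d) < 0.7))

    # identical constant values: undefined t reported, not an error
    d3 <- d[d$timepoint == "T1", ]; d3$value <- 2
    expect_warning(res3 <- posthoc_pairwise(d3), "zero variance")
    expect_true(all(is.na(res3$t)))
    expect_true(all(res3$d == 0))
  })
})

test_that("rendered cohorts show the planted group-by-time cortisol signature", {
  coh <- render_trajectories(simulate_cohort(simulation_config(seed = 12)))
  long <- log_cortisol(coh$saliva) %>%
    dplyr::left_join(dplyr::select(coh$covariates, participant_id, group),
                     by = "participant_id")
  res <- rm_anova(long)
  expect_lt(res$p[res$effect == "group:timepoint"], 0.05)
  ph <- posthoc_pairwise(long)
  # pre-stress comparability, post-stress separation
  expect_gt(ph$p_holm[ph$timepoint == "T1"], 0.05)
  expect_lt(ph$p_holm[ph$timepoint == "T4"], 0.05)
})
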