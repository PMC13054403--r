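#' Mixed between-within repeated-measures ANOVA
#'
#' Two-way mixed ANOVA with group as the between-subjects factor and
#' timepoint as the within-subjects factor, on complete balanced data (every
#' participant observed at every timepoint). Sums of squares come from the
#' univariate [stats::aov()] decomposition with subject error strata;
#' within-subject effects are corrected for sphericity violations with the
#' Greenhouse-Geisser epsilon, computed from the pooled within-group
#' covariance of the timepoints via orthonormal contrasts and multiplying
#' both degrees of freedom. Effect sizes are generalized eta-squared
#' (effect SS over effect SS plus all error SS).
#'
#' @param data Long tibble with columns `participant_id`, `group`,
#'   `timepoint`, `value`.
#' @param correction `"greenhouse_geisser"` (default) or `"none"`.
#' @return A tibble with one row per effect (`group`, `timepoint`,
#'   `group:timepoint`): `F`, `df_num`, `df_den`, `p`, `eta_sq`, `epsilon`
#'   (`NA` for the between-subjects effect).
#' @export
rm_anova <- function(data, correction = c("greenhouse_geisser", "none")) {
  correction <- match.arg(correction)
  need <- c("participant_id", "group", "timepoint", "value")
  if (!all(need %in% names(data))) {
    abort(paste0("data must have columns ", paste(need, collapse = ", ")))
  }
  tab <- table(data$participant_id, data$timepoint)
  if (any(tab != 1)) {
    abort("ANOVA requires complete data: one value per participant per timepoint")
  }
  d <- data
  d$participant_id <- factor(d$participant_id)
  d$group <- factor(d$group)
  d$timepoint <- factor(d$timepoint)
  k <- nlevels(d$timepoint)
  if (nlevels(d$group) < 2 || k < 2) abort("need >= 2 groups and >= 2 timepoints")

  if (var(d$value) == 0) { # flat data: every effect vanishes
    return(tibble(
      effect = c("group", "timepoint", "group:timepoint"),
      F = 0, df_num = c(1, k - 1, k - 1), df_den = NA_real_, p = 1,
      eta_sq = 0, epsilon = c(NA_real_, NA_real_, NA_real_)
    ))
  }
  g_levels <- nlevels(d$group)

  # direct sums-of-squares decomposition for the balanced within-subject
  # design (every subject at every timepoint); equals the aov() strata
  wide <- tidyr::pivot_wider(d, id_cols = c("participant_id", "group"),
                             names_from = "timepoint", values_from = "value")
  Y <- as.matrix(wide[, -(1:2)])
  grp <- wide$group
  n_g <- as.numeric(table(grp))
  n_subj <- nrow(Y)
  m <- mean(Y)
  m_gi <- rowMeans(Y)
  m_g <- tapply(m_gi, grp, mean)
  m_t <- colMeans(Y)
  m_gt <- do.call(rbind, lapply(split(as.data.frame(Y), grp), colMeans))

  gi <- as.integer(grp)
  ss <- c(
    group = k * sum(n_g * (m_g - m)^2),
    err_between = k * sum((m_gi - m_g[gi])^2),
    timepoint = n_subj * sum((m_t - m)^2),
    interaction = sum(n_g * rowSums(
      (m_gt - matrix(m_g, g_levels, k) -
         matrix(m_t, g_levels, k, byrow = TRUE) + m)^2)),
    err_within = sum((Y - matrix(m_gi, n_subj, k) - m_gt[gi, , drop = FALSE] +
                        matrix(m_g[gi], n_subj, k))^2)
  )
  df <- c(
    group = g_levels - 1,
    err_between = n_subj - g_levels,
    timepoint = k - 1,
    interaction = (g_levels - 1) * (k - 1),
    err_within = (n_subj - g_levels) * (k - 1)
  )

  eps <- if (correction == "greenhouse_geisser") {
    gg_epsilon(d)
  } else 1

  err_all <- ss[["err_between"]] + ss[["err_within"]]
  row_for <- function(effect, ss_e, df_num, df_den, ss_err, df_err, within_eff) {
    e <- if (within_eff && !is.na(eps)) eps else 1
    ms_e <- ss_e / df_num
    ms_err <- ss_err / df_err
    if (!is.finite(ms_err) || ms_err == 0) {
      f <- 0; pval <- 1  # degenerate: no residual variance
    } else {
      f <- ms_e / ms_err
      pval <- pf(f, df_num * e, df_den * e, lower.tail = FALSE)
    }
    tibble(
      effect = effect, F = f, df_num = df_num * e, df_den = df_den * e,
      p = pval, eta_sq = if (ss_e + err_all > 0) ss_e / (ss_e + err_all) else 0,
      epsilon = if (within_eff) eps else NA_real_
    )
  }
  bind_rows(
    row_for("group", ss[["group"]], df[["group"]], df[["err_between"]],
            ss[["err_between"]], df[["err_between"]], FALSE),
    row_for("timepoint", ss[["timepoint"]], df[["timepoint"]],
            df[["err_within"]], ss[["err_within"]], df[["err_within"]], TRUE),
    row_for("group:timepoint", ss[["interaction"]], df[["interaction"]],
            df[["err_within"]], ss[["err_within"]], df[["err_within"]], TRUE)
  )
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# k timepoints, via normalized orthogonal contrasts:
# eps = tr(M)^2 / ((k-1) * tr(M M')) with M = C S C'
gg_epsilon <- function(d) {
  wide <- tidyr::pivot_wider(d, id_cols = c("participant_id", "group"),
                             names_from = "timepoint", values_from = "value")
  groups <- split(wide, wide$group)
  k <- ncol(wide) - 2
  S <- matrix(0, k, k); wsum <- 0
  for (g in groups) {
    m <- as.matrix(g[, -(1:2)])
    if (nrow(m) > 1) {
      S <- S + (nrow(m) - 1) * stats::cov(m)
      wsum <- wsum + nrow(m) - 1
    }
  }
  S <- S / wsum
  C <- t(stats::contr.helmert(k))
  C <- C / sqrt(rowSums(C^2))
  M <- C %*% S %*% t(C)
  tr <- sum(diag(M))
  if (tr <= 0) return(NA_real_)
  max(1 / (k - 1), min(1, tr^2 / ((k - 1) * sum(M * M))))
}

#' Per-timepoint group comparisons with Holm correction
#'
#' Independent two-sample t-test of stress vs control at each timepoint,
#' Bonferroni-Holm-adjusted across the timepoint family, with Cohen's d
#' from the pooled standard deviation. Pooled-variance (Student) tests by
#' default; set `welch = TRUE` for unequal-variance tests.
#'
#' @inheritParams rm_anova
#' @param welch Use Welch's correction instead of pooled variance?
#' @return A tibble with columns `timepoint`, `t`, `df`, `p_raw`, `p_holm`,
#'   `d`.
#' @export
posthoc_pairwise <- function(data, welch = FALSE) {
  tps <- unique(data$timepoint)
  rows <- lapply(tps, function(tp) {
    d <- data[data$timepoint == tp, ]
    groups <- split(d$value, d$group)
    if (length(groups) != 2 || any(vapply(groups, length, 1L) < 2)) {
      abort(paste0("need two groups with >= 2 observations at ", tp))
    }
    x <- groups[[1]]; y <- groups[[2]]
    sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    if (sp2 == 0) {
      warn(paste0("zero variance in both groups at ", tp, "; t undefined"))
      return(tibble(timepoint = tp, t = NA_real_, df = NA_real_,
                    p_raw = NA_real_, d = 0))
    }
    tt <- t.test(x, y, var.equal = !welch)
    tibble(timepoint = tp, t = unname(tt$statistic),
           df = unname(tt$parameter), p_raw = tt$p.value,
           d = (mean(x) - mean(y)) / sqrt(sp2))
  })
  out <- bind_rows(rows)
  out$p_holm <- p.adjust(out$p_raw, method = "holm")
  out[c("timepoint", "t", "df", "p_raw", "p_holm", "d")]
}

#' Chi-squared test on a 2x2 contingency table
#'
#' Pearson chi-squared with optional Yates continuity correction, used for
#' group-comparability checks (e.g. the sex-by-group distribution).
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @param yates Apply the continuity correction (default `TRUE`)?
#' @return A tibble with columns `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square(matrix(c(25, 10, 19, 20), 2, byrow = TRUE))
chi_square <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("all margins must be positive")
  }
  res <- suppressWarnings(chisq.test(table, correct = yates))
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value)
}

#' Fisher's exact test on a 2-by-k table
#'
#' Exact conditional test: the p-value sums the hypergeometric probabilities
#' of all tables with the observed margins whose probability does not exceed
#' that of the observed table. Enumeration is restricted to small tables
#' (k <= 5 categories and at most ~1e7 candidate tables); larger problems
#' should fall back to the chi-squared test.
#'
#' @param table 2-by-k matrix of non-negative integer counts.
#' @return The two-sided exact p-value (numeric scalar).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2) abort("table must have 2 rows")
  if (ncol(table) > 5) abort("k > 5 categories: use chi_square() instead")
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be non-negative integers")
  }
  n_tables <- prod(pmin(colSums(table), sum(table[1, ])) + 1)
  if (n_tables > 1e7) {
    abort("table too large to enumerate exactly: use chi_square() instead")
  }
  fisher.test(table)$p.value
}
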