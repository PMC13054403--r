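#' Run the end-to-end microbiome/stress analysis
#'
#' Orchestrates the full pipeline on a set of inputs: rarefy the ASV table,
#' zero rare ASVs, aggregate to genus, compute alpha diversity and the F/B
#' ratio, score butyrate/propionate producer capacity, derive the
#' per-participant stress statistics, assemble the feature table, and fit —
#' for every outcome x microbiota term x model family — a Huber robust
#' model with its OLS companion, coefficient table, variance-based R-squared
#' pair and Cook's-distance flags. Group-comparability checks (sex
#' chi-squared) and the mixed group-by-timepoint ANOVA with Holm-corrected
#' post-hoc t-tests are run alongside.
#'
#' Model families mirror the analysis design: `across_groups` fits
#' `outcome ~ sex + trait anxiety + perceived stress (+ baseline cortisol)
#' + term * group` on everyone; `stress_only` and `control_only` drop the
#' group terms and fit within one group. Baseline log-cortisol enters only
#' the cortisol outcomes.
#'
#' @param inputs A fixtures directory (see [write_fixtures()]), a list as
#'   returned by [read_fixtures()], or a rendered `synthetic_cohort`.
#' @param depth Rarefaction depth, `"auto"` (minimum library size) or an
#'   integer.
#' @param threshold Rare-ASV relative-abundance cutoff.
#' @param seed Seed for the rarefaction draw.
#' @param diversity_on Compute diversity on the `"filtered"` or `"rarefied"`
#'   table.
#' @param auc_window Timepoint window for the AUC statistics.
#' @param outcomes Outcome columns to model.
#' @param terms Microbiota predictors to model.
#' @param families Model families to fit.
#' @param huber_k,alpha Huber tuning constant and retention level.
#' @param eliminate Apply [backward_eliminate()] to each model (protected:
#'   the microbiota term, group, and their interaction)?
#' @param out_dir Optional directory for CSV result tables and a run
#'   manifest.
#' @return A list of class `gutstress_results`: `diversity`, `capacities`,
#'   `outcomes`, `features`, `models` (tibble with one row per fitted
#'   model and list-columns holding the fits), `model_table` (long
#'   coefficient table in the layout Predictor/b/SE/z/p), `comparability`,
#'   `anova`, `posthoc`.
#' @export
run_pipeline <- function(inputs,
                         depth = "auto", threshold = 0.001, seed = 1L,
                         diversity_on = "filtered",
                         auc_window = c("T2", "T5"),
                         outcomes = c("reactivity", "recovery",
                                      "subj_reactivity", "auc_g", "auc_i"),
                         terms = c("shannon", "inverse_simpson", "observed",
                                   "butyrate", "propionate", "fb_ratio"),
                         families = c("across_groups", "stress_only",
                                      "control_only"),
                         huber_k = 1.345, alpha = 0.05,
                         eliminate = FALSE, out_dir = NULL) {
  inp <- resolve_inputs(inputs)
  depth_val <- if (identical(depth, "auto")) NULL else as.integer(depth)

  prof <- profile_microbiome(inp$counts, inp$taxonomy, depth = depth_val,
                             threshold = threshold, seed = seed,
                             diversity_on = diversity_on)
  caps <- bind_rows(
    capacity_score(prof$genus_rel, inp$producer_map, "butyrate"),
    capacity_score(prof$genus_rel, inp$producer_map, "propionate")
  )
  outc <- stress_outcomes(inp$saliva, inp$ratings, auc_window = auc_window)
  div <- inner_join(prof$diversity, prof$fb, by = "sample_id")
  features <- build_feature_table(div, caps, outc, inp$covariates)

  models <- fit_model_grid(features, outcomes, terms, families,
                           huber_k, alpha, eliminate)

  sex_tab <- table(factor(inp$covariates$group, c("stress", "control")),
                   factor(inp$covariates$sex, c("female", "male")))
  comparability <- chi_square(unclass(sex_tab))

  cort_long <- log_cortisol(inp$saliva) %>%
    impute_baseline() %>%
    left_join(select(inp$covariates, "participant_id", "group"),
              by = "participant_id") %>%
    select("participant_id", "group", "timepoint", "value")
  anova_tab <- rm_anova(cort_long)
  posthoc_tab <- posthoc_pairwise(cort_long)

  res <- structure(list(
    diversity = div, capacities = caps, outcomes = outc,
    features = features, models = models,
    model_table = model_table(models),
    comparability = comparability, anova = anova_tab, posthoc = posthoc_tab,
    dropped = attr(features, "dropped"),
    seed = seed
  ), class = "gutstress_results")

  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

resolve_inputs <- function(inputs) {
  if (inherits(inputs, "synthetic_cohort")) {
    if (is.null(inputs$saliva)) {
      abort("cohort has no trajectories; call render_trajectories() first")
    }
    return(list(counts = inputs$asv_counts, taxonomy = inputs$taxonomy,
                producer_map = inputs$producer_map, saliva = inputs$saliva,
                ratings = inputs$ratings, covariates = inputs$covariates))
  }
  if (is.character(inputs) && length(inputs) == 1) return(read_fixtures(inputs))
  if (is.list(inputs)) return(inputs)
  abort("inputs must be a fixtures directory, an input list, or a cohort")
}

fit_model_grid <- function(features, outcomes, terms, families,
                           huber_k, alpha, eliminate) {
  grid <- expand.grid(outcome = outcomes, term = terms, family = families,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    dat <- switch(g$family,
      across_groups = features,
      stress_only = features[features$group == 1, , drop = FALSE],
      control_only = features[features$group == 0, , drop = FALSE]
    )
    covs <- c("sex", "gad7", "pss")
    if (g$outcome %in% c("reactivity", "recovery", "auc_g", "auc_i")) {
      covs <- c(covs, "baseline_log_cortisol")
    }
    rhs <- if (g$family == "across_groups") {
      c(covs, paste0(g$term, " * group"))
    } else {
      c(covs, g$term)
    }
    fml <- reformulate(rhs, response = g$outcome)
    sel <- NULL
    fit <- if (eliminate) {
      prot <- if (g$family == "across_groups") {
        c(g$term, "group", paste0(g$term, ":group"))
      } else g$term
      sel <- backward_eliminate(fml, dat, protected = prot,
                                alpha = alpha, k = huber_k)
      sel$fit
    } else {
      fit_huber(fml, dat, k = huber_k)
    }
    ols <- fit_ols(if (is.null(sel)) fml else sel$formula, dat)
    tibble(
      outcome = g$outcome, term = g$term, family = g$family,
      n = fit$n,
      r2_adjusted = fit$r2_adjusted, r2_variance = fit$r2_variance,
      ols_r2 = glance(ols)$r2,
      n_cooks_flagged = sum(cooks_flags(ols)$flagged, na.rm = TRUE),
      fit = list(fit), ols = list(ols),
      trace = list(if (is.null(sel)) NULL else sel$trace)
    )
  })
  bind_rows(rows)
}

# long coefficient table in the published layout: Predictor, b, SE, z, p
model_table <- function(models) {
  rows <- lapply(seq_len(nrow(models)), function(i) {
    co <- coefficient_tests(models$fit[[i]])
    tibble(
      outcome = models$outcome[i], term = models$term[i],
      family = models$family[i], predictor = co$term,
      b = co$estimate, se = co$std.error, z = co$statistic, p = co$p.value
    )
  })
  bind_rows(rows)
}

write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$diversity, file.path(out_dir, "diversity.csv"),
                   progress = FALSE)
  readr::write_csv(res$capacities, file.path(out_dir, "capacities.csv"),
                   progress = FALSE)
  readr::write_csv(res$outcomes, file.path(out_dir, "outcomes.csv"),
                   progress = FALSE)
  readr::write_csv(res$model_table, file.path(out_dir, "model_table.csv"),
                   progress = FALSE)
  readr::write_csv(select(res$models, -"fit", -"ols", -"trace"),
                   file.path(out_dir, "model_summaries.csv"), progress = FALSE)
  readr::write_csv(res$anova, file.path(out_dir, "anova.csv"), progress = FALSE)
  readr::write_csv(res$posthoc, file.path(out_dir, "posthoc.csv"),
                   progress = FALSE)
  yaml::write_yaml(list(
    seed = res$seed,
    package_version = as.character(utils::packageVersion("gutstress")),
    n_models = nrow(res$models)
  ), file.path(out_dir, "run_manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.gutstress_results <- function(x, ...) {
  cat("<gutstress_results>\n")
  cat(sprintf("  %d participants modeled, %d fitted models\n",
              nrow(x$features), nrow(x$models)))
  cat(sprintf("  sex comparability: chi2 = %.3f, p = %.3f\n",
              x$comparability$statistic, x$comparability$p_value))
  inter <- x$anova[x$anova$effect == "group:timepoint", ]
  cat(sprintf("  group x time ANOVA: F(%.2f, %.2f) = %.3f, p = %.4g\n",
              inter$df_num, inter$df_den, inter$F, inter$p))
  invisible(x)
}
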