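#' Assemble the per-participant modeling table
#'
#' Inner-joins the microbiome summaries, SCFA capacities, stress outcomes
#' and covariates on `participant_id` (stool samples map 1:1 to
#' participants), reporting every participant dropped by the join and why.
#' Group and sex are coded numerically (control = 0 / stress = 1,
#' female = 0 / male = 1) and all continuous predictors — the microbiota
#' measures, GAD-7, PSS and baseline log-cortisol — are z-scored within the
#' modeled set, so coefficient magnitudes are per standardized unit.
#'
#' @param diversity Tibble from [alpha_diversity()] (plus optionally an
#'   `fb_ratio` column, see [fb_ratio()]); `sample_id` doubles as the
#'   participant id.
#' @param capacities Tibble of [capacity_score()] rows for both SCFAs
#'   (long: `sample_id`, `scfa`, `capacity`).
#' @param outcomes Tibble from [stress_outcomes()].
#' @param covariates Covariates tibble (see `simulate_cohort()` for the
#'   schema).
#' @param standardize_cols Columns to z-score when present.
#' @return A tibble, one row per modeled participant, with attribute
#'   `dropped`: a tibble of excluded participants and reasons.
#' @export
build_feature_table <- function(diversity, capacities, outcomes, covariates,
                                standardize_cols = c(
                                  "shannon", "inverse_simpson", "observed",
                                  "butyrate", "propionate", "fb_ratio",
                                  "gad7", "pss", "baseline_log_cortisol")) {
  div <- rename(diversity, participant_id = "sample_id")
  caps <- capacities %>%
    rename(participant_id = "sample_id") %>%
    tidyr::pivot_wider(names_from = "scfa", values_from = "capacity")

  sources <- list(diversity = div, capacities = caps,
                  outcomes = outcomes, covariates = covariates)
  for (nm in names(sources)) {
    dup <- duplicated(sources[[nm]]$participant_id)
    if (any(dup)) {
      abort(paste0("duplicate participant(s) in ", nm, ": ",
                   paste(unique(sources[[nm]]$participant_id[dup]),
                         collapse = ", ")))
    }
  }

  tab <- covariates %>%
    inner_join(div, by = "participant_id") %>%
    inner_join(caps, by = "participant_id") %>%
    inner_join(select(outcomes, -dplyr::any_of("baseline_log_cortisol")),
               by = "participant_id")

  all_ids <- unique(unlist(lapply(sources, function(s) s$participant_id)))
  dropped <- lapply(setdiff(all_ids, tab$participant_id), function(id) {
    absent <- names(sources)[!vapply(sources, function(s)
      id %in% s$participant_id, logical(1))]
    tibble(participant_id = id,
           reason = paste0("missing from: ", paste(absent, collapse = ", ")))
  }) %>% bind_rows()
  incomplete <- !complete.cases(tab)
  if (any(incomplete)) {
    dropped <- bind_rows(dropped, tibble(
      participant_id = tab$participant_id[incomplete],
      reason = "incomplete record"))
    tab <- tab[!incomplete, , drop = FALSE]
  }
  if (nrow(dropped) > 0) {
    inform(paste0(nrow(dropped), " participant(s) dropped from the feature table"))
  }

  tab$group <- as.numeric(tab$group == "stress")
  tab$sex <- as.numeric(tab$sex == "male")
  for (col in intersect(standardize_cols, names(tab))) {
    tab[[col]] <- standardize(tab[[col]])
  }
  attr(tab, "dropped") <- dropped
  tab
}
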