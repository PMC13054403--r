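#' Simulate a complete study cohort with planted effects
#'
#' Builds everything the analysis consumes: a Dirichlet-multinomial
#' microbiome (via [simulate_microbiome()]), participant covariates, and a
#' latent cortisol reactivity slope generated from the linear model the
#' analysis later fits —
#' `beta_intercept + beta_sex*sex + beta_anxiety*z(GAD-7) + beta_pss*z(PSS)
#' + beta_baseline*z(log T2 cortisol) + beta_group*group +
#' (beta_div_main + beta_div_by_group*group) * z(Shannon) + noise` —
#' so parameter-recovery harnesses know the ground truth exactly. The
#' Shannon index entering the latent model is computed through the same
#' rarefy-and-filter chain the profiling module applies (rarefaction seeded
#' with `config$seed`), so an analysis run with the same seed sees the
#' identical predictor. Latent recovery is a partial return toward baseline
#' (uniform 50-90% of the rise recovered by T5). All noise enters at the
#' latent level; trajectories rendered from the latents are deterministic,
#' which makes slope extraction an exact round trip.
#'
#' Covariates are drawn to mirror the study population: GAD-7 integer in
#' 0-21 around 6 +/- 4, PSS integer in 0-40 around 17 +/- 7, afternoon
#' baseline cortisol log-normal around 7 nmol/L, roughly 60% female.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_cohort` with elements `config`,
#'   `asv_counts`, `taxonomy`, `producer_map`, `covariates`, `truth`
#'   (latent slopes and planted effect sizes), and — after
#'   [render_trajectories()] — `saliva` and `ratings`.
#' @export
#' @examples
#' coh <- simulate_cohort(simulation_config(n_stress = 4, n_control = 4))
#' coh$truth$latent_reactivity
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_stress + config$n_control
  mb <- simulate_microbiome(config)

  prof <- profile_microbiome(mb$counts, mb$taxonomy, seed = config$seed)
  shannon <- prof$diversity$shannon
  zdiv <- standardize(shannon)

  off <- config$timepoint_offsets
  es <- config$effect_sizes

  with_seed_(config$seed + 1L, {
    pid <- rownames(mb$counts)
    group <- c(rep("stress", config$n_stress), rep("control", config$n_control))
    g <- as.numeric(group == "stress")
    sex <- ifelse(rbinom(n, 1, 0.4) == 1, "male", "female")
    s <- as.numeric(sex == "male")
    gad7 <- pmin(21L, pmax(0L, as.integer(round(rnorm(n, 6, 4)))))
    pss <- pmin(40L, pmax(0L, as.integer(round(rnorm(n, 17, 7)))))
    bmi <- round(pmin(35, pmax(16, rnorm(n, 21.6, 2.9))), 1)
    diet <- sample(c("animal-based", "plant-based", "highly-processed"),
                   n, replace = TRUE, prob = c(0.50, 0.42, 0.08))
    birth_mode <- sample(c("vaginal", "caesarean"), n, replace = TRUE,
                         prob = c(0.8, 0.2))
    early_nutrition <- sample(c("breastfed", "bottle-fed", "both"),
                              n, replace = TRUE, prob = c(0.55, 0.25, 0.20))
    baseline_log <- rnorm(n, log(7), 0.35)

    reactivity <- es$beta_intercept +
      es$beta_sex * s +
      es$beta_anxiety * standardize(gad7) +
      es$beta_pss * standardize(pss) +
      es$beta_baseline * standardize(baseline_log) +
      es$beta_group * g +
      (es$beta_div_main + es$beta_div_by_group * g) * zdiv +
      rnorm(n, 0, config$noise_sd)

    peak_label <- ifelse(rbinom(n, 1, 0.5) == 1, "T4", "T3")
    t_peak <- off[peak_label]
    u <- runif(n, 0.5, 0.9)
    recovery <- -u * reactivity * t_peak / (off[["T5"]] - t_peak)

    # subjective stress: appraisal peaks earlier (mostly T3) and carries a
    # milder diversity-by-group signature on the raw Likert scale
    subj_peak_label <- ifelse(rbinom(n, 1, 0.2) == 1, "T4", "T3")
    t_speak <- off[subj_peak_label]
    rating_baseline <- sample(1:3, n, replace = TRUE)
    delta <- pmax(0, pmin(4, ifelse(
      g == 1,
      2 + 0.6 * zdiv + rnorm(n, 0, 0.6),
      0.4 + rnorm(n, 0, 0.3)
    )))
    subj_reactivity <- delta / t_speak
    us <- runif(n, 0.6, 0.95)
    subj_recovery <- -us * delta / (off[["T5"]] - t_speak)

    covariates <- tibble(
      participant_id = pid, group = group, sex = sex,
      gad7 = gad7, pss = pss, bmi = bmi, diet = diet,
      birth_mode = birth_mode, early_nutrition = early_nutrition,
      baseline_log_cortisol = baseline_log
    )
    truth <- tibble(
      participant_id = pid, group = group,
      shannon = shannon, shannon_z = zdiv,
      latent_reactivity = reactivity, latent_recovery = recovery,
      peak_label = peak_label,
      latent_subj_reactivity = subj_reactivity,
      latent_subj_recovery = subj_recovery,
      subj_peak_label = subj_peak_label,
      rating_baseline = rating_baseline
    )
    attr(truth, "effect_sizes") <- es

    structure(
      list(config = config, asv_counts = mb$counts, taxonomy = mb$taxonomy,
           producer_map = mb$producer_map, covariates = covariates,
           truth = truth, saliva = NULL, ratings = NULL),
      class = "synthetic_cohort"
    )
  })
}

#' Render saliva and rating trajectories from latent slopes
#'
#' Inverts the slope definitions: each participant's 7-point log-cortisol
#' series is constructed so that the peak sits at the drawn T3/T4 label,
#' the rise from T2 to the peak equals the latent reactivity times the
#' elapsed minutes, and the fall from peak to T5 equals the latent recovery
#' times the elapsed minutes. Applying [reactivity_slope()] and
#' [recovery_slope()] to the rendered series therefore recovers the latents
#' to numerical precision. Cortisol is emitted on the raw nmol/L scale
#' (positive by construction via the exponential); ratings stay on the raw
#' Likert scale and are kept continuous so the round trip is exact.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param config The cohort's configuration (defaults to `cohort$config`).
#' @return The cohort with long tibbles `saliva` and `ratings` filled in.
#' @export
render_trajectories <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  off <- config$timepoint_offsets
  tr <- cohort$truth
  base <- cohort$covariates$baseline_log_cortisol

  logv <- t(vapply(seq_len(nrow(tr)), function(i) {
    series_from_slopes(
      base = base[i], r = tr$latent_reactivity[i],
      rec = tr$latent_recovery[i], peak = tr$peak_label[i], off = off,
      pre_bumps = c(T0 = 0.05, T1 = 0.03), tail_frac = 0.4
    )
  }, numeric(7)))
  raw <- exp(logv)
  if (any(!is.finite(raw) | raw <= 0)) {
    abort("rendered cortisol values must be positive and finite")
  }
  cohort$saliva <- as_long_series(raw, tr$participant_id, off)

  ratev <- t(vapply(seq_len(nrow(tr)), function(i) {
    v <- series_from_slopes(
      base = tr$rating_baseline[i], r = tr$latent_subj_reactivity[i],
      rec = tr$latent_subj_recovery[i], peak = tr$subj_peak_label[i],
      off = off, pre_bumps = c(T0 = 0, T1 = 0), tail_frac = 0.3
    )
    v[["T6"]] <- max(v[["T6"]], 1)  # decorative tail stays on the scale
    v
  }, numeric(7)))
  cohort$ratings <- as_long_series(ratev, tr$participant_id, off)
  cohort
}

# one 7-point series from (baseline, reactivity, recovery, peak label):
# exact inversion on T2..T5, decorative values elsewhere
series_from_slopes <- function(base, r, rec, peak, off, pre_bumps, tail_frac) {
  v <- setNames(numeric(7), paste0("T", 0:6))
  t_peak <- off[[peak]]
  v[["T2"]] <- base
  v_peak <- base + r * t_peak
  v[["T5"]] <- v_peak + rec * (off[["T5"]] - t_peak)
  if (peak == "T3") {
    v[["T3"]] <- v_peak
    # decline continues after the peak; never exceed it (ties resolve to T3)
    v[["T4"]] <- min(v_peak, v_peak + rec * (off[["T4"]] - off[["T3"]]))
  } else {
    v[["T4"]] <- v_peak
    v[["T3"]] <- min(base + 0.9 * r * off[["T3"]], v_peak - 1e-3)
  }
  v[["T0"]] <- base + pre_bumps[["T0"]]
  v[["T1"]] <- base + pre_bumps[["T1"]]
  v[["T6"]] <- v[["T5"]] + tail_frac * rec * (off[["T6"]] - off[["T5"]])
  v
}

as_long_series <- function(values, pids, off) {
  tibble(
    participant_id = rep(pids, each = 7),
    timepoint = rep(paste0("T", 0:6), length(pids)),
    minutes = rep(as.numeric(off), length(pids)),
    value = as.numeric(t(values))
  )
}

standardize <- function(x) {
  s <- sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat(sprintf("  %d participants (%d stress / %d control), %d ASVs\n",
              nrow(x$covariates), x$config$n_stress, x$config$n_control,
              ncol(x$asv_counts)))
  cat(sprintf("  trajectories rendered: %s\n", !is.null(x$saliva)))
  invisible(x)
}
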