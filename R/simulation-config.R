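#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic-data module: cohort composition, the
#' Dirichlet-multinomial microbiome model, the producer-capacity calibration
#' targets, the linear effect sizes planted on the latent cortisol reactivity
#' slope, and the saliva sampling schedule. Defaults reproduce the study
#' conditions the pipeline is built for: a stress group of 35 and a control
#' group of 39, seven sampling timepoints (two pre-stress days collapsed onto
#' one minute axis relative to stress induction at T2), butyrate producers
#' summing to about 29% of the community and propionate producers to about
#' 89%, and a positive diversity-by-group interaction on the reactivity slope
#' of 0.003 log-nmol/L per minute per standardized diversity unit.
#'
#' @param n_stress,n_control Participants per group (both >= 2).
#' @param n_genera,n_asvs Number of genera and of ASVs distributed over them
#'   (`n_asvs >= n_genera`).
#' @param library_size_range Length-2 integer vector; each sample's library
#'   size is drawn uniformly from this range.
#' @param dirichlet_concentration Total concentration of the Dirichlet prior
#'   over ASV proportions; larger values give samples closer to the cohort
#'   base composition.
#' @param producer_targets Named numeric vector (`butyrate`, `propionate`),
#'   target expected summed relative abundance of producer genera, in [0, 1].
#' @param effect_sizes Named list of planted coefficients on the latent
#'   reactivity slope (log-nmol/L per minute per standardized predictor):
#'   `beta_intercept`, `beta_sex`, `beta_anxiety`, `beta_pss`,
#'   `beta_baseline`, `beta_div_main`, `beta_div_by_group`, `beta_group`.
#' @param noise_sd Standard deviation of the latent reactivity noise (> 0).
#' @param timepoint_offsets Named numeric vector T0..T6 of minutes relative
#'   to stress induction (T2 = 0); strictly increasing.
#' @param seed Integer seed making the whole cohort reproducible.
#'
#' @return A list of class `stress_sim_config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_stress = 5, n_control = 5, seed = 1)
#' cfg$producer_targets
simulation_config <- function(n_stress = 35,
                              n_control = 39,
                              n_genera = 60,
                              n_asvs = 240,
                              library_size_range = c(6000L, 20000L),
                              dirichlet_concentration = 300,
                              producer_targets = c(butyrate = 0.29,
                                                   propionate = 0.89),
                              effect_sizes = list(),
                              noise_sd = 0.004,
                              timepoint_offsets = c(T0 = -77, T1 = -57,
                                                    T2 = 0, T3 = 23, T4 = 40,
                                                    T5 = 59, T6 = 84),
                              seed = 1L) {
  default_effects <- list(
    beta_intercept    = -0.006,
    beta_sex          = 0.003,
    beta_anxiety      = 0.004,
    beta_pss          = -0.003,
    beta_baseline     = -0.002,
    beta_div_main     = 0.0004,
    beta_div_by_group = 0.003,
    beta_group        = 0.007
  )
  bad <- setdiff(names(effect_sizes), names(default_effects))
  if (length(bad) > 0) {
    abort(paste0("unknown effect size(s): ", paste(bad, collapse = ", ")))
  }
  effect_sizes <- modifyList(default_effects, as.list(effect_sizes))

  cfg <- list(
    n_stress = as.integer(n_stress),
    n_control = as.integer(n_control),
    n_genera = as.integer(n_genera),
    n_asvs = as.integer(n_asvs),
    library_size_range = as.integer(library_size_range),
    dirichlet_concentration = dirichlet_concentration,
    producer_targets = producer_targets,
    effect_sizes = effect_sizes,
    noise_sd = noise_sd,
    timepoint_offsets = timepoint_offsets,
    seed = as.integer(seed)
  )
  class(cfg) <- "stress_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "stress_sim_config"))
  if (cfg$n_stress < 2 || cfg$n_control < 2) {
    abort("n_stress and n_control must both be >= 2")
  }
  if (cfg$n_genera > cfg$n_asvs) {
    abort("invalid configuration: n_genera exceeds n_asvs")
  }
  if (length(cfg$library_size_range) != 2 ||
      min(cfg$library_size_range) < 1) {
    abort("library_size_range must be two integers with minimum >= 1")
  }
  if (cfg$dirichlet_concentration <= 0) {
    abort("dirichlet_concentration must be positive")
  }
  tg <- cfg$producer_targets
  if (!all(c("butyrate", "propionate") %in% names(tg)) ||
      any(tg < 0) || any(tg > 1)) {
    abort("producer_targets must name butyrate and propionate, values in [0, 1]")
  }
  if (cfg$noise_sd <= 0) abort("noise_sd must be > 0")
  off <- cfg$timepoint_offsets
  if (!identical(names(off), paste0("T", 0:6))) {
    abort("timepoint_offsets must be named T0..T6")
  }
  if (any(diff(off) <= 0)) abort("timepoint offsets must be strictly increasing")
  if (off[["T2"]] != 0) abort("T2 must sit at 0 minutes (stress induction)")
  invisible(cfg)
}

#' @export
print.stress_sim_config <- function(x, ...) {
  cat("<stress_sim_config>\n")
  cat(sprintf("  groups: %d stress / %d control\n", x$n_stress, x$n_control))
  cat(sprintf("  microbiome: %d ASVs in %d genera, library %d-%d, concentration %g\n",
              x$n_asvs, x$n_genera, x$library_size_range[1],
              x$library_size_range[2], x$dirichlet_concentration))
  cat(sprintf("  producer targets: butyrate %.2f, propionate %.2f\n",
              x$producer_targets[["butyrate"]], x$producer_targets[["propionate"]]))
  cat(sprintf("  diversity-by-group effect: %g, noise sd %g, seed %d\n",
              x$effect_sizes$beta_div_by_group, x$noise_sd, x$seed))
  invisible(x)
}
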