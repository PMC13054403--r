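#' Simulate an ASV count table with taxonomy and SCFA producer annotation
#'
#' Draws a synthetic gut community: genus base abundances follow a log-normal
#' rank-abundance curve, ASVs are nested within genera, and per-sample counts
#' are Dirichlet-multinomial around the cohort base composition with library
#' sizes uniform over `config$library_size_range`. Genera are flagged as
#' butyrate and/or propionate producers greedily from the most abundant genus
#' down, stopping at the step that lands closest to the configured target
#' expected summed relative abundance, so the cohort-mean producer capacity
#' is calibrated to `config$producer_targets` by construction.
#'
#' @param config A [simulation_config()].
#' @param n_samples Number of stool samples; defaults to
#'   `n_stress + n_control`.
#' @param sample_ids Optional character vector of sample labels.
#'
#' @return A list of class `synthetic_microbiome` with elements `counts`
#'   (integer matrix, samples x ASVs), `taxonomy` (tibble with columns
#'   `asv_id`, `domain` .. `genus`) and `producer_map` (tibble with columns
#'   `genus`, `butyrate`, `propionate`).
#' @export
#' @examples
#' mb <- simulate_microbiome(simulation_config(n_stress = 3, n_control = 3))
#' dim(mb$counts)
simulate_microbiome <- function(config,
                                n_samples = config$n_stress + config$n_control,
                                sample_ids = NULL) {
  validate_sim_config(config)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("P%03d", seq_len(n_samples))
  }
  stopifnot(length(sample_ids) == n_samples)

  with_seed_(config$seed, {
    ng <- config$n_genera
    na <- config$n_asvs

    # log-normal rank-abundance curve over genera
    genus_prop <- sort(rlnorm(ng, meanlog = 0, sdlog = 1), decreasing = TRUE)
    genus_prop <- genus_prop / sum(genus_prop)
    genus_ids <- sprintf("Genus_%02d", seq_len(ng))

    phyla <- c("Firmicutes", "Bacteroidota", "Actinobacteriota",
               "Proteobacteria", "Verrucomicrobiota", "Desulfobacterota")
    genus_phylum <- sample(phyla, ng, replace = TRUE,
                           prob = c(0.45, 0.25, 0.12, 0.10, 0.05, 0.03))

    # nest ASVs in genera: one guaranteed ASV each, remainder abundance-weighted
    extra <- c(rmultinom(1, na - ng, prob = genus_prop))
    asv_per_genus <- 1L + extra
    asv_genus <- rep(genus_ids, asv_per_genus)
    asv_ids <- sprintf("ASV_%04d", seq_len(na))
    split_w <- rgamma(na, shape = 1.5)
    asv_prop <- unlist(lapply(seq_len(ng), function(g) {
      idx <- which(asv_genus == genus_ids[g])
      w <- split_w[idx]
      genus_prop[g] * w / sum(w)
    }), use.names = FALSE)

    producer_map <- tibble(
      genus = genus_ids,
      butyrate = flag_producers(genus_prop, config$producer_targets[["butyrate"]]),
      propionate = flag_producers(genus_prop, config$producer_targets[["propionate"]])
    )
    # only producer genera belong in the map (non-producers carry no entry)
    producer_map <- producer_map[producer_map$butyrate | producer_map$propionate, ]
    producer_map <- producer_map[order(producer_map$genus), ]

    alpha <- asv_prop * config$dirichlet_concentration
    lib_range <- config$library_size_range
    counts <- t(vapply(seq_len(n_samples), function(i) {
      lib <- if (lib_range[1] == lib_range[2]) lib_range[1] else
        sample(seq(lib_range[1], lib_range[2]), 1)
      p <- rgamma(na, shape = alpha)
      if (sum(p) == 0) p <- rep(1, na)
      c(rmultinom(1, lib, prob = p / sum(p)))
    }, integer(na)))
    dimnames(counts) <- list(sample_ids, asv_ids)

    taxonomy <- tibble(
      asv_id = asv_ids,
      domain = "Bacteria",
      phylum = genus_phylum[match(asv_genus, genus_ids)],
      class = paste0(genus_phylum[match(asv_genus, genus_ids)], "_c"),
      order = paste0(genus_phylum[match(asv_genus, genus_ids)], "_o"),
      family = paste0(sub("Genus", "Family", asv_genus)),
      genus = asv_genus
    )

    structure(
      list(counts = counts, taxonomy = taxonomy, producer_map = producer_map),
      class = "synthetic_microbiome"
    )
  })
}

# Greedy nearest-step producer flagging: walk genera from most to least
# abundant and flag each one whenever doing so moves the cumulative expected
# producer abundance closer to the target. Granularity is bounded by the
# smallest genus share, so the expected capacity lands essentially on target.
flag_producers <- function(genus_prop, target) {
  flags <- logical(length(genus_prop))
  cum <- 0
  for (i in seq_along(genus_prop)) {
    if (abs(cum + genus_prop[i] - target) < abs(cum - target)) {
      flags[i] <- TRUE
      cum <- cum + genus_prop[i]
    }
  }
  flags
}
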