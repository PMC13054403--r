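#' Rarefy an ASV count table to a common depth
#'
#' Subsamples each sample's reads uniformly without replacement (multivariate
#' hypergeometric, one draw per sample) to exactly `depth` reads, removing
#' sequencing-depth bias before diversity is computed. Delegates the draw to
#' [vegan::rrarefy()] under a fixed seed.
#'
#' @param counts Integer matrix, samples x ASVs, non-negative.
#' @param depth Target depth; defaults to the minimum sample total (the
#'   convention for 16S libraries; a fixed depth such as 5991 can be pinned).
#' @param seed Integer seed; the draw is deterministic given it.
#'
#' @return An integer matrix with every row summing to `depth`.
#' @export
#' @examples
#' m <- matrix(c(9000L, 1000L, 500L, 9500L), 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), c("x", "y")))
#' rowSums(rarefy_counts(m, depth = 1000, seed = 1))
rarefy_counts <- function(counts, depth = NULL, seed = 1L) {
  check_counts(counts)
  totals <- rowSums(counts)
  if (is.null(depth)) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth < 1) abort("depth must be >= 1")
  shallow <- totals < depth
  if (any(shallow)) {
    abort(paste0(
      "cannot rarefy to depth ", depth, "; sample(s) below depth: ",
      paste(rownames(counts)[shallow], collapse = ", ")
    ))
  }
  out <- with_seed_(seed, withCallingHandlers(
    vegan::rrarefy(counts, sample = depth),
    # vegan nags when a table looks unusually deep; counts are validated above
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  ))
  storage.mode(out) <- "integer"
  out
}

#' Convert counts to within-sample relative abundances
#'
#' @param counts Non-negative numeric matrix, samples x taxa, with positive
#'   sample totals.
#' @return A numeric matrix whose rows sum to 1.
#' @export
relative_abundance <- function(counts) {
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    abort(paste0("all-zero sample(s): ",
                 paste(rownames(counts)[totals <= 0], collapse = ", ")))
  }
  sweep(counts, 1, totals, "/")
}

#' Zero out rare ASVs within each sample
#'
#' Within each sample, ASVs whose relative abundance is strictly below
#' `threshold` (default 0.1%) are set to zero; an ASV at exactly the
#' threshold is retained. ASVs left with zero counts in every sample are
#' dropped from the table. Counts are not renormalized afterwards:
#' downstream relative abundances are recomputed from the filtered counts.
#'
#' @param counts Integer matrix, samples x ASVs, positive sample totals.
#' @param threshold Within-sample relative-abundance cutoff in [0, 1).
#' @return The filtered count matrix.
#' @export
filter_rare_asvs <- function(counts, threshold = 0.001) {
  check_counts(counts)
  if (threshold < 0 || threshold >= 1) abort("threshold must lie in [0, 1)")
  rel <- relative_abundance(counts)
  counts[rel < threshold] <- 0L
  keep <- colSums(counts) > 0
  counts[, keep, drop = FALSE]
}

#' Aggregate a sample-by-ASV table at a taxonomic rank
#'
#' Sums counts (or relative abundances) over ASVs sharing the same taxon at
#' `rank`. ASVs with a missing or "unassigned" taxon are pooled into one
#' explicit `"unassigned"` column. Per-sample totals are conserved exactly.
#'
#' @param table Numeric matrix, samples x ASVs.
#' @param taxonomy Tibble/data frame with column `asv_id` and rank columns
#'   (`domain`, `phylum`, ..., `genus`) covering every ASV in `table`.
#' @param rank Rank name to aggregate at, e.g. `"genus"` or `"phylum"`.
#' @return A numeric matrix, samples x taxa at `rank`.
#' @export
aggregate_at_rank <- function(table, taxonomy, rank = "genus") {
  if (!rank %in% names(taxonomy)) {
    abort(paste0("rank '", rank, "' not present in taxonomy"))
  }
  missing_asv <- setdiff(colnames(table), taxonomy$asv_id)
  if (length(missing_asv) > 0) {
    abort(paste0("ASV(s) missing from taxonomy: ",
                 paste(head(missing_asv, 5), collapse = ", ")))
  }
  taxa <- taxonomy[[rank]][match(colnames(table), taxonomy$asv_id)]
  taxa[is.na(taxa) | taxa == ""] <- "unassigned"
  t(rowsum(t(table), group = taxa))
}

#' Per-sample alpha diversity
#'
#' Shannon entropy (natural log, nats), inverse Simpson (effective number of
#' equally abundant taxa) and observed richness, computed from within-sample
#' proportions via [vegan::diversity()]. By convention these are taken from
#' the rarefied (and rare-ASV-filtered) table.
#'
#' @param counts Numeric matrix, samples x taxa, positive sample totals.
#' @return A tibble with columns `sample_id`, `shannon`, `inverse_simpson`,
#'   `observed`.
#' @export
#' @examples
#' m <- matrix(rep(25L, 4), 1, dimnames = list("s1", paste0("a", 1:4)))
#' alpha_diversity(m)  # shannon = log(4), inverse_simpson = 4
alpha_diversity <- function(counts) {
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    abort(paste0("all-zero sample(s): ",
                 paste(rownames(counts)[totals <= 0], collapse = ", ")))
  }
  tibble(
    sample_id = rownames(counts) %||% sprintf("S%03d", seq_len(nrow(counts))),
    shannon = as.numeric(vegan::diversity(counts, index = "shannon")),
    inverse_simpson = as.numeric(vegan::diversity(counts, index = "invsimpson")),
    observed = as.integer(rowSums(counts > 0))
  )
}

#' Firmicutes/Bacteroidetes ratio per sample
#'
#' Ratio of summed Firmicutes to summed Bacteroidetes relative abundance, a
#' coarse compositional index. Samples with no Bacteroidetes reads get `NA`
#' (with a warning), never infinity. Both the classical phylum names and
#' their current SILVA/GTDB spellings (Bacillota, Bacteroidota) are matched.
#'
#' @param counts Numeric matrix, samples x ASVs.
#' @param taxonomy Taxonomy table with a `phylum` rank (see
#'   [aggregate_at_rank()]).
#' @return A tibble with columns `sample_id`, `fb_ratio`.
#' @export
fb_ratio <- function(counts, taxonomy) {
  phy <- aggregate_at_rank(relative_abundance(counts), taxonomy, "phylum")
  firm_cols <- colnames(phy) %in% c("Firmicutes", "Bacillota")
  bact_cols <- colnames(phy) %in% c("Bacteroidetes", "Bacteroidota")
  firm <- rowSums(phy[, firm_cols, drop = FALSE])
  bact <- rowSums(phy[, bact_cols, drop = FALSE])
  ratio <- ifelse(bact > 0, firm / bact, NA_real_)
  if (anyNA(ratio)) {
    warn(paste0("F/B ratio undefined (no Bacteroidetes) for sample(s): ",
                paste(rownames(phy)[is.na(ratio)], collapse = ", ")))
  }
  tibble(sample_id = rownames(phy), fb_ratio = as.numeric(ratio))
}

#' Run the full microbiome profiling chain
#'
#' Convenience wrapper applying the canonical order: rarefy to a common
#' depth, zero rare ASVs, then compute genus-level relative abundances,
#' alpha diversity and the F/B ratio from the processed table.
#'
#' @inheritParams rarefy_counts
#' @inheritParams filter_rare_asvs
#' @param taxonomy Taxonomy table covering every ASV.
#' @param diversity_on Compute diversity on the `"filtered"` (default) or
#'   merely `"rarefied"` table.
#' @return A list with elements `rarefied`, `filtered` (count matrices),
#'   `genus_rel` (genus-level relative abundances), `diversity` and
#'   `fb` (tibbles).
#' @export
profile_microbiome <- function(counts, taxonomy, depth = NULL,
                               threshold = 0.001, seed = 1L,
                               diversity_on = c("filtered", "rarefied")) {
  diversity_on <- match.arg(diversity_on)
  rarefied <- rarefy_counts(counts, depth = depth, seed = seed)
  filtered <- filter_rare_asvs(rarefied, threshold = threshold)
  div_tab <- if (diversity_on == "filtered") filtered else rarefied
  list(
    rarefied = rarefied,
    filtered = filtered,
    genus_rel = aggregate_at_rank(relative_abundance(filtered), taxonomy, "genus"),
    diversity = alpha_diversity(div_tab),
    fb = fb_ratio(filtered, taxonomy)
  )
}

check_counts <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) < 1 || ncol(counts) < 1) {
    abort("counts must be a matrix with at least 1 sample and 1 ASV")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  invisible(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
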