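#' Write a synthetic cohort to plain-text fixture files
#'
#' Serializes every pipeline input to the on-disk formats the pipeline
#' reads: ASV counts as TSV (rows = ASVs, columns = samples), taxonomy TSV,
#' producer map as long TSV (`genus`, `scfa`), saliva and rating
#' trajectories and covariates as CSV, plus a YAML manifest recording the
#' seed and a hash of the generating configuration. Writing the same cohort
#' twice produces byte-identical files.
#'
#' @param cohort A rendered [simulate_cohort()] result (see
#'   [render_trajectories()]).
#' @param dir Output directory, created if needed.
#' @return The manifest list, invisibly.
#' @export
write_fixtures <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$saliva)) {
    abort("cohort has no trajectories; call render_trajectories() first")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("cannot create directory ", dir))

  counts_df <- as_tibble(t(cohort$asv_counts), rownames = "asv_id")
  readr::write_tsv(counts_df, file.path(dir, "asv_counts.tsv"), progress = FALSE)
  readr::write_tsv(cohort$taxonomy, file.path(dir, "taxonomy.tsv"),
                   progress = FALSE)

  pm <- cohort$producer_map
  long <- bind_rows(
    tibble(genus = pm$genus[pm$butyrate], scfa = "butyrate"),
    tibble(genus = pm$genus[pm$propionate], scfa = "propionate")
  ) %>% arrange(.data$genus, .data$scfa)
  readr::write_tsv(long, file.path(dir, "producer_map.tsv"), progress = FALSE)

  readr::write_csv(cohort$saliva, file.path(dir, "saliva.csv"), progress = FALSE)
  readr::write_csv(cohort$ratings, file.path(dir, "ratings.csv"), progress = FALSE)
  readr::write_csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"), progress = FALSE)

  manifest <- list(
    seed = cohort$config$seed,
    config_hash = rlang::hash(cohort$config),
    files = c("asv_counts.tsv", "taxonomy.tsv", "producer_map.tsv",
              "saliva.csv", "ratings.csv", "covariates.csv", "truth.csv")
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Read pipeline input fixtures from a directory
#'
#' Inverse of [write_fixtures()]: returns the count matrix (samples x ASVs),
#' taxonomy, producer map (wide logical form), trajectories and covariates.
#'
#' @param dir Directory holding the fixture files.
#' @return A named list of pipeline inputs.
#' @export
read_fixtures <- function(dir) {
  counts_df <- readr::read_tsv(file.path(dir, "asv_counts.tsv"),
                               col_types = readr::cols(), progress = FALSE)
  counts <- t(as.matrix(counts_df[-1]))
  colnames(counts) <- counts_df$asv_id
  storage.mode(counts) <- "integer"

  series_cols <- readr::cols(
    participant_id = "c", timepoint = "c", minutes = "d", value = "d"
  )
  list(
    counts = counts,
    taxonomy = readr::read_tsv(file.path(dir, "taxonomy.tsv"),
                               col_types = readr::cols(.default = "c"),
                               progress = FALSE),
    producer_map = load_producer_map(file.path(dir, "producer_map.tsv")),
    saliva = readr::read_csv(file.path(dir, "saliva.csv"),
                             col_types = series_cols, progress = FALSE),
    ratings = readr::read_csv(file.path(dir, "ratings.csv"),
                              col_types = series_cols, progress = FALSE),
    covariates = readr::read_csv(file.path(dir, "covariates.csv"),
                                 col_types = readr::cols(), progress = FALSE),
    manifest = yaml::read_yaml(file.path(dir, "manifest.yaml"))
  )
}
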