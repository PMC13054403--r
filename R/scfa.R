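#' Load a genus-level SCFA producer annotation
#'
#' Reads a two-column TSV (`genus`, `scfa`) mapping genera to the short-chain
#' fatty acids they are annotated to produce. Production is treated as a
#' binary phenotype at the genus level: a genus carrying several biosynthesis
#' pathways for the same SCFA is counted once, so duplicate rows collapse.
#' Only butyrate and propionate are admissible; acetate is excluded by design
#' because its biosynthesis pathway is near-ubiquitous among gut bacteria and
#' would not discriminate between communities.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `genus`, `butyrate`, `propionate`
#'   (logicals), one row per genus.
#' @export
load_producer_map <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("genus", "scfa") %in% names(raw))) {
    abort("producer map must have columns 'genus' and 'scfa'")
  }
  raw$genus <- trimws(raw$genus)
  raw$scfa <- trimws(tolower(raw$scfa))
  bad_row <- which(is.na(raw$genus) | raw$genus == "" |
                     is.na(raw$scfa) | raw$scfa == "")
  if (length(bad_row) > 0) {
    abort(paste0("malformed producer-map row(s) at line(s): ",
                 paste(bad_row + 1L, collapse = ", ")))
  }
  if (any(raw$scfa == "acetate")) {
    abort(paste0(
      "acetate rows are not admitted: acetate biosynthesis is present in ",
      "almost all gut bacteria and is excluded from capacity scoring ",
      "(line(s) ", paste(which(raw$scfa == "acetate") + 1L, collapse = ", "), ")"
    ))
  }
  unknown <- setdiff(unique(raw$scfa), c("butyrate", "propionate"))
  if (length(unknown) > 0) {
    abort(paste0("unknown SCFA name(s): ", paste(unknown, collapse = ", ")))
  }
  producer_map_from_long(raw)
}

producer_map_from_long <- function(long) {
  genera <- sort(unique(long$genus))
  tibble(
    genus = genera,
    butyrate = genera %in% long$genus[long$scfa == "butyrate"],
    propionate = genera %in% long$genus[long$scfa == "propionate"]
  )
}

#' Inferred SCFA production capacity per sample
#'
#' The summed relative abundance of all genera annotated as producers of the
#' given SCFA: one aggregate value per SCFA per sample, a taxonomy-based
#' proxy for functional potential (not a metabolite measurement). Genus
#' matching is exact and case-sensitive after whitespace trimming; genera
#' absent from the map contribute zero.
#'
#' @param genus_rel Numeric matrix of genus-level relative abundances,
#'   samples x genera (rows sum to at most 1; rare-ASV filtering may have
#'   removed mass).
#' @param map Producer map as returned by [load_producer_map()].
#' @param scfa `"butyrate"` or `"propionate"`.
#' @return A tibble with columns `sample_id`, `scfa`, `capacity` (fraction
#'   in [0, 1]).
#' @export
#' @examples
#' rel <- matrix(c(0.3, 0.2, 0.5), 1, dimnames = list("s1", c("A", "B", "C")))
#' map <- tibble::tibble(genus = c("A", "B"),
#'                       butyrate = c(TRUE, TRUE),
#'                       propionate = c(FALSE, TRUE))
#' capacity_score(rel, map, "butyrate")$capacity  # 0.5
capacity_score <- function(genus_rel, map, scfa = c("butyrate", "propionate")) {
  scfa <- match.arg(scfa)
  flagged <- trimws(map$genus[map[[scfa]]])
  cols <- trimws(colnames(genus_rel)) %in% flagged
  capacity <- rowSums(genus_rel[, cols, drop = FALSE])
  tibble(
    sample_id = rownames(genus_rel) %||% sprintf("S%03d", seq_len(nrow(genus_rel))),
    scfa = scfa,
    capacity = as.numeric(capacity)
  )
}
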