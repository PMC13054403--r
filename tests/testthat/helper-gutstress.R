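# shared fixtures, all generated in code

# a small, fast cohort configuration for unit tests
tiny_config <- function(..., seed = 11L) {
  simulation_config(
    n_stress = 8, n_control = 8, n_genera = 15, n_asvs = 50,
    library_size_range = c(2000L, 3000L), dirichlet_concentration = 200,
    seed = seed, ...
  )
}

# long saliva series for one participant from named T0..T6 values
make_series <- function(values, pid = "p1",
                        minutes = c(T0 = -77, T1 = -57, T2 = 0, T3 = 23,
                                    T4 = 40, T5 = 59, T6 = 84)) {
  tp <- names(values)
  tibble::tibble(
    participant_id = pid, timepoint = tp,
    minutes = unname(minutes[tp]), value = unname(values)
  )
}

# small deterministic count matrix
toy_counts <- function() {
  m <- matrix(
    c(600L, 300L, 90L, 10L,
      250L, 250L, 400L, 100L),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("s1", "s2"), paste0("ASV_", 1:4))
  )
  m
}

toy_taxonomy <- function() {
  tibble::tibble(
    asv_id = paste0("ASV_", 1:4),
    domain = "Bacteria",
    phylum = c("Firmicutes", "Firmicutes", "Bacteroidota", "Proteobacteria"),
    class = "c", order = "o", family = "f",
    genus = c("G1", "G1", "G2", "G3")
  )
}
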