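# shared fixture builders and a lazily computed full-pipeline run used by the
# acceptance tests (computed once per session)

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                  collapse = "")

# substitute exactly k positions of a sequence (new symbol always different)
substitute_positions <- function(seq, k, alphabet = c("A", "C", "G", "T")) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(alphabet, v[p]), 1)
  paste(v, collapse = "")
}

# tiny genome_assembly wrapper
toy_genome <- function(id, seq, species = "sp", clade = NULL) {
  genome_assembly(id, setNames(Biostrings::DNAStringSet(seq),
                               paste0(id, "_c1")),
                  species_label = species, clade_label = clade)
}

# brute-force family clustering: all-pairs metrics + connected components
brute_force_families <- function(proteins, id_threshold = 0.80,
                                 cov_threshold = 0.80) {
  build_families(proteins, id_threshold, cov_threshold, brute_force = TRUE)
}

# the default-condition synthetic study shared by the end-to-end tests:
# 4 clades x 5 strains + outgroup, default divergences, fixed seed
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_dataset <- function() {
  if (is.null(.acceptance_cache$sim))
    .acceptance_cache$sim <- simulate_dataset(sim_config(seed = 101L))
  .acceptance_cache$sim
}

acceptance_pipeline <- function() {
  if (is.null(.acceptance_cache$pipe)) {
    sim <- acceptance_dataset()
    .acceptance_cache$pipe <- suppressWarnings(suppressMessages(
      run_pipeline(sim$genomes, sim$annotations, sim$proteins, seed = 202L)))
  }
  .acceptance_cache$pipe
}
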