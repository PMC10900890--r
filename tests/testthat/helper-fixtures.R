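# Small in-code fixtures shared across tests.

# Toy catalog: ring branches of 3 + 2 shared, 3 loop families, so the
# completeness denominator (best branch incl. shared + loop) is 8.
toyCatalog <- function() {
  fam <- data.frame(
    family_id = c("aer1", "aer2", "aer3",
                  "ana1", "ana2", "ana3",
                  "sh1", "sh2",
                  "loop1", "loop2", "loop3",
                  "use1", "use2", "use3",
                  sprintf("sc%02d", 1:6),
                  "pre1", "tra1"),
    pathway_section = c(rep("ring_aerobic", 3), rep("ring_anaerobic", 3),
                        rep("ring_shared", 2), rep("loop", 3),
                        rep("user_dependent", 3), rep("single_copy", 6),
                        "precursor", "transport_salvage"),
    stringsAsFactors = FALSE)
  GeneCatalog(fam, version = "toy")
}

randomHits <- function(n, genomes = sprintf("G%02d", 1:5),
                       families = c("aer1", "loop1", "sc01")) {
  g <- sample(genomes, n, replace = TRUE)
  data.frame(genome_id = g,
             protein_id = paste0(g, "_", seq_len(n)),
             family_id = sample(families, n, replace = TRUE),
             e_value = 10^runif(n, -12, -1),
             bit_score = runif(n, 20, 300),
             stringsAsFactors = FALSE)
}

# Phenotype category ordered worst-to-best for monotonicity checks.
phenotypeRank <- function(x) {
  match(x, rev(phenotypeLevels()))
}
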