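# Shared miniature study configurations. Sizes are kept small: these
# fixtures exercise contracts, not statistical power.

tiny_config <- function(...) {
  generator_config(
    n_families = 200, n_snps = 60, n_cpgs = 12, n_reference_duos = 1500,
    ...
  )
}

tiny_study <- function(seed = 42, ...) {
  simulate_cohort(tiny_config(...), seed = seed)
}

# Hand-built two-SNP panel for scoring arithmetic tests.
toy_panel <- function() {
  structure(
    data.frame(
      snp_id = c("rs1", "rs2"),
      effect_allele = c("A", "C"),
      other_allele = c("G", "T"),
      freq = c(0.3, 0.6),
      beta_fetal = c(0, 0),
      beta_maternal = c(0, 0),
      beta_own = c(0, 0),
      stringsAsFactors = FALSE
    ),
    class = c("snp_panel", "data.frame")
  )
}
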