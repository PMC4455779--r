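# Shared fixtures: small genomes and experiments built in code.

tiny_genome_config <- function(seed = 1L, n_genes = 60L) {
  genome_config(n_chromosomes = 2L, chrom_length_bp = 3e5,
                n_genes = n_genes, probe_spacing_bp = 500,
                pfam_catalog = c(DOM1 = 6L, DOM2 = 4L), seed = seed)
}

six_class_probs <- function() {
  stats::setNames(rep(1 / 6, 6),
                  c("DownCNV/PAV", "UpPAV", "UpPAV+UpCNV", "UpCNV+DownCNV",
                    "UpCNV", "Multi-Allelic UpCNV"))
}

# A small noise-free experiment covering all six categories.
noise_free_experiment <- function(seed = 5L, n_events = 6L) {
  simulate_sv_experiment(
    tiny_genome_config(), n_events = n_events,
    class_probs = six_class_probs(), carrier_spectrum = "uniform",
    het_prob = 0, cgh_noise_sd = 0,
    coverage = coverage_config(noise = "none"), seed = seed)
}

fixed_cfg <- function(seed = 5L, ...) {
  sv_config(genome = list(n_chromosomes = 2L, chrom_length_bp = 3e5,
                          n_genes = 60L, probe_spacing_bp = 500,
                          paralog_fraction = 0.6),
            thresholds = list(down_sd = 3, up_sd = 2,
                              fixed_lower = -0.5, fixed_upper = 0.5),
            seed = seed, ...)
}

# Direction matrix helper for hand-built calling fixtures.
dir_matrix <- function(genes, genotypes, value = "neutral") {
  matrix(value, length(genes), length(genotypes),
         dimnames = list(genes, genotypes))
}
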