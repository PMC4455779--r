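# Simulation of CGH intensities and resequencing read counts from truth.

#' Sequencing coverage configuration
#'
#' Emulates a NAM-style design: one deeply sequenced hub line, a moderately
#' covered reference genotype and minor lines at low coverage. Read counts
#' per gene are Poisson around depth x gene_length / read_length x copy
#' number (`noise = "none"` replaces the Poisson draw by its rounded mean,
#' for noise-free end-to-end checks).
#'
#' @param hub_depth mean depth of the hub line.
#' @param ref_depth mean depth of the reference genotype.
#' @param minor_depth_range depth range for the remaining test lines,
#'   drawn uniformly.
#' @param read_length_bp read length used to convert depth to counts.
#' @param noise `"poisson"` or `"none"`.
#' @param seed random seed.
#' @return object of class `coverage_config`.
#' @export
coverage_config <- function(hub_depth = 31, ref_depth = 13,
                            minor_depth_range = c(2, 8),
                            read_length_bp = 150L,
                            noise = c("poisson", "none"),
                            seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(hub_depth > 0, ref_depth > 0, all(minor_depth_range > 0),
            length(minor_depth_range) == 2L,
            minor_depth_range[1] <= minor_depth_range[2],
            read_length_bp > 0)
  structure(list(hub_depth = hub_depth, ref_depth = ref_depth,
                 minor_depth_range = minor_depth_range,
                 read_length_bp = as.integer(read_length_bp),
                 noise = noise, seed = as.integer(seed)),
            class = "coverage_config")
}

#' Simulate the CGH probe panel log2 ratios
#'
#' Each probe's expected log2 ratio is `log2(copy_test / copy_ref)` for the
#' single-plant copy state implied by the planted truth (default 1/1 away
#' from events); copy 0 is represented by a residual cross-hybridization
#' floor (`deletion_floor`, default 1/16, so a hemizygous-reference deletion
#' reads near -4). Gaussian noise of SD `cgh_noise_sd` is added per probe.
#' With `cgh_noise_sd = 0` and no planted events every ratio is exactly 0.
#'
#' @param truth an `sv_truth` from [plant_events()].
#' @param genome the `sv_genome` the truth was planted on.
#' @param cgh_noise_sd per-probe Gaussian noise SD on the log2 ratio.
#' @param deletion_floor copy value substituted for 0 in the ratio.
#' @param seed random seed.
#' @return object of class `sv_panel`: list with `probes` (coordinates) and
#'   `ratios` (probes x test-genotypes matrix), plus a `normalized` flag.
#' @export
simulate_cgh <- function(truth, genome, cgh_noise_sd = 0.15,
                         deletion_floor = 1 / 16, seed = 1L) {
  stopifnot(inherits(truth, "sv_truth"), inherits(genome, "sv_genome"),
            cgh_noise_sd >= 0, deletion_floor > 0)
  set.seed(as.integer(seed))
  tests <- truth$genotypes$tests
  ref <- truth$genotypes$reference
  probes <- genome$probes
  n_probe <- nrow(probes)

  # Probe copy states: default 1/1, overridden inside event intervals.
  cp_test <- matrix(1, n_probe, length(tests), dimnames = list(NULL, tests))
  cp_ref <- rep(1, n_probe)
  if (nrow(truth$events)) {
    hits <- GenomicRanges::findOverlaps(
      granges_from0(probes$chrom, probes$start, probes$end),
      granges_from0(truth$events$chrom, truth$events$start,
                    truth$events$end))
    pi <- S4Vectors::queryHits(hits)
    ei <- S4Vectors::subjectHits(hits)
    cp_test[pi, ] <- truth$copies[ei, tests, drop = FALSE]
    cp_ref[pi] <- truth$copies[ei, ref]
  }
  cp_test[cp_test == 0] <- deletion_floor
  cp_ref[cp_ref == 0] <- deletion_floor
  ratios <- log2(cp_test / cp_ref)
  if (cgh_noise_sd > 0) {
    ratios <- ratios + matrix(stats::rnorm(length(ratios), 0, cgh_noise_sd),
                              nrow(ratios))
  }
  dimnames(ratios) <- list(probes$probe_id, tests)
  structure(list(probes = probes, ratios = ratios, normalized = FALSE),
            class = "sv_panel")
}

#' @export
print.sv_panel <- function(x, ...) {
  cat(sprintf("CGH probe panel: %d probes x %d genotypes (%s)\n",
              nrow(x$ratios), ncol(x$ratios),
              if (isTRUE(x$normalized)) "normalized" else "raw"))
  invisible(x)
}

#' Simulate per-gene uniquely-mapped read counts
#'
#' Expected count for gene g in genotype j is
#' `depth_j * length_g / read_length * copy_{gj}` where the copy state is
#' the *bulk* one from the truth (heterogeneous carriers contribute a
#' mixture), so the sequencing channel can disagree with the single-plant
#' CGH channel. Copy 0 gives expected 0, i.e. hard zero-read genes.
#'
#' @param truth an `sv_truth`.
#' @param genome the matching `sv_genome`.
#' @param coverage a [coverage_config()].
#' @return integer matrix genes x genotypes (reference column included),
#'   with attributes `depths` and `read_length_bp`.
#' @export
simulate_counts <- function(truth, genome, coverage = coverage_config()) {
  stopifnot(inherits(truth, "sv_truth"), inherits(genome, "sv_genome"),
            inherits(coverage, "coverage_config"))
  seeds <- derive_seeds(coverage$seed, 2L)
  g <- truth$genotypes
  set.seed(seeds[1])
  depths <- stats::setNames(numeric(length(g$all)), g$all)
  depths[g$reference] <- coverage$ref_depth
  depths[g$tests[1]] <- coverage$hub_depth
  minors <- g$tests[-1]
  depths[minors] <- stats::runif(length(minors), coverage$minor_depth_range[1],
                                 coverage$minor_depth_range[2])

  cp <- truth_gene_copies(truth, genome)$bulk
  lambda <- sweep(cp, 1, genome$genes$length, `*`)
  lambda <- sweep(lambda, 2, depths[colnames(cp)] / coverage$read_length_bp,
                  `*`)
  set.seed(seeds[2])
  counts <- if (coverage$noise == "poisson") {
    matrix(stats::rpois(length(lambda), lambda), nrow(lambda))
  } else {
    round(lambda)
  }
  dimnames(counts) <- dimnames(cp)
  storage.mode(counts) <- "integer"
  attr(counts, "depths") <- depths
  attr(counts, "read_length_bp") <- coverage$read_length_bp
  counts
}

#' Simulate a complete dual-platform experiment
#'
#' Convenience wrapper chaining [generate_annotation()], [plant_events()],
#' [simulate_cgh()] and [simulate_counts()] with sub-seeds derived from one
#' master seed.
#'
#' @param genome_cfg a [genome_config()] (its own seed is overridden).
#' @param n_events,class_probs,carrier_spectrum,het_prob passed to
#'   [plant_events()].
#' @param cgh_noise_sd,deletion_floor passed to [simulate_cgh()].
#' @param coverage a [coverage_config()] (its seed is overridden).
#' @param n_test number of test genotypes.
#' @param seed master seed.
#' @return object of class `sv_experiment`: list with `genome`, `truth`,
#'   `panel`, `counts`, `genotypes`, `deletion_floor`, `seed`.
#' @export
simulate_sv_experiment <- function(genome_cfg = genome_config(),
                                   n_events = 20L,
                                   class_probs = default_class_probs(),
                                   carrier_spectrum = "onebyk",
                                   het_prob = 0.05,
                                   cgh_noise_sd = 0.15,
                                   deletion_floor = 1 / 16,
                                   coverage = coverage_config(),
                                   n_test = 41L,
                                   seed = 1L) {
  seeds <- derive_seeds(seed, 4L)
  genome_cfg$seed <- seeds[1]
  genome <- generate_annotation(genome_cfg)
  genotypes <- panel_genotypes(n_test)
  truth <- plant_events(genome, n_events = n_events,
                        class_probs = class_probs, genotypes = genotypes,
                        carrier_spectrum = carrier_spectrum,
                        het_prob = het_prob, seed = seeds[2])
  panel <- simulate_cgh(truth, genome, cgh_noise_sd = cgh_noise_sd,
                        deletion_floor = deletion_floor, seed = seeds[3])
  coverage$seed <- seeds[4]
  counts <- simulate_counts(truth, genome, coverage)
  structure(list(genome = genome, truth = truth, panel = panel,
                 counts = counts, genotypes = genotypes,
                 deletion_floor = deletion_floor, seed = seed),
            class = "sv_experiment")
}

#' @export
print.sv_experiment <- function(x, ...) {
  cat("Synthetic dual-platform SV experiment\n")
  print(x$genome)
  print(x$truth)
  cat(sprintf("  counts: %d genes x %d genotypes\n", nrow(x$counts),
              ncol(x$counts)))
  invisible(x)
}
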