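# End-to-end orchestration: simulate -> call -> cross-validate -> classify
# -> collapse -> spectra -> neutral comparison -> enrichment.

#' Pipeline configuration
#'
#' Nested parameter blocks for every stage, serializable losslessly to and
#' from YAML. Defaults reproduce the calling parameters the method was
#' designed with (3-SD lower / 2-SD upper thresholds; segmentation
#' min_diff 0.1, min_len 2, acceptance 0.99, 10 permutations; clustering
#' gap 0.75 copies; per-locus recombination 21.54; 10,000 enrichment
#' resamples).
#'
#' @param genome,events,coverage,cgh,thresholds,segmentation,clustering,
#'   coalescent,enrichment stage parameter blocks (lists); see the source
#'   for the member defaults.
#' @param seed master seed.
#' @param verbose emit stage messages.
#' @return list of class `sv_config`.
#' @export
sv_config <- function(genome = list(n_chromosomes = 2L,
                                    chrom_length_bp = 1e6,
                                    n_genes = 200L,
                                    probe_spacing_bp = 500,
                                    paralog_fraction = 0.60),
                      events = list(n_events = 20L,
                                    carrier_spectrum = "onebyk",
                                    het_prob = 0.05),
                      coverage = list(hub_depth = 31, ref_depth = 13,
                                      minor_depth_range = c(2, 8),
                                      read_length_bp = 150L,
                                      noise = "poisson"),
                      cgh = list(noise_sd = 0.15, deletion_floor = 1 / 16),
                      thresholds = list(down_sd = 3, up_sd = 2,
                                        fixed_lower = NULL,
                                        fixed_upper = NULL),
                      segmentation = list(min_diff = 0.1, min_len = 2L,
                                          acceptance = 0.99, n_perm = 10L),
                      clustering = list(gap_min = 0.75, disagree_tol = 2),
                      coalescent = list(rho_locus = 21.54, locus_bp = 14000,
                                        mu = 7e-9, n_loci = 500L),
                      enrichment = list(n_sims = 10000L),
                      seed = 1L,
                      verbose = FALSE) {
  structure(list(genome = genome, events = events, coverage = coverage,
                 cgh = cgh, thresholds = thresholds,
                 segmentation = segmentation, clustering = clustering,
                 coalescent = coalescent, enrichment = enrichment,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "sv_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config an `sv_config`.
#' @param path file path.
#' @export
write_sv_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sv_config
#' @export
read_sv_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(sv_config, raw)
}

stage <- function(name, verbose, expr) {
  if (verbose) message("[svpanel] stage: ", name)
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full structural-variant discovery pipeline
#'
#' Either simulates a dual-platform experiment from the config or analyzes
#' a supplied one, then runs CGH normalization, thresholding and
#' segmentation, gene scoring and probe calls, sequence (RPKM) calls,
#' cross-validation and six-category classification, segment collapsing,
#' Up and Down reference-based frequency spectra, an optional neutral
#' coalescent comparison, domain enrichment and the paralog contrast.
#' Identical config + seed gives identical output.
#'
#' @param config an [sv_config()].
#' @param experiment optional `sv_experiment` to analyze instead of
#'   simulating one.
#' @param run_neutral simulate the neutral comparison spectra.
#' @param run_enrichment run domain enrichment per category.
#' @return object of class `sv_run`; see `summary()` for the category
#'   count table.
#' @export
run_sv_pipeline <- function(config = sv_config(), experiment = NULL,
                            run_neutral = TRUE, run_enrichment = TRUE) {
  stopifnot(inherits(config, "sv_config"))
  vb <- config$verbose
  seeds <- derive_seeds(config$seed, 6L)

  if (is.null(experiment)) {
    experiment <- stage("simulate", vb, {
      gcfg <- do.call(genome_config, config$genome)
      cov <- do.call(coverage_config, config$coverage)
      simulate_sv_experiment(
        genome_cfg = gcfg,
        n_events = config$events$n_events,
        carrier_spectrum = config$events$carrier_spectrum,
        het_prob = config$events$het_prob,
        cgh_noise_sd = config$cgh$noise_sd,
        deletion_floor = config$cgh$deletion_floor,
        coverage = cov,
        seed = seeds[1])
    })
  }
  genome <- experiment$genome
  genotypes <- experiment$genotypes
  floor_ <- experiment$deletion_floor

  panel <- stage("normalize", vb, normalize_ratios(experiment$panel))

  fixed <- !is.null(config$thresholds$fixed_lower)
  cgh_thr <- stage("cgh-thresholds", vb, {
    if (fixed) {
      fixed_thresholds(config$thresholds$fixed_lower,
                       config$thresholds$fixed_upper,
                       colnames(panel$ratios))
    } else {
      compute_thresholds(panel, down_sd = config$thresholds$down_sd,
                         up_sd = config$thresholds$up_sd)
    }
  })

  seg_params <- do.call(segmentation_params,
                        c(config$segmentation, list(seed = seeds[2])))
  segment_calls <- stage("segmentation", vb,
                         call_cgh_segments(panel, cgh_thr, seg_params))

  cgh_scores <- stage("gene-scores", vb,
                      score_genes_cgh(genome, panel, segment_calls))
  probe_calls <- stage("probe-calls", vb,
                       call_probe_cnv(cgh_scores, cgh_thr))

  seq <- stage("seq-calls", vb, {
    thr <- if (fixed) {
      fixed_thresholds(config$thresholds$fixed_lower,
                       config$thresholds$fixed_upper,
                       genotypes$tests)
    } else NULL
    call_seq_all(experiment$counts,
                 stats::setNames(genome$genes$length, genome$genes$gene_id),
                 reference = genotypes$reference, thresholds = thr,
                 down_sd = config$thresholds$down_sd,
                 up_sd = config$thresholds$up_sd)
  })

  candidates <- stage("candidates", vb,
                      candidate_set(genome, segment_calls, probe_calls, seq))
  classification <- stage("classify", vb, {
    crossval_classify(candidates, cgh_scores, seq, cgh_thr,
                      gap_min = config$clustering$gap_min,
                      disagree_tol = config$clustering$disagree_tol,
                      deletion_floor = floor_)
  })

  n_test <- length(genotypes$tests)
  spectra <- stage("segments-sfs", vb, {
    out <- list()
    for (dirn in c("Down", "Up")) {
      segs <- collapse_segments(classification, genome, segment_calls,
                                direction = dirn, retained = seq$retained)
      k <- segment_frequency(segs, probe_calls, seq)
      out[[dirn]] <- list(
        segments = segs, k = k,
        spectrum = build_rsfs(k, n_test = n_test,
                              label = paste0("empirical-", dirn)))
    }
    out
  })

  neutral <- NULL
  if (run_neutral) {
    neutral <- stage("neutral-model", vb, {
      out <- list()
      for (dirn in c("Down", "Up")) {
        S_obs <- sum(spectra[[dirn]]$spectrum)
        if (S_obs == 0) next
        # Watterson theta from the observed event count, spread over the
        # independent simulated loci.
        theta_total <- estimate_theta_locus(S_obs, n_test + 1L)
        params <- popgen_params(
          theta_locus = theta_total / config$coalescent$n_loci,
          n_chrom = n_test + 1L,
          rho_locus = config$coalescent$rho_locus,
          n_loci = config$coalescent$n_loci,
          locus_bp = config$coalescent$locus_bp,
          mu = config$coalescent$mu,
          seed = seeds[3] + match(dirn, c("Down", "Up")))
        haps <- simulate_neutral(params)
        sim_spec <- ascertain_reference(haps)
        out[[dirn]] <- list(
          params = params, spectrum = sim_spec,
          comparison = compare_spectra(spectra[[dirn]]$spectrum, sim_spec,
                                       seed = seeds[4]))
      }
      out
    })
  }

  enrichment <- NULL
  contrast <- NULL
  if (run_enrichment) {
    enrichment <- stage("enrichment", vb, {
      cv <- classification$genes
      out <- list()
      for (cat_ in intersect(SV_CLASSES, cv$category)) {
        lst <- cv$gene_id[cv$cross_validated & cv$category %in% cat_]
        if (length(lst) && nrow(genome$pfam)) {
          out[[cat_]] <- enrich_domains(lst, genome$pfam,
                                        genome$genes$gene_id,
                                        n_sims = config$enrichment$n_sims,
                                        seed = seeds[5])
        }
      }
      out
    })
    contrast <- stage("paralog-contrast", vb, {
      sv_genes <- classification$genes$gene_id[
        classification$genes$cross_validated &
          classification$genes$category %in% SV_CLASSES]
      if (length(sv_genes)) paralog_contrast(sv_genes, genome) else NULL
    })
  }

  structure(list(config = config, experiment = experiment, panel = panel,
                 cgh_thresholds = cgh_thr, segment_calls = segment_calls,
                 cgh_scores = cgh_scores, probe_calls = probe_calls,
                 seq = seq, candidates = candidates,
                 classification = classification, spectra = spectra,
                 neutral = neutral, enrichment = enrichment,
                 paralog = contrast),
            class = "sv_run")
}

#' Category count table in the survey's standard layout
#'
#' One column per SV category; rows split the cross-validated genes by
#' retained-paralog status, plus the total.
#'
#' @param run an `sv_run` (or an `sv_classification` plus `genome`).
#' @param genome required when `run` is an `sv_classification`.
#' @return integer matrix: rows (with paralog / without paralog / total) x
#'   six categories.
#' @export
category_table <- function(run, genome = NULL) {
  if (inherits(run, "sv_run")) {
    classification <- run$classification
    genome <- run$experiment$genome
  } else {
    classification <- run
  }
  cv <- classification$genes[classification$genes$cross_validated &
                               classification$genes$category %in% SV_CLASSES,
                             , drop = FALSE]
  has_par <- !is.na(genome$genes[cv$gene_id, "paralog"])
  f <- factor(cv$category, levels = SV_CLASSES)
  m <- rbind(`with paralog` = table(f[has_par]),
             `without paralog` = table(f[!has_par]))
  rbind(m, total = colSums(m))
}

#' @export
print.sv_run <- function(x, ...) {
  cat("svpanel pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat(sprintf("  candidates: %d; cross-validated SV genes: %d\n",
              length(x$candidates),
              sum(x$classification$genes$cross_validated &
                    x$classification$genes$category %in% SV_CLASSES)))
  cat(sprintf("  Down segments: %d; Up segments: %d\n",
              nrow(x$spectra$Down$segments), nrow(x$spectra$Up$segments)))
  invisible(x)
}

#' @export
summary.sv_run <- function(object, ...) {
  tab <- category_table(object)
  cat("SV category counts (cross-validated genes)\n")
  print(tab)
  if (!is.null(object$paralog)) print(object$paralog)
  if (!is.null(object$neutral)) {
    for (d in names(object$neutral)) {
      cat(sprintf("-- %s spectrum vs neutral --\n", d))
      print(object$neutral[[d]]$comparison)
    }
  }
  invisible(tab)
}
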