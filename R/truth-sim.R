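# Planting of ground-truth structural-variant events on a synthetic genome.

#' Default class mix for planted events
#'
#' Proportions follow the category frequencies typical of a genic SV survey
#' in a selfing crop panel: deletions/PAV dominate, copy-gain classes are
#' the minority.
#' @return named numeric vector over the six categories, summing to 1.
#' @export
default_class_probs <- function() {
  c("DownCNV/PAV" = 0.72, "UpPAV" = 0.065, "UpPAV+UpCNV" = 0.010,
    "UpCNV+DownCNV" = 0.058, "UpCNV" = 0.127, "Multi-Allelic UpCNV" = 0.020)
}

#' Plant structural-variant events with known truth
#'
#' Draws event intervals over the gene catalog (each event overlaps at
#' least one gene and events do not share genes), assigns each a category,
#' a carrier set among the test genotypes and per-genotype copy numbers
#' consistent with the category, and optionally marks carriers as
#' intra-line heterogeneous (bulk-seed copy state differing from the
#' single-plant state).
#'
#' Event lengths are log-normal with a long right tail (median ~2.8 kb,
#' heavy enough that the mean is several-fold larger), mimicking observed
#' genic deletion segments. Carrier counts k are drawn either uniformly on
#' 1..n_test or proportional to 1/k (neutral-like spectrum).
#'
#' @param genome an `sv_genome` from [generate_annotation()].
#' @param n_events number of events to attempt.
#' @param class_probs named proportions over the six categories (sum to 1).
#' @param genotypes a [panel_genotypes()] list (reference + test ids).
#' @param carrier_spectrum `"onebyk"` (default) or `"uniform"`.
#' @param size_meanlog,size_sdlog log-normal event-size parameters (bp).
#' @param het_prob probability that any given carrier of an event is
#'   heterogeneous within-line.
#' @param seed random seed.
#' @return object of class `sv_truth`: list with `events` (data.frame:
#'   event_id, chrom, start, end, class, n_carriers), `copies` (events x
#'   all-genotypes integer matrix of single-plant copy number, reference
#'   included), `het` (events x test-genotypes logical), `genotypes`, and
#'   `gene_events` (map gene_id -> event_id).
#' @export
plant_events <- function(genome,
                         n_events = 20L,
                         class_probs = default_class_probs(),
                         genotypes = panel_genotypes(),
                         carrier_spectrum = c("onebyk", "uniform"),
                         size_meanlog = log(2775),
                         size_sdlog = 1.2,
                         het_prob = 0.05,
                         seed = 1L) {
  stopifnot(inherits(genome, "sv_genome"))
  n_events <- check_count(n_events, "n_events", min = 0L)
  carrier_spectrum <- match.arg(carrier_spectrum)
  if (abs(sum(class_probs) - 1) > 1e-8) {
    stop("`class_probs` must sum to 1", call. = FALSE)
  }
  if (!all(names(class_probs) %in% SV_CLASSES)) {
    stop("unknown category in `class_probs`", call. = FALSE)
  }
  set.seed(as.integer(seed))

  n_test <- length(genotypes$tests)
  kprob <- switch(carrier_spectrum,
                  uniform = rep(1 / n_test, n_test),
                  onebyk = (1 / seq_len(n_test)) / sum(1 / seq_len(n_test)))

  genes <- genome$genes
  used <- rep(FALSE, nrow(genes))
  classes <- sample(names(class_probs), n_events, replace = TRUE,
                    prob = class_probs)

  ev_list <- list()
  copies <- list()
  het <- list()
  gene_events <- character(0)

  for (i in seq_len(n_events)) {
    cls <- classes[i]
    free <- which(!used)
    if (!length(free)) {
      warning(sprintf("event %d skipped: no gene available", i))
      next
    }
    anchor <- if (length(free) == 1L) free else sample(free, 1L)
    achrom <- genes$chrom[anchor]
    size <- round(min(max(stats::rlnorm(1, size_meanlog, size_sdlog), 800),
                      genome$chrom_lengths[[achrom]] / 10))
    # Grow the member set outward from the anchor gene, whole genes only
    # (both platforms then see a consistent dosage change), never claiming
    # a gene used by an earlier event, until the target size is reached.
    on_chrom <- which(genes$chrom == achrom)
    lo <- hi <- match(anchor, on_chrom)
    repeat {
      span <- genes$end[on_chrom[hi]] - genes$start[on_chrom[lo]]
      if (span >= size) break
      cl <- lo > 1L && !used[on_chrom[lo - 1L]]
      cr <- hi < length(on_chrom) && !used[on_chrom[hi + 1L]]
      if (cl && (!cr || stats::runif(1) < 0.5)) {
        if (genes$end[on_chrom[hi]] - genes$start[on_chrom[lo - 1L]] >
              2 * size) break
        lo <- lo - 1L
      } else if (cr) {
        if (genes$end[on_chrom[hi + 1L]] - genes$start[on_chrom[lo]] >
              2 * size) break
        hi <- hi + 1L
      } else break
    }
    ovl <- on_chrom[lo:hi]
    # Pad into intergenic space without touching the flanking genes.
    gap_l <- if (lo > 1L) {
      genes$start[on_chrom[lo]] - genes$end[on_chrom[lo - 1L]]
    } else genes$start[on_chrom[lo]]
    gap_r <- if (hi < length(on_chrom)) {
      genes$start[on_chrom[hi + 1L]] - genes$end[on_chrom[hi]]
    } else genome$chrom_lengths[[achrom]] - genes$end[on_chrom[hi]]
    start <- genes$start[on_chrom[lo]] -
      round(stats::runif(1, 0, max(0, gap_l - 1)))
    end <- genes$end[on_chrom[hi]] +
      round(stats::runif(1, 0, max(0, gap_r - 1)))
    used[ovl] <- TRUE

    # Carrier set and per-genotype copy state.
    k <- sample.int(n_test, 1L, prob = kprob)
    need2 <- cls %in% c("UpPAV+UpCNV", "UpCNV+DownCNV", "Multi-Allelic UpCNV")
    if (need2 && k < 2L) k <- 2L
    carriers <- sample(genotypes$tests, k)
    cp <- ev_copy_pattern(cls, genotypes, carriers)

    hrow <- stats::setNames(rep(FALSE, n_test), genotypes$tests)
    if (het_prob > 0) {
      hrow[carriers] <- stats::runif(k) < het_prob
    }

    id <- sprintf("sv%04d", length(ev_list) + 1L)
    ev_list[[id]] <- data.frame(
      event_id = id, chrom = achrom, start = start, end = end, class = cls,
      n_carriers = k, stringsAsFactors = FALSE)
    copies[[id]] <- cp
    het[[id]] <- hrow
    gene_events[genes$gene_id[ovl]] <- id
  }

  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(event_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), class = character(0),
               n_carriers = integer(0), stringsAsFactors = FALSE)
  rownames(events) <- events$event_id
  structure(list(
    events = events,
    copies = if (length(copies)) do.call(rbind, copies) else
      matrix(integer(0), 0, length(genotypes$all),
             dimnames = list(NULL, genotypes$all)),
    het = if (length(het)) do.call(rbind, het) else
      matrix(logical(0), 0, length(genotypes$tests),
             dimnames = list(NULL, genotypes$tests)),
    genotypes = genotypes,
    gene_events = gene_events
  ), class = "sv_truth")
}

# Copy-number vector (reference + tests) for one event of a given category.
# Reference copy is 0 or 1 exactly as the category requires.
ev_copy_pattern <- function(cls, genotypes, carriers) {
  tests <- genotypes$tests
  cp <- stats::setNames(rep(1L, length(genotypes$all)), genotypes$all)
  k <- length(carriers)
  split2 <- function() {
    # Two non-empty carrier groups.
    n1 <- sample.int(k - 1L, 1L)
    list(g1 = carriers[seq_len(n1)], g2 = carriers[(n1 + 1L):k])
  }
  switch(cls,
    "DownCNV/PAV" = {
      cp[carriers] <- 0L
    },
    "UpPAV" = {
      cp[] <- 0L
      cp[carriers] <- sample(c(1L, 2L), 1L)
    },
    "UpPAV+UpCNV" = {
      cp[] <- 0L
      g <- split2()
      cp[g$g1] <- 1L
      cp[g$g2] <- 3L
    },
    "UpCNV+DownCNV" = {
      g <- split2()
      cp[g$g1] <- 0L
      cp[g$g2] <- 2L
    },
    "UpCNV" = {
      cp[carriers] <- sample(c(2L, 3L), 1L)
    },
    "Multi-Allelic UpCNV" = {
      g <- split2()
      cp[g$g1] <- 3L
      cp[g$g2] <- 10L
    },
    stop("unknown category: ", cls)
  )
  cp[genotypes$reference] <- if (cls %in% c("UpPAV", "UpPAV+UpCNV")) 0L else 1L
  cp
}

#' @export
print.sv_truth <- function(x, ...) {
  cat(sprintf("Planted SV truth: %d events over %d genotypes\n",
              nrow(x$events), length(x$genotypes$tests)))
  if (nrow(x$events)) {
    print(table(x$events$class))
    cat(sprintf("  heterogeneous carrier flags: %d\n", sum(x$het)))
  }
  invisible(x)
}

# Per-gene copy matrices implied by the truth.
# single_plant: integer copies sampled by the array (one plant).
# bulk: real-valued copies sampled by resequencing (40-plant bulk); for a
# heterogeneous carrier the bulk is an equal mixture of the variant and the
# reference-like state.
truth_gene_copies <- function(truth, genome) {
  g <- genome$genes
  all_g <- truth$genotypes$all
  tests <- truth$genotypes$tests
  ref <- truth$genotypes$reference
  single <- matrix(1, nrow(g), length(all_g),
                   dimnames = list(g$gene_id, all_g))
  bulk <- single
  for (id in rownames(truth$events)) {
    gene_ids <- names(truth$gene_events)[truth$gene_events == id]
    if (!length(gene_ids)) next
    cp <- truth$copies[id, all_g]
    single[gene_ids, ] <- matrix(cp, length(gene_ids), length(all_g),
                                 byrow = TRUE)
    bcp <- cp
    hets <- tests[truth$het[id, tests]]
    if (length(hets)) {
      bcp[hets] <- 0.5 * cp[hets] + 0.5 * cp[ref]
    }
    bulk[gene_ids, ] <- matrix(bcp, length(gene_ids), length(all_g),
                               byrow = TRUE)
  }
  list(single_plant = single, bulk = bulk)
}

#' Write / read planted truth (lossless round trip)
#'
#' Serializes an `sv_truth` as a single tab-separated table: one row per
#' event with copy and heterogeneity columns per genotype plus the member
#' gene list.
#'
#' @param truth an `sv_truth`.
#' @param path file path.
#' @return `read_truth()` returns an `sv_truth` equal to the one written.
#' @export
write_truth <- function(truth, path) {
  ev <- truth$events
  cp <- truth$copies
  colnames(cp) <- paste0("copy.", colnames(cp))
  het <- truth$het
  colnames(het) <- paste0("het.", colnames(het))
  genes_by_event <- vapply(ev$event_id, function(id) {
    paste(names(truth$gene_events)[truth$gene_events == id], collapse = ",")
  }, character(1))
  out <- cbind(ev, as.data.frame(cp), as.data.frame(het),
               genes = genes_by_event)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @param genotypes the `panel_genotypes()` list used when planting.
#' @export
read_truth <- function(path, genotypes = panel_genotypes()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  ev <- tab[, c("event_id", "chrom", "start", "end", "class", "n_carriers")]
  rownames(ev) <- ev$event_id
  cp_cols <- grep("^copy\\.", names(tab), value = TRUE)
  cp <- as.matrix(tab[, cp_cols, drop = FALSE])
  colnames(cp) <- sub("^copy\\.", "", cp_cols)
  rownames(cp) <- ev$event_id
  het_cols <- grep("^het\\.", names(tab), value = TRUE)
  het <- as.matrix(tab[, het_cols, drop = FALSE])
  colnames(het) <- sub("^het\\.", "", het_cols)
  rownames(het) <- ev$event_id
  gene_events <- character(0)
  for (i in seq_len(nrow(tab))) {
    ids <- strsplit(tab$genes[i], ",", fixed = TRUE)[[1]]
    gene_events[ids] <- tab$event_id[i]
  }
  structure(list(events = ev, copies = cp, het = het == "TRUE" | het == TRUE,
                 genotypes = genotypes, gene_events = gene_events),
            class = "sv_truth")
}
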