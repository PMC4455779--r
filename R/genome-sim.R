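# Synthetic genome, gene-model catalog and CGH probe panel design.

#' Configuration for the synthetic genome and array design
#'
#' Describes a miniature genome with non-overlapping gene models, a tiling
#' CGH probe panel (50-70 bp probes at a target median spacing), syntenic
#' paralog pairing for a fraction of genes, and a protein-domain catalog.
#' Defaults emulate, at reduced scale, a paleopolyploid crop genome in which
#' roughly 60% of gene models retain a syntenic paralog from the last
#' whole-genome duplication and the array tiles the genome at a median probe
#' spacing of about 500 bp.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param n_genes total number of gene models.
#' @param gene_length_meanlog,gene_length_sdlog log-normal parameters for
#'   gene length (bp); lengths are clamped to `[300, 20000]`.
#' @param probe_spacing_bp target median distance between successive probe
#'   starts.
#' @param probe_length_bp length-2 vector giving the probe length range.
#' @param paralog_fraction fraction of genes assigned a syntenic paralog
#'   (pairs are symmetric and 1:1; the count is rounded down to an even
#'   number of genes).
#' @param pfam_catalog named integer vector: domain id -> number of genes
#'   carrying that domain.
#' @param seed random seed for the annotation stage.
#' @return object of class `genome_config`.
#' @export
genome_config <- function(n_chromosomes = 2L,
                          chrom_length_bp = 1e6,
                          n_genes = 200L,
                          gene_length_meanlog = log(1500),
                          gene_length_sdlog = 0.4,
                          probe_spacing_bp = 500,
                          probe_length_bp = c(50L, 70L),
                          paralog_fraction = 0.60,
                          pfam_catalog = c(CL0022 = 12L, PF00931 = 8L,
                                           PF07714 = 10L, PF01582 = 5L,
                                           PF00067 = 8L),
                          seed = 1L) {
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes")
  n_genes <- check_count(n_genes, "n_genes")
  stopifnot(chrom_length_bp > 0, probe_spacing_bp > 0,
            length(probe_length_bp) == 2L,
            probe_length_bp[1] <= probe_length_bp[2],
            paralog_fraction >= 0, paralog_fraction <= 1)
  if (length(pfam_catalog) && (is.null(names(pfam_catalog)) ||
                               any(!nzchar(names(pfam_catalog))))) {
    stop("`pfam_catalog` must be a named vector", call. = FALSE)
  }
  structure(list(
    n_chromosomes = n_chromosomes,
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_genes = n_genes,
    gene_length_meanlog = gene_length_meanlog,
    gene_length_sdlog = gene_length_sdlog,
    probe_spacing_bp = probe_spacing_bp,
    probe_length_bp = as.integer(probe_length_bp),
    paralog_fraction = paralog_fraction,
    pfam_catalog = pfam_catalog,
    seed = as.integer(seed)
  ), class = "genome_config")
}

#' Generate the gene-model catalog and probe panel coordinates
#'
#' Places non-overlapping gene models on each chromosome, tiles probes at a
#' jittered spacing whose median matches `probe_spacing_bp`, assigns
#' symmetric 1:1 syntenic-paralog pairs to `paralog_fraction` of genes and
#' distributes protein-domain labels per the catalog. Deterministic for a
#' fixed seed. All coordinates are 0-based half-open.
#'
#' @param config a [genome_config()].
#' @return object of class `sv_genome`: a list with elements `genes`
#'   (data.frame: gene_id, chrom, start, end, length, paralog),
#'   `probes` (data.frame: probe_id, chrom, start, end), `pfam`
#'   (data.frame: gene_id, domain), `chrom_lengths`, and `config`. The
#'   number of genes with no overlapping probe is recorded in attribute
#'   `n_genes_without_probes` and shown by `print()`.
#' @export
generate_annotation <- function(config = genome_config()) {
  stopifnot(inherits(config, "genome_config"))
  seeds <- derive_seeds(config$seed, 4L)
  chroms <- sprintf("chr%02d", seq_len(config$n_chromosomes))
  chrom_lengths <- stats::setNames(rep(config$chrom_length_bp,
                                       config$n_chromosomes), chroms)

  # Gene counts per chromosome: as even as possible.
  per_chrom <- rep(config$n_genes %/% config$n_chromosomes,
                   config$n_chromosomes)
  extra <- config$n_genes %% config$n_chromosomes
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L

  set.seed(seeds[1])
  gene_rows <- vector("list", config$n_chromosomes)
  for (ci in seq_len(config$n_chromosomes)) {
    ng <- per_chrom[ci]
    if (ng == 0L) next
    lens <- round(pmin(pmax(stats::rlnorm(ng, config$gene_length_meanlog,
                                          config$gene_length_sdlog),
                            300), 20000))
    slack <- config$chrom_length_bp - sum(lens)
    if (slack < ng + 1L) {
      stop(sprintf(
        "gene count infeasible: %d genes totalling %.0f bp do not fit on a %.0f bp chromosome",
        ng, sum(lens), config$chrom_length_bp), call. = FALSE)
    }
    gaps <- stats::rexp(ng + 1L)
    gaps <- floor(gaps / sum(gaps) * slack)
    starts <- cumsum(c(gaps[1], lens[-ng] + gaps[-c(1, ng + 1L)]))
    gene_rows[[ci]] <- data.frame(
      chrom = chroms[ci],
      start = starts,
      end = starts + lens,
      length = lens,
      stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, gene_rows)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  genes$gene_id <- sprintf("gene%05d", seq_len(nrow(genes)))
  genes <- genes[, c("gene_id", "chrom", "start", "end", "length")]
  rownames(genes) <- genes$gene_id

  # Probe tiling: spacing log-normally jittered around the target median.
  set.seed(seeds[2])
  probe_rows <- vector("list", config$n_chromosomes)
  for (ci in seq_len(config$n_chromosomes)) {
    L <- config$chrom_length_bp
    m <- ceiling(L / config$probe_spacing_bp) + 10L
    spacing <- round(config$probe_spacing_bp * exp(stats::rnorm(m, 0, 0.15)))
    starts <- cumsum(c(round(stats::runif(1, 0, config$probe_spacing_bp)),
                       spacing))
    plens <- sample(seq(config$probe_length_bp[1], config$probe_length_bp[2]),
                    length(starts), replace = TRUE)
    keep <- starts + plens <= L
    probe_rows[[ci]] <- data.frame(
      chrom = chroms[ci],
      start = starts[keep],
      end = (starts + plens)[keep],
      stringsAsFactors = FALSE
    )
  }
  probes <- do.call(rbind, probe_rows)
  probes$probe_id <- sprintf("probe%06d", seq_len(nrow(probes)))
  probes <- probes[, c("probe_id", "chrom", "start", "end")]
  rownames(probes) <- NULL

  # Symmetric 1:1 paralog pairing.
  set.seed(seeds[3])
  n_paired <- floor(config$paralog_fraction * nrow(genes))
  if (n_paired %% 2L == 1L) n_paired <- n_paired - 1L
  genes$paralog <- NA_character_
  if (n_paired >= 2L) {
    chosen <- sample(genes$gene_id, n_paired)
    a <- chosen[seq_len(n_paired / 2L)]
    b <- chosen[(n_paired / 2L + 1L):n_paired]
    genes[a, "paralog"] <- b
    genes[b, "paralog"] <- a
  }

  # Domain labels: each domain drawn over distinct genes; a gene may carry
  # several different domains.
  set.seed(seeds[4])
  pfam <- data.frame(gene_id = character(0), domain = character(0),
                     stringsAsFactors = FALSE)
  for (d in names(config$pfam_catalog)) {
    k <- min(as.integer(config$pfam_catalog[[d]]), nrow(genes))
    if (k > 0) {
      pfam <- rbind(pfam, data.frame(gene_id = sample(genes$gene_id, k),
                                     domain = d, stringsAsFactors = FALSE))
    }
  }
  rownames(pfam) <- NULL

  ov <- GenomicRanges::countOverlaps(
    granges_from0(genes$chrom, genes$start, genes$end),
    granges_from0(probes$chrom, probes$start, probes$end))
  genome <- structure(list(
    genes = genes, probes = probes, pfam = pfam,
    chrom_lengths = chrom_lengths, config = config
  ), class = "sv_genome")
  attr(genome, "n_genes_without_probes") <- sum(ov == 0L)
  genome
}

#' @export
print.sv_genome <- function(x, ...) {
  cat(sprintf(
    "Synthetic genome: %d chromosomes (%.0f bp each), %d gene models, %d probes\n",
    length(x$chrom_lengths), x$config$chrom_length_bp, nrow(x$genes),
    nrow(x$probes)))
  cat(sprintf("  genes with a syntenic paralog: %d; domain labels: %d over %d domains\n",
              sum(!is.na(x$genes$paralog)), nrow(x$pfam),
              length(unique(x$pfam$domain))))
  cat(sprintf("  genes with zero overlapping probes: %d\n",
              attr(x, "n_genes_without_probes")))
  invisible(x)
}

# GRanges views of the annotation (internal).
genes_gr <- function(genome) {
  gr <- granges_from0(genome$genes$chrom, genome$genes$start,
                      genome$genes$end)
  names(gr) <- genome$genes$gene_id
  gr
}
probes_gr <- function(genome) {
  granges_from0(genome$probes$chrom, genome$probes$start, genome$probes$end)
}
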