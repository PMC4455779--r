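# Plain-text I/O: probe panels, count matrices, BED/GFF3 exports.

#' Write / read a probe panel as a tab-separated table
#'
#' Columns: chrom, start, end, probe_id, then one log2-ratio column per
#' genotype. Coordinates are 0-based half-open.
#'
#' @param panel an `sv_panel`.
#' @param path file path.
#' @export
write_probe_panel <- function(panel, path) {
  out <- cbind(panel$probes[, c("chrom", "start", "end", "probe_id")],
               as.data.frame(panel$ratios))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_panel
#' @export
read_probe_panel <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  probes <- tab[, c("probe_id", "chrom", "start", "end")]
  ratios <- as.matrix(tab[, setdiff(names(tab),
                                    c("chrom", "start", "end", "probe_id")),
                          drop = FALSE])
  rownames(ratios) <- probes$probe_id
  structure(list(probes = probes, ratios = ratios, normalized = FALSE),
            class = "sv_panel")
}

#' Write / read a gene x genotype count matrix
#'
#' Tab-separated with a `gene_id` column and one column per genotype.
#'
#' @param counts integer matrix with gene rownames.
#' @param path file path.
#' @export
write_counts <- function(counts, path) {
  out <- data.frame(gene_id = rownames(counts), counts,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  storage.mode(m) <- "integer"
  m
}

#' Export segment calls as BED6
#'
#' Name field carries `genotype:direction` (or the carrier count for
#' collapsed SV segments), score the mean log2 ratio (or carrier count).
#'
#' @param segments segment calls from [call_cgh_segments()] or an
#'   `sv_segments` data.frame.
#' @param path file path.
#' @param k optional named carrier counts (for collapsed segments).
#' @export
write_bed_segments <- function(segments, path, k = NULL) {
  if (!nrow(segments)) {
    file.create(path)
    return(invisible(path))
  }
  if (!is.null(segments$genotype)) {
    name <- paste0(segments$genotype, ":", segments$direction)
    score <- round(segments$mean, 4)
  } else {
    kk <- if (!is.null(k)) k[segments$segment_id] else rep(0L,
                                                           nrow(segments))
    name <- paste0(segments$segment_id, ":", segments$direction)
    score <- as.integer(kk)
  }
  bed <- data.frame(chrom = segments$chrom, start = segments$start,
                    end = segments$end, name = name, score = score,
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export the gene catalog as GFF3 (1-based coordinates)
#'
#' @param genome an `sv_genome`.
#' @param path file path.
#' @export
write_gff3_genes <- function(genome, path) {
  g <- genome$genes
  attr_col <- sprintf("ID=%s%s", g$gene_id,
                      ifelse(is.na(g$paralog), "",
                             sprintf(";paralog=%s", g$paralog)))
  gff <- data.frame(seqid = g$chrom, source = "svpanel", type = "gene",
                    start = g$start + 1L, end = g$end, score = ".",
                    strand = ".", phase = ".", attributes = attr_col)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(gff, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write every pipeline artifact to a directory
#'
#' Emits plain-text tables for the probe panel, thresholds, segment calls,
#' gene scores and calls, classification, collapsed segments (BED), the
#' spectra and enrichment tables, plus a category summary. Headers name
#' the units; all coordinate files are BED (0-based) or GFF3 (1-based).
#'
#' @param run an `sv_run`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_sv_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_probe_panel(run$panel, p("probe_panel.tsv"))
  utils::write.table(run$cgh_thresholds, p("cgh_thresholds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$segment_calls, p("cgh_segments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed_segments(run$segment_calls, p("cgh_segments.bed"))
  write_gff3_genes(run$experiment$genome, p("genes.gff3"))
  write_counts(run$experiment$counts, p("read_counts.tsv"))
  utils::write.table(
    data.frame(gene_id = rownames(run$cgh_scores$score),
               run$cgh_scores$score, check.names = FALSE),
    p("gene_cgh_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$classification$genes, p("classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_scatter(run$classification, p("scatter_points.tsv"))
  write_truth(run$experiment$truth, p("planted_truth.tsv"))
  for (d in names(run$spectra)) {
    write_bed_segments(run$spectra[[d]]$segments,
                       p(sprintf("sv_segments_%s.bed", tolower(d))),
                       k = run$spectra[[d]]$k)
    write_spectrum(run$spectra[[d]]$spectrum,
                   p(sprintf("rsfs_%s.tsv", tolower(d))))
  }
  if (!is.null(run$neutral)) {
    for (d in names(run$neutral)) {
      write_spectrum(run$neutral[[d]]$spectrum,
                     p(sprintf("rsfs_neutral_%s.tsv", tolower(d))))
    }
  }
  if (!is.null(run$enrichment)) {
    for (cat_ in names(run$enrichment)) {
      safe <- gsub("[^A-Za-z0-9]+", "_", cat_)
      utils::write.table(run$enrichment[[cat_]],
                         p(sprintf("enrichment_%s.tsv", safe)), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  utils::write.table(as.data.frame(category_table(run)),
                     p("category_summary.tsv"), sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(dir)
}

#' Previously reported category counts for the 41-parent soybean NAM panel
#'
#' Loads the published gene-model counts per SV category (split by
#' retained-paralog status) and the domain-enrichment table shipped with
#' the package, used to reproduce the survey's summary arithmetic.
#'
#' @return `published_category_counts()`: data.frame with one row per
#'   gene group (with/without retained paralog, total assessed) and one
#'   column per category plus `genes_evaluated`.
#'   `published_enrichment_rows()`: data.frame with one row per Pfam
#'   domain: domain id, description, genome-wide gene count and the
#'   observed overlap with the deletion/PAV category list.
#' @export
published_category_counts <- function() {
  utils::read.delim(system.file("extdata", "soynam_category_counts.tsv",
                                package = "svpanel"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname published_category_counts
#' @export
published_enrichment_rows <- function() {
  utils::read.delim(system.file("extdata", "soynam_domain_enrichment.tsv",
                                package = "svpanel"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}
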