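# Collapse adjacent cross-validated genic CNVs into segments and build the
# reference-based site frequency spectra (rSFS).

rsfs_member_classes <- function(direction) {
  switch(direction,
         Down = "DownCNV/PAV",
         Up = c("UpCNV", "Multi-Allelic UpCNV"),
         stop("direction must be 'Up' or 'Down'"))
}

#' Collapse adjacent cross-validated genes into SV segments
#'
#' Nearby genic CNVs are assumed to descend from a single mutational event.
#' Using the significant CGH segments as a guide, cross-validated genes of
#' the direction's member classes (Down: DownCNV/PAV only; Up: UpCNV and
#' Multi-Allelic UpCNV) are merged when they are adjacent in gene order
#' (no intervening retained gene of another status) and the junction is
#' covered by one significant CGH segment of the same direction in at
#' least one shared genotype. Runs spanning two guide segments are split
#' at the guide boundary.
#'
#' @param classification an `sv_classification`.
#' @param genome an `sv_genome`.
#' @param segment_calls segment calls from [call_cgh_segments()].
#' @param direction `"Down"` or `"Up"`.
#' @param retained gene ids retained by the count filter (intervening-gene
#'   universe); defaults to all genes.
#' @return data.frame of class `sv_segments`: segment_id, chrom, start,
#'   end, direction, n_genes, genes (comma-separated member ids),
#'   length_bp.
#' @export
collapse_segments <- function(classification, genome, segment_calls,
                              direction = c("Down", "Up"),
                              retained = NULL) {
  direction <- match.arg(direction)
  member_classes <- rsfs_member_classes(direction)
  genes <- genome$genes
  if (is.null(retained)) retained <- genes$gene_id
  cls <- classification$genes
  member_ids <- cls$gene_id[cls$cross_validated &
                              cls$category %in% member_classes]
  sig <- segment_calls[segment_calls$direction == direction, , drop = FALSE]

  # Universe for adjacency: retained genes, in genome order.
  uni <- genes[genes$gene_id %in% retained, , drop = FALSE]
  uni <- uni[order(uni$chrom, uni$start), , drop = FALSE]
  is_member <- uni$gene_id %in% member_ids

  # Shared guide segment covering two neighbouring genes in >= 1 genotype.
  covered_together <- function(i, j) {
    if (!nrow(sig)) return(FALSE)
    s <- sig[sig$chrom == uni$chrom[i], , drop = FALSE]
    if (!nrow(s)) return(FALSE)
    cov_i <- s$start < uni$end[i] & s$end > uni$start[i]
    cov_j <- s$start < uni$end[j] & s$end > uni$start[j]
    any(cov_i & cov_j)
  }

  runs <- list()
  current <- integer(0)
  flush <- function() {
    if (length(current)) runs[[length(runs) + 1L]] <<- current
    current <<- integer(0)
  }
  for (i in seq_len(nrow(uni))) {
    if (!is_member[i]) {
      flush()
      next
    }
    if (length(current)) {
      prev <- current[length(current)]
      same_chrom <- uni$chrom[prev] == uni$chrom[i]
      if (!(same_chrom && covered_together(prev, i))) flush()
    }
    current <- c(current, i)
  }
  flush()

  out <- lapply(seq_along(runs), function(k) {
    idx <- runs[[k]]
    data.frame(
      segment_id = sprintf("%s_seg%04d", tolower(direction), k),
      chrom = uni$chrom[idx[1]],
      start = min(uni$start[idx]), end = max(uni$end[idx]),
      direction = direction, n_genes = length(idx),
      genes = paste(uni$gene_id[idx], collapse = ","),
      length_bp = max(uni$end[idx]) - min(uni$start[idx]),
      stringsAsFactors = FALSE)
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(segment_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), direction = character(0),
               n_genes = integer(0), genes = character(0),
               length_bp = numeric(0), stringsAsFactors = FALSE)
  class(res) <- c("sv_segments", "data.frame")
  res
}

#' Carrier count of an SV segment
#'
#' A genotype carries the segment iff at least one member gene exceeds the
#' significance thresholds on *both* platforms (the same gene on both) in
#' that genotype, in the segment's direction. Segments with no carrier are
#' dropped from the spectrum with a warning.
#'
#' @param segments an `sv_segments` data.frame.
#' @param probe_calls gene x genotype matrix from [call_probe_cnv()].
#' @param seq_calls a `seq_calls` object or its direction matrix.
#' @return integer vector of carrier counts `k` (named by segment id);
#'   dropped segments are absent.
#' @export
segment_frequency <- function(segments, probe_calls, seq_calls) {
  seq_dir <- if (inherits(seq_calls, "seq_calls")) seq_calls$direction else
    seq_calls
  gts <- colnames(probe_calls)
  ks <- integer(0)
  for (i in seq_len(nrow(segments))) {
    members <- strsplit(segments$genes[i], ",", fixed = TRUE)[[1]]
    # Both-platform carriers must exceed thresholds at the SAME member gene.
    members_seq <- intersect(members, rownames(seq_dir))
    dirn <- segments$direction[i]
    carrier <- vapply(gts, function(g) {
      length(members_seq) > 0L &&
        any(probe_calls[members_seq, g] == dirn &
              seq_dir[members_seq, g] == dirn)
    }, logical(1))
    k <- sum(carrier)
    if (k == 0L) {
      warning("segment ", segments$segment_id[i],
              " has no carrier exceeding both platforms; dropped")
    } else {
      ks[segments$segment_id[i]] <- k
    }
  }
  ks
}

#' Build a site frequency spectrum from carrier counts
#'
#' @param k integer carrier counts (each in 1..n_test).
#' @param n_test number of test genotypes (spectrum classes 1..n_test).
#' @param label spectrum label (e.g. `"empirical-Down"`).
#' @return object of class `sv_spectrum`: integer counts vector of length
#'   `n_test` (index = carrier count), with attributes `n_test` and
#'   `label`.
#' @export
build_rsfs <- function(k, n_test = 41L, label = "empirical") {
  stopifnot(all(k >= 1), all(k <= n_test))
  counts <- tabulate(k, nbins = n_test)
  structure(as.integer(counts), n_test = as.integer(n_test), label = label,
            class = "sv_spectrum")
}

#' @export
print.sv_spectrum <- function(x, ...) {
  cat(sprintf("Site frequency spectrum [%s]: %d items over k = 1..%d\n",
              attr(x, "label"), sum(x), attr(x, "n_test")))
  nz <- which(unclass(x) > 0)
  if (length(nz)) {
    print(stats::setNames(as.integer(x)[nz], nz))
  }
  invisible(x)
}

#' @export
plot.sv_spectrum <- function(x, ...) {
  graphics::barplot(as.integer(x), names.arg = seq_along(x),
                    xlab = "carrier count k", ylab = "segments",
                    main = attr(x, "label"), ...)
  invisible(x)
}

#' Write / read a spectrum as a two-column table
#' @param spectrum an `sv_spectrum`.
#' @param path file path.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(
    data.frame(k = seq_along(spectrum), count = as.integer(spectrum)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @param label label for the read spectrum.
#' @export
read_spectrum <- function(path, label = "empirical") {
  tab <- utils::read.delim(path)
  structure(as.integer(tab$count), n_test = nrow(tab), label = label,
            class = "sv_spectrum")
}

#' Member genes of collapsed segments (round trip helper)
#'
#' @param segments an `sv_segments`.
#' @return character vector of all member gene ids.
#' @export
explode_segments <- function(segments) {
  unlist(strsplit(segments$genes, ",", fixed = TRUE), use.names = FALSE)
}
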