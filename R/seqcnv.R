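# Read-depth (RPKM log2 ratio) CNV calling with zero-read special streams.

#' Drop genes with zero reads in every genotype
#'
#' @param counts genes x genotypes integer matrix including the reference
#'   genotype column.
#' @return the retained sub-matrix (attributes preserved).
#' @export
filter_all_zero_genes <- function(counts) {
  keep <- rowSums(counts) > 0
  out <- counts[keep, , drop = FALSE]
  attr(out, "depths") <- attr(counts, "depths")
  attr(out, "read_length_bp") <- attr(counts, "read_length_bp")
  out
}

#' Partition retained genes into analysis streams
#'
#' Three parallel streams mirror the scaling issues of an all-by-one
#' read-depth comparison:
#' * `normal`: reference count > 0; analyzed via RPKM log2 ratios.
#' * `zero_in_reference`: reference count 0 and more than one read in at
#'   least one test genotype; ratios are undefined, so copy number is later
#'   estimated from absolute RPKM.
#' * `ambiguous`: reference count 0 but no test genotype exceeds one read;
#'   too weak for the zero-in-reference stream, kept with the flags and
#'   logged.
#'
#' Additionally `potential_down` flags (gene x test genotype) mark genes
#' with reads in the reference but zero reads in that test genotype.
#'
#' @param counts retained counts from [filter_all_zero_genes()].
#' @param reference reference genotype column name.
#' @return list with character vectors `normal`, `zero_in_reference`,
#'   `ambiguous` and logical matrix `potential_down`.
#' @export
split_streams <- function(counts, reference = "Wm82") {
  stopifnot(reference %in% colnames(counts))
  tests <- setdiff(colnames(counts), reference)
  ref0 <- counts[, reference] == 0
  any_gt1 <- apply(counts[, tests, drop = FALSE] > 1, 1, any)
  zero_in_reference <- rownames(counts)[ref0 & any_gt1]
  ambiguous <- rownames(counts)[ref0 & !any_gt1]
  normal <- rownames(counts)[!ref0]
  if (length(ambiguous)) {
    message(length(ambiguous),
            " gene(s) with a zero-read reference but no test count > 1 ",
            "assigned to the flag stream")
  }
  pd <- counts[, tests, drop = FALSE] == 0 & !ref0
  list(normal = normal, zero_in_reference = zero_in_reference,
       ambiguous = ambiguous, potential_down = pd)
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count * 1e9 / (gene_length_bp * total_mapped_reads)`. Invariant
#' to uniform depth scaling of a genotype.
#'
#' @param counts genes x genotypes matrix.
#' @param gene_lengths named (by gene id) lengths in bp.
#' @param totals per-genotype total mapped reads; defaults to the column
#'   sums of the full count matrix.
#' @return RPKM matrix with attribute `totals`.
#' @export
compute_rpkm <- function(counts, gene_lengths, totals = colSums(counts)) {
  stopifnot(all(rownames(counts) %in% names(gene_lengths)))
  len <- gene_lengths[rownames(counts)]
  if (any(len <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  if (any(totals <= 0)) stop("zero total mapped reads", call. = FALSE)
  rpkm <- sweep(counts * 1e9, 1, len, `/`)
  rpkm <- sweep(rpkm, 2, totals[colnames(counts)], `/`)
  attr(rpkm, "totals") <- totals
  rpkm
}

#' Per-gene log2 RPKM ratios against the reference genotype
#'
#' Defined for the normal stream only (reference RPKM > 0); a zero test
#' RPKM maps to `-Inf`, which is below every finite threshold and so feeds
#' the potential-DownCNV flags.
#'
#' @param rpkm RPKM matrix including the reference column.
#' @param reference reference genotype name.
#' @param genes gene ids to include (default: all with reference RPKM > 0).
#' @return genes x test-genotypes matrix of log2 ratios.
#' @export
seq_ratios <- function(rpkm, reference = "Wm82", genes = NULL) {
  stopifnot(reference %in% colnames(rpkm))
  if (is.null(genes)) genes <- rownames(rpkm)[rpkm[, reference] > 0]
  tests <- setdiff(colnames(rpkm), reference)
  log2(rpkm[genes, tests, drop = FALSE] / rpkm[genes, reference])
}

#' Thresholds on the sequence log2 ratio distribution
#'
#' Per genotype, mean and SD are computed over that genotype's finite
#' ratios only; lower = mean - `down_sd` SD, upper = mean + `up_sd` SD.
#'
#' @param ratios matrix from [seq_ratios()].
#' @param down_sd,up_sd SD multipliers.
#' @return an `sv_thresholds` data.frame.
#' @export
seq_thresholds <- function(ratios, down_sd = 3, up_sd = 2) {
  gts <- colnames(ratios)
  m <- s <- numeric(length(gts))
  for (i in seq_along(gts)) {
    x <- ratios[, i]
    x <- x[is.finite(x)]
    if (length(x) < 2L || stats::sd(x) == 0) {
      stop("degenerate sequence-ratio distribution for genotype ", gts[i],
           "; supply fixed_thresholds() instead", call. = FALSE)
    }
    m[i] <- mean(x)
    s[i] <- stats::sd(x)
  }
  structure(data.frame(genotype = gts, mean = m, sd = s,
                       lower = m - down_sd * s, upper = m + up_sd * s,
                       row.names = gts, stringsAsFactors = FALSE),
            class = c("sv_thresholds", "data.frame"))
}

#' Sequence CNV direction calls
#'
#' Up iff ratio strictly above the genotype's upper threshold, Down iff
#' strictly below the lower threshold (a `-Inf` ratio from a zero-read test
#' gene is therefore Down).
#'
#' @param ratios matrix from [seq_ratios()].
#' @param thresholds an `sv_thresholds` (typically [seq_thresholds()]).
#' @return character matrix genes x genotypes with
#'   `"Down"`, `"Up"`, `"neutral"`.
#' @export
call_seq_cnv <- function(ratios, thresholds) {
  gts <- colnames(ratios)
  stopifnot(all(gts %in% rownames(thresholds)))
  lo <- matrix(thresholds[gts, "lower"], nrow(ratios), length(gts),
               byrow = TRUE)
  up <- matrix(thresholds[gts, "upper"], nrow(ratios), length(gts),
               byrow = TRUE)
  out <- matrix("neutral", nrow(ratios), ncol(ratios),
                dimnames = dimnames(ratios))
  out[ratios < lo] <- "Down"
  out[ratios > up] <- "Up"
  out
}

#' Run the full sequence-calling stage
#'
#' Filters all-zero genes, splits streams, computes RPKM, ratios and
#' thresholds, and assembles one direction-call matrix over all retained
#' genes: normal-stream genes are called from their log2 ratios;
#' zero-in-reference genes are called Up in genotypes with more than one
#' read (the reference lacks the gene entirely); ambiguous genes stay
#' neutral.
#'
#' Also estimates, per genotype, the RPKM of a single-copy gene (median
#' over normal-stream genes) used downstream for absolute copy estimates of
#' zero-in-reference genes.
#'
#' @param counts raw genes x genotypes counts (reference included).
#' @param gene_lengths named gene lengths in bp.
#' @param reference reference genotype name.
#' @param thresholds optional fixed `sv_thresholds`; default computed via
#'   [seq_thresholds()].
#' @param down_sd,up_sd multipliers when thresholds are computed.
#' @return list of class `seq_calls`: `direction` (matrix over retained
#'   genes x test genotypes), `ratios`, `rpkm`, `thresholds`, `streams`,
#'   `single_copy_rpkm` (per genotype), `retained` (gene ids).
#' @export
call_seq_all <- function(counts, gene_lengths, reference = "Wm82",
                         thresholds = NULL, down_sd = 3, up_sd = 2) {
  kept <- filter_all_zero_genes(counts)
  streams <- split_streams(kept, reference)
  rpkm <- compute_rpkm(kept, gene_lengths, totals = colSums(kept))
  tests <- setdiff(colnames(kept), reference)

  direction <- matrix("neutral", nrow(kept), length(tests),
                      dimnames = list(rownames(kept), tests))
  ratios <- matrix(NA_real_, nrow(kept), length(tests),
                   dimnames = list(rownames(kept), tests))
  if (length(streams$normal)) {
    r <- seq_ratios(rpkm, reference, streams$normal)
    if (is.null(thresholds)) {
      thresholds <- seq_thresholds(r, down_sd = down_sd, up_sd = up_sd)
    }
    direction[streams$normal, ] <- call_seq_cnv(r, thresholds)
    ratios[streams$normal, ] <- r
  }
  if (length(streams$zero_in_reference)) {
    up <- kept[streams$zero_in_reference, tests, drop = FALSE] > 1
    direction[streams$zero_in_reference, ][up] <- "Up"
  }
  single_copy_rpkm <- apply(rpkm[streams$normal, , drop = FALSE], 2,
                            stats::median)
  structure(list(direction = direction, ratios = ratios, rpkm = rpkm,
                 thresholds = thresholds, streams = streams,
                 single_copy_rpkm = single_copy_rpkm,
                 retained = rownames(kept)),
            class = "seq_calls")
}
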