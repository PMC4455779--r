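# Cross-platform validation, copy-number estimation, six-category
# classification and intra-line heterogeneity flags.

#' Candidate gene set for cross-validation
#'
#' A gene is a candidate iff it overlaps a significant (non-neutral) CGH
#' segment in at least one genotype, OR it appears on both the gene-level
#' CGH (probe-average) call list and the sequence call list, each in at
#' least one genotype (gene-level "any genotype" logic).
#'
#' @param genome an `sv_genome` (or gene data.frame).
#' @param segment_calls segment calls from [call_cgh_segments()].
#' @param probe_calls matrix from [call_probe_cnv()].
#' @param seq_calls a `seq_calls` object or its direction matrix.
#' @return character vector of candidate gene ids, in genome order.
#' @export
candidate_set <- function(genome, segment_calls, probe_calls, seq_calls) {
  genes <- if (inherits(genome, "sv_genome")) genome$genes else genome
  seq_dir <- if (inherits(seq_calls, "seq_calls")) seq_calls$direction else
    seq_calls
  sig <- segment_calls[segment_calls$direction != "neutral", , drop = FALSE]
  in_segment <- character(0)
  if (nrow(sig)) {
    hits <- GenomicRanges::findOverlaps(
      granges_from0(genes$chrom, genes$start, genes$end),
      granges_from0(sig$chrom, sig$start, sig$end))
    in_segment <- genes$gene_id[unique(S4Vectors::queryHits(hits))]
  }
  probe_list <- rownames(probe_calls)[
    apply(probe_calls != "neutral", 1, any)]
  seq_list <- rownames(seq_dir)[apply(seq_dir != "neutral", 1, any)]
  cand <- union(in_segment, intersect(probe_list, seq_list))
  genes$gene_id[genes$gene_id %in% cand]
}

#' Per-gene platform points
#'
#' Assembles, for one gene, the CGH score, sequence score and the implied
#' copy-number estimate per platform for every test genotype. For genes in
#' the zero-in-reference stream (reference copy 0) the sequence axis uses
#' absolute RPKM scaled by the genotype's single-copy RPKM, and the CGH
#' copy estimate divides out the deletion floor.
#'
#' @param gene gene id.
#' @param cgh_scores a `gene_cgh_scores`.
#' @param seq a `seq_calls`.
#' @param deletion_floor the CGH deletion floor used in simulation/copy
#'   conversion (copy 0 hybridizes at this apparent copy value).
#' @return data.frame: genotype, cgh_score, seq_score, cgh_copy, seq_copy,
#'   seq_count_zero, ref_copies (attribute-like column, 0 or 1).
#' @export
platform_points <- function(gene, cgh_scores, seq,
                            deletion_floor = 1 / 16) {
  gts <- colnames(cgh_scores$score)
  cgh <- cgh_scores$score[gene, gts]
  zero_ref <- gene %in% seq$streams$zero_in_reference ||
    gene %in% seq$streams$ambiguous
  ref_copies <- if (zero_ref) 0L else 1L
  if (zero_ref) {
    rp <- seq$rpkm[gene, gts]
    seq_copy <- rp / seq$single_copy_rpkm[gts]
    seq_score <- log2(ifelse(seq_copy > 0, seq_copy, deletion_floor))
    cgh_copy <- 2^cgh * deletion_floor
  } else {
    seq_score <- seq$ratios[gene, gts]
    seq_copy <- ifelse(is.finite(seq_score), 2^seq_score, 0)
    cgh_copy <- 2^cgh
  }
  count_zero <- if (gene %in% rownames(seq$streams$potential_down)) {
    seq$streams$potential_down[gene, gts]
  } else rep(FALSE, length(gts))
  data.frame(genotype = gts, cgh_score = cgh, seq_score = seq_score,
             cgh_copy = cgh_copy, seq_copy = seq_copy,
             seq_count_zero = count_zero, ref_copies = ref_copies,
             row.names = gts, stringsAsFactors = FALSE)
}

#' Integer copy-number calls per genotype
#'
#' Combined estimate `ref_copies * 2^mean(cgh_score, seq_score)`, rounded
#' half-away-from-zero and floored at 0 (for a reference copy of 0 the
#' platform copy estimates are averaged directly). Copy 0 is assigned
#' outright when the CGH score is below the Down threshold and the gene has
#' zero reads in that genotype. When the two platforms disagree by more
#' than `disagree_tol` log2 units no integer call is made (`NA`) and the
#' genotype is flagged for heterogeneity review.
#'
#' @param points data.frame from [platform_points()].
#' @param cgh_thresholds an `sv_thresholds` for the CGH axis.
#' @param disagree_tol maximum |cgh_score - seq_score| for an integer call.
#' @return list with integer vector `copies` (NA where no call) and logical
#'   `disagree` per genotype.
#' @export
estimate_copies <- function(points, cgh_thresholds, disagree_tol = 2) {
  gts <- points$genotype
  ref <- points$ref_copies[1]
  lo <- cgh_thresholds[gts, "lower"]
  hard_zero <- points$seq_count_zero & points$cgh_score < lo
  if (ref >= 1) {
    est <- ref * 2^((points$cgh_score + points$seq_score) / 2)
    disagree <- is.finite(points$cgh_score) & is.finite(points$seq_score) &
      abs(points$cgh_score - points$seq_score) > disagree_tol
  } else {
    # Reference-absent gene: both axes already on the copy scale; compare
    # them there (a small floor keeps the log defined at copy 0).
    f <- 1 / 16
    est <- (points$cgh_copy + points$seq_copy) / 2
    disagree <- abs(log2((points$cgh_copy + f) / (points$seq_copy + f))) >
      disagree_tol
  }
  est[hard_zero] <- 0
  disagree <- disagree & !hard_zero
  copies <- as.integer(pmax(round_half_away(est), 0))
  copies[!is.finite(est)] <- 0L  # both-platform -Inf: absent
  copies[disagree] <- NA_integer_
  list(copies = stats::setNames(copies, gts),
       disagree = stats::setNames(disagree, gts))
}

#' Allele clustering in the (CGH, sequence) copy plane
#'
#' One-dimensional gap clustering (gap > `gap_min` copy units) on each
#' platform's copy estimates; the joint clustering is the intersection of
#' the two axis partitions. The gene is cross-validated when two joint
#' clusters are separated by at least `gap_min` on *both* axes, or when all
#' genotypes lie beyond the significance thresholds on both platforms.
#'
#' @param points data.frame from [platform_points()].
#' @param cgh_thresholds,seq_thresholds `sv_thresholds` for the two axes.
#' @param gap_min minimum inter-cluster gap in copy units (default 0.75).
#' @return list with `assignment` (joint cluster id per genotype),
#'   `centers` (cluster x 2 matrix of axis means), `n_clusters`,
#'   `cross_validated`.
#' @export
cluster_alleles <- function(points, cgh_thresholds, seq_thresholds,
                            gap_min = 0.75) {
  a <- gap_clusters(points$cgh_copy, gap_min)
  b <- gap_clusters(pmin(points$seq_copy, 64), gap_min)
  joint <- as.integer(factor(paste(a$assignment, b$assignment)))
  k <- max(joint)
  centers <- cbind(
    cgh = as.numeric(tapply(points$cgh_copy, joint, mean)),
    seq = as.numeric(tapply(points$seq_copy, joint, mean)))
  split_both <- FALSE
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if (abs(centers[i, 1] - centers[j, 1]) >= gap_min &&
            abs(centers[i, 2] - centers[j, 2]) >= gap_min) {
          split_both <- TRUE
        }
      }
    }
  }
  gts <- points$genotype
  beyond_cgh <- points$cgh_score < cgh_thresholds[gts, "lower"] |
    points$cgh_score > cgh_thresholds[gts, "upper"]
  beyond_seq <- (points$seq_score < seq_thresholds[gts, "lower"] |
                   points$seq_score > seq_thresholds[gts, "upper"] |
                   points$seq_count_zero)
  all_beyond <- all(beyond_cgh & beyond_seq)
  list(assignment = stats::setNames(joint, gts), centers = centers,
       n_clusters = k, cross_validated = split_both || all_beyond)
}

#' Classify one copy-number pattern into a category
#'
#' Decision order: reference copy (0 vs 1), then presence of zero-copy test
#' genotypes, then the multiplicity of distinct copy groups. Two copy
#' groups are distinct when the rounded integer calls differ.
#'
#' @param ref_copy 0 or 1.
#' @param parent_copies integer copies for the test genotypes (NAs, from
#'   platform-discordant genotypes, are ignored).
#' @return one of the six category labels, or `"unclassifiable"`.
#' @export
classify_pattern <- function(ref_copy, parent_copies) {
  cp <- parent_copies[!is.na(parent_copies)]
  if (!length(cp)) return("unclassifiable")
  if (ref_copy == 0) {
    groups <- unique(cp[cp > 0])
    if (length(groups) >= 2L) return("UpPAV+UpCNV")
    if (length(groups) == 1L) return("UpPAV")
    return("unclassifiable")
  }
  has0 <- any(cp == 0)
  up_groups <- unique(cp[cp > 1])
  if (has0 && length(up_groups)) return("UpCNV+DownCNV")
  if (has0) return("DownCNV/PAV")
  if (length(up_groups) >= 2L) return("Multi-Allelic UpCNV")
  if (length(up_groups) == 1L) return("UpCNV")
  "unclassifiable"
}

#' Heterogeneity flags per genotype
#'
#' A genotype is flagged when one platform is beyond its significance
#' thresholds while the other sits within 1 SD of its mean - the signature
#' of intra-line heterogeneity when the two platforms sample different
#' plants (bulk seed vs a single individual).
#'
#' @param points data.frame from [platform_points()].
#' @param cgh_thresholds,seq_thresholds `sv_thresholds`.
#' @return named logical vector per genotype.
#' @export
flag_heterogeneity <- function(points, cgh_thresholds, seq_thresholds) {
  gts <- points$genotype
  if (points$ref_copies[1] == 0) {
    # Reference-absent gene: "beyond" means the gene is present in the
    # test genotype; "null" means it is absent there too (both platforms
    # then agree with the empty reference).
    cgh_beyond <- points$cgh_score > cgh_thresholds[gts, "upper"]
    seq_beyond <- points$seq_copy > 0.5
    cgh_null <- abs(points$cgh_score - cgh_thresholds[gts, "mean"]) <=
      cgh_thresholds[gts, "sd"]
    seq_null <- points$seq_copy <= 0.25
    return(stats::setNames((cgh_beyond & seq_null) | (seq_beyond & cgh_null),
                           gts))
  }
  cgh_beyond <- points$cgh_score < cgh_thresholds[gts, "lower"] |
    points$cgh_score > cgh_thresholds[gts, "upper"]
  seq_beyond <- (points$seq_score < seq_thresholds[gts, "lower"] |
                   points$seq_score > seq_thresholds[gts, "upper"] |
                   points$seq_count_zero)
  cgh_null <- abs(points$cgh_score - cgh_thresholds[gts, "mean"]) <=
    cgh_thresholds[gts, "sd"]
  seq_null <- is.finite(points$seq_score) &
    abs(points$seq_score - seq_thresholds[gts, "mean"]) <=
    seq_thresholds[gts, "sd"]
  stats::setNames((cgh_beyond & seq_null) | (seq_beyond & cgh_null), gts)
}

#' Cross-validate and classify every candidate gene
#'
#' For each candidate gene: build the platform points, cluster alleles,
#' decide cross-validation, estimate integer copies and assign one of the
#' six categories; collect heterogeneity flags.
#'
#' @param candidates character vector from [candidate_set()].
#' @param cgh_scores a `gene_cgh_scores`.
#' @param seq a `seq_calls`.
#' @param cgh_thresholds an `sv_thresholds` for the CGH axis.
#' @param gap_min clustering gap (copy units).
#' @param disagree_tol platform-disagreement tolerance (log2 units).
#' @param deletion_floor CGH deletion floor.
#' @return object of class `sv_classification`: list with `genes`
#'   (data.frame: gene_id, category, cross_validated, n_clusters,
#'   ref_copies, n_het_flags), `copies` (genes x genotypes integer matrix),
#'   `het` (logical matrix), `points` (list per gene).
#' @export
crossval_classify <- function(candidates, cgh_scores, seq, cgh_thresholds,
                              gap_min = 0.75, disagree_tol = 2,
                              deletion_floor = 1 / 16) {
  seq_thr <- seq$thresholds
  gts <- colnames(cgh_scores$score)
  n <- length(candidates)
  copies <- matrix(NA_integer_, n, length(gts),
                   dimnames = list(candidates, gts))
  het <- matrix(FALSE, n, length(gts), dimnames = list(candidates, gts))
  rows <- vector("list", n)
  pts_list <- vector("list", n)
  names(pts_list) <- candidates
  for (i in seq_len(n)) {
    gene <- candidates[i]
    pts <- platform_points(gene, cgh_scores, seq, deletion_floor)
    pts_list[[i]] <- pts
    cl <- cluster_alleles(pts, cgh_thresholds, seq_thr, gap_min)
    est <- estimate_copies(pts, cgh_thresholds, disagree_tol)
    hflags <- flag_heterogeneity(pts, cgh_thresholds, seq_thr) |
      est$disagree
    category <- if (cl$cross_validated) {
      classify_pattern(pts$ref_copies[1], est$copies)
    } else NA_character_
    copies[i, ] <- est$copies
    het[i, ] <- hflags
    rows[[i]] <- data.frame(
      gene_id = gene, category = category,
      cross_validated = cl$cross_validated, n_clusters = cl$n_clusters,
      ref_copies = pts$ref_copies[1], n_het_flags = sum(hflags),
      stringsAsFactors = FALSE)
  }
  genes <- if (n) do.call(rbind, rows) else
    data.frame(gene_id = character(0), category = character(0),
               cross_validated = logical(0), n_clusters = integer(0),
               ref_copies = integer(0), n_het_flags = integer(0))
  rownames(genes) <- genes$gene_id
  structure(list(genes = genes, copies = copies, het = het,
                 points = pts_list),
            class = "sv_classification")
}

#' @export
print.sv_classification <- function(x, ...) {
  cat(sprintf("SV classification: %d candidate genes, %d cross-validated\n",
              nrow(x$genes), sum(x$genes$cross_validated)))
  cv <- x$genes$category[x$genes$cross_validated]
  if (length(cv)) print(table(factor(cv, levels = c(SV_CLASSES,
                                                    "unclassifiable"))))
  invisible(x)
}

#' Export per-gene scatter points
#'
#' Tab-separated long table (gene, genotype, scores, copy call, category) -
#' the package's analog of a public CGH-vs-RPKM scatter database.
#'
#' @param classification an `sv_classification`.
#' @param path output file.
#' @export
write_scatter <- function(classification, path) {
  rows <- lapply(names(classification$points), function(g) {
    p <- classification$points[[g]]
    data.frame(gene_id = g, genotype = p$genotype,
               cgh_score = p$cgh_score, seq_score = p$seq_score,
               copy_call = classification$copies[g, p$genotype],
               het_flag = classification$het[g, p$genotype],
               category = classification$genes[g, "category"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
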