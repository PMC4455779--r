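# Array-CGH calling: normalization, per-genotype thresholds, segmentation,
# segment- and gene-level (probe-average) CNV calls.

#' Median-center probe log2 ratios per genotype
#'
#' Stand-in for vendor spatial correction / qspline normalization: each
#' genotype's ratios are shifted so their median is 0. Idempotent.
#'
#' @param panel an `sv_panel`.
#' @return the panel with per-genotype median log2 ratio 0 and
#'   `normalized = TRUE`.
#' @export
normalize_ratios <- function(panel) {
  stopifnot(inherits(panel, "sv_panel"))
  if (nrow(panel$ratios) < 2L) {
    stop("need >= 2 probes per genotype to normalize", call. = FALSE)
  }
  if (length(unique(as.vector(panel$ratios))) == 1L &&
      nrow(panel$ratios) * ncol(panel$ratios) > 1L) {
    warning("all-constant ratio matrix: returned unchanged")
    panel$normalized <- TRUE
    return(panel)
  }
  med <- apply(panel$ratios, 2, stats::median)
  panel$ratios <- sweep(panel$ratios, 2, med, `-`)
  panel$normalized <- TRUE
  panel
}

#' Per-genotype significance thresholds
#'
#' For each genotype the lower threshold is `down_sd` (default 3) standard
#' deviations below that genotype's mean log2 ratio and the upper threshold
#' `up_sd` (default 2) SDs above it. Thresholds are computed separately per
#' genotype comparison.
#'
#' @param panel an `sv_panel` (or any probes x genotypes numeric matrix).
#' @param genotypes genotypes to compute (default all columns).
#' @param down_sd,up_sd SD multipliers for the lower / upper threshold.
#' @return object of class `sv_thresholds`: data.frame with columns
#'   genotype, mean, sd, lower, upper.
#' @export
compute_thresholds <- function(panel, genotypes = NULL, down_sd = 3,
                               up_sd = 2) {
  x <- if (inherits(panel, "sv_panel")) panel$ratios else as.matrix(panel)
  if (is.null(genotypes)) genotypes <- colnames(x)
  if (!all(is.finite(x[, genotypes]))) {
    stop("non-finite ratios in panel", call. = FALSE)
  }
  m <- colMeans(x[, genotypes, drop = FALSE])
  s <- apply(x[, genotypes, drop = FALSE], 2, stats::sd)
  if (any(s == 0)) {
    stop("degenerate panel: zero SD for genotype(s) ",
         paste(genotypes[s == 0], collapse = ", "),
         "; supply fixed_thresholds() instead", call. = FALSE)
  }
  structure(data.frame(genotype = genotypes, mean = m, sd = s,
                       lower = m - down_sd * s, upper = m + up_sd * s,
                       row.names = genotypes, stringsAsFactors = FALSE),
            class = c("sv_thresholds", "data.frame"))
}

#' Fixed thresholds for degenerate (noise-free) panels
#'
#' @param lower,upper fixed thresholds applied to every genotype.
#' @param genotypes genotype ids.
#' @param mean,sd nominal center/scale recorded alongside (defaults: 0 and
#'   `upper / 2`, consistent with a 2-SD upper threshold).
#' @return an `sv_thresholds` data.frame.
#' @export
fixed_thresholds <- function(lower, upper, genotypes, mean = 0, sd = NULL) {
  stopifnot(lower < upper)
  if (is.null(sd)) sd <- (upper - mean) / 2
  structure(data.frame(genotype = genotypes, mean = mean, sd = sd,
                       lower = lower, upper = upper, row.names = genotypes,
                       stringsAsFactors = FALSE),
            class = c("sv_thresholds", "data.frame"))
}

# Best candidate segment of x: the interval [i, j] (min_len <= length <=
# max_len, flanks empty or >= min_len) maximizing the absolute difference
# between the interval mean and the mean of its complement. Returns
# list(i, j, stat) or NULL when the window cannot be split. The scan is
# compiled (see src/best_interval.cpp).
best_split <- function(x, min_len, max_len = length(x)) {
  res <- best_interval_cpp(x, as.integer(min_len), as.integer(max_len))
  if (res$i == 0L) return(NULL)
  res
}

#' Segmentation parameters
#'
#' Defaults match the array-vendor segmentation settings the calling
#' procedure was tuned with: minimum between-segment mean difference 0.1,
#' minimum segment length 2 probes, permutation acceptance percentile 0.99
#' with 10 permutations.
#'
#' @param min_diff minimum difference between adjacent segment means.
#' @param min_len minimum probes per segment.
#' @param acceptance percentile of the permutation null the observed split
#'   statistic must exceed.
#' @param n_perm number of within-window permutations per candidate split.
#' @param max_len maximum probes in a candidate segment scanned per
#'   recursion step (longer runs emerge by recursion on the flanks).
#' @param seed seed for the permutation draws.
#' @return a named list of class `segmentation_params`.
#' @export
segmentation_params <- function(min_diff = 0.1, min_len = 2L,
                                acceptance = 0.99, n_perm = 10L,
                                max_len = 100L, seed = 1L) {
  stopifnot(min_diff >= 0, min_len >= 1, acceptance > 0, acceptance <= 1,
            n_perm >= 1, max_len >= min_len)
  structure(list(min_diff = min_diff, min_len = as.integer(min_len),
                 acceptance = acceptance, n_perm = as.integer(n_perm),
                 max_len = as.integer(max_len), seed = as.integer(seed)),
            class = "segmentation_params")
}

# Recursive changepoint segmentation of one probe vector: per step the best
# candidate interval (vs its complement) is found and accepted only if its
# mean difference exceeds both `min_diff` and the `acceptance` percentile of
# `n_perm` within-window permutations; accepted intervals split the window
# into up to three children, recursed independently.
segment_vector <- function(x, params) {
  recurse <- function(lo, hi) {
    w <- x[lo:hi]
    sp <- best_split(w, params$min_len, params$max_len)
    if (is.null(sp)) return(list(c(lo, hi)))
    if (sp$stat >= params$min_diff) {
      perm <- vapply(seq_len(params$n_perm), function(b) {
        best_split(sample(w), params$min_len, params$max_len)$stat
      }, numeric(1))
      thr <- stats::quantile(perm, params$acceptance, names = FALSE)
      if (sp$stat > thr) {
        i <- lo + sp$i - 1L
        j <- lo + sp$j - 1L
        out <- list()
        if (i > lo) out <- c(out, recurse(lo, i - 1L))
        out <- c(out, recurse(i, j))
        if (j < hi) out <- c(out, recurse(j + 1L, hi))
        return(out)
      }
    }
    list(c(lo, hi))
  }
  pieces <- recurse(1L, length(x))
  # Enforce the contract that adjacent segments differ by >= min_diff:
  # iteratively merge neighbours whose means are closer than that.
  repeat {
    if (length(pieces) < 2L) break
    means <- vapply(pieces, function(p) mean(x[p[1]:p[2]]), numeric(1))
    d <- abs(diff(means))
    if (all(d >= params$min_diff)) break
    i <- which.min(d)
    pieces[[i]] <- c(pieces[[i]][1], pieces[[i + 1L]][2])
    pieces[[i + 1L]] <- NULL
  }
  pieces
}

#' Segment one genotype's probe ratios
#'
#' Recursive binary changepoint splitting per chromosome: each candidate
#' split maximizes the absolute difference of flanking means and is accepted
#' only when that difference exceeds both `min_diff` and the `acceptance`
#' percentile of `n_perm` within-window permutations of the probe values.
#' Windows shorter than `2 * min_len` are returned as single segments.
#'
#' @param panel an `sv_panel` with probes sorted by coordinate.
#' @param genotype genotype id (a column of the ratio matrix).
#' @param params a [segmentation_params()].
#' @return data.frame of segments: genotype, chrom, start, end (bp, 0-based
#'   half-open, spanning first to last member probe), first_probe,
#'   last_probe (row indices into `panel$probes`), n_probes, mean.
#' @export
segment_probes <- function(panel, genotype, params = segmentation_params()) {
  stopifnot(inherits(panel, "sv_panel"),
            genotype %in% colnames(panel$ratios))
  set.seed(params$seed + match(genotype, colnames(panel$ratios)))
  out <- list()
  for (ch in unique(panel$probes$chrom)) {
    idx <- which(panel$probes$chrom == ch)
    if (!length(idx)) next
    stopifnot(!is.unsorted(panel$probes$start[idx]))
    x <- panel$ratios[idx, genotype]
    pieces <- segment_vector(x, params)
    for (p in pieces) {
      gi <- idx[p[1]:p[2]]
      out[[length(out) + 1L]] <- data.frame(
        genotype = genotype, chrom = ch,
        start = panel$probes$start[gi[1]],
        end = panel$probes$end[gi[length(gi)]],
        first_probe = gi[1], last_probe = gi[length(gi)],
        n_probes = length(gi), mean = mean(x[p[1]:p[2]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Direction-call segments against a genotype's thresholds
#'
#' A segment is Down iff its mean is strictly below the lower threshold, Up
#' iff strictly above the upper threshold, otherwise neutral (boundary
#' equality is neutral).
#'
#' @param segments data.frame from [segment_probes()] (any genotypes).
#' @param thresholds an `sv_thresholds`.
#' @return the segments with a `direction` column in
#'   `c("Down", "Up", "neutral")`.
#' @export
call_segment_cnv <- function(segments, thresholds) {
  stopifnot(all(segments$genotype %in% rownames(thresholds)))
  lo <- thresholds[segments$genotype, "lower"]
  up <- thresholds[segments$genotype, "upper"]
  segments$direction <- ifelse(segments$mean < lo, "Down",
                               ifelse(segments$mean > up, "Up", "neutral"))
  segments
}

#' Segment and call every genotype
#'
#' @param panel an `sv_panel`.
#' @param thresholds an `sv_thresholds` covering all genotypes.
#' @param params a [segmentation_params()].
#' @return row-bound segment calls for all genotypes (see
#'   [call_segment_cnv()]).
#' @export
call_cgh_segments <- function(panel, thresholds,
                              params = segmentation_params()) {
  segs <- do.call(rbind, lapply(colnames(panel$ratios), function(g) {
    segment_probes(panel, g, params)
  }))
  call_segment_cnv(segs, thresholds)
}

#' Probe-average log2 score per gene
#'
#' Every gene receives a score per genotype via one of three pathways,
#' recorded in `source`: the mean of probes overlapping genic space
#' (`"probe-average"`; overlap is any bp intersection of half-open
#' intervals); for probe-less genes the mean of the covering segment in that
#' genotype (`"segment-average"`); otherwise the mean of the two nearest
#' probes on the chromosome (`"nearest-two-probes"`).
#'
#' @param genome an `sv_genome` (or a gene data.frame with gene_id, chrom,
#'   start, end).
#' @param panel an `sv_panel`.
#' @param segments segment calls from [call_cgh_segments()]; may be `NULL`,
#'   in which case the segment-average fallback is skipped.
#' @return object of class `gene_cgh_scores`: list with matrices `score`
#'   and `source` (genes x genotypes).
#' @export
score_genes_cgh <- function(genome, panel, segments = NULL) {
  genes <- if (inherits(genome, "sv_genome")) genome$genes else genome
  gts <- colnames(panel$ratios)
  ng <- nrow(genes)
  score <- matrix(NA_real_, ng, length(gts),
                  dimnames = list(genes$gene_id, gts))
  src <- matrix(NA_character_, ng, length(gts),
                dimnames = list(genes$gene_id, gts))

  gr_genes <- granges_from0(genes$chrom, genes$start, genes$end)
  gr_probes <- granges_from0(panel$probes$chrom, panel$probes$start,
                             panel$probes$end)
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_probes)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (gi in unique(qh)) {
    pidx <- sh[qh == gi]
    score[gi, ] <- colMeans(panel$ratios[pidx, , drop = FALSE])
    src[gi, ] <- "probe-average"
  }

  missing <- which(is.na(score[, 1]))
  if (length(missing)) {
    gr_segs <- if (!is.null(segments) && nrow(segments)) {
      granges_from0(segments$chrom, segments$start, segments$end)
    } else NULL
    for (gi in missing) {
      ch <- genes$chrom[gi]
      pidx <- which(panel$probes$chrom == ch)
      seg_here <- if (!is.null(gr_segs)) {
        which(segments$chrom == ch & segments$start < genes$end[gi] &
                segments$end > genes$start[gi])
      } else integer(0)
      if (!length(pidx) && !length(seg_here)) {
        stop("gene without probes or segments on its chromosome: ",
             genes$gene_id[gi], call. = FALSE)
      }
      mid <- (genes$start[gi] + genes$end[gi]) / 2
      for (g in gts) {
        sg <- seg_here[segments$genotype[seg_here] == g]
        if (length(sg)) {
          score[gi, g] <- mean(segments$mean[sg])
          src[gi, g] <- "segment-average"
        } else if (length(pidx) >= 2L) {
          d <- abs((panel$probes$start[pidx] + panel$probes$end[pidx]) / 2 -
                     mid)
          nearest <- pidx[order(d)[1:2]]
          score[gi, g] <- mean(panel$ratios[nearest, g])
          src[gi, g] <- "nearest-two-probes"
        } else if (length(pidx) == 1L) {
          score[gi, g] <- panel$ratios[pidx, g]
          src[gi, g] <- "nearest-two-probes"
        } else {
          stop("gene without probes or covering segment for genotype ", g,
               ": ", genes$gene_id[gi], call. = FALSE)
        }
      }
    }
  }
  structure(list(score = score, source = src), class = "gene_cgh_scores")
}

#' Gene-level CGH CNV calls from probe-average scores
#'
#' Applies the same strict threshold rule as [call_segment_cnv()] to the
#' per-gene scores.
#'
#' @param scores a `gene_cgh_scores` from [score_genes_cgh()].
#' @param thresholds an `sv_thresholds`.
#' @return character matrix genes x genotypes with values
#'   `"Down"`, `"Up"`, `"neutral"`.
#' @export
call_probe_cnv <- function(scores, thresholds) {
  x <- scores$score
  gts <- colnames(x)
  stopifnot(all(gts %in% rownames(thresholds)))
  lo <- matrix(thresholds[gts, "lower"], nrow(x), length(gts), byrow = TRUE)
  up <- matrix(thresholds[gts, "upper"], nrow(x), length(gts), byrow = TRUE)
  out <- matrix("neutral", nrow(x), ncol(x), dimnames = dimnames(x))
  out[x < lo] <- "Down"
  out[x > up] <- "Up"
  out
}
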