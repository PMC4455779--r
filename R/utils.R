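#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

#' Derive deterministic sub-seeds from a master seed
#'
#' All stochastic stages draw their own seed from the master seed so that
#' stages can be re-run independently yet reproduce the full-pipeline result.
#'
#' @param master integer master seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Round half away from zero
#'
#' Copy-number estimates are rounded half-away-from-zero (so 2.5 -> 3),
#' unlike base `round()`'s round-half-to-even.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 2.5, -0.5))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' One-dimensional gap clustering
#'
#' Sorts values and opens a new cluster wherever the gap between successive
#' values exceeds `gap`. Deterministic and auditable; used to separate
#' copy-number allele classes.
#'
#' @param x numeric vector (finite values).
#' @param gap minimum gap that separates two clusters.
#' @return list with `assignment` (integer cluster id per element of `x`,
#'   clusters numbered by increasing center) and `centers` (numeric vector of
#'   cluster means).
#' @export
gap_clusters <- function(x, gap) {
  stopifnot(is.numeric(x), length(x) >= 1L, all(is.finite(x)), gap >= 0)
  ord <- order(x)
  xs <- x[ord]
  new_cluster <- c(TRUE, diff(xs) > gap)
  cl_sorted <- cumsum(new_cluster)
  assignment <- integer(length(x))
  assignment[ord] <- cl_sorted
  centers <- as.numeric(tapply(x, assignment, mean))
  list(assignment = assignment, centers = centers)
}

# Validate a scalar count argument.
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

# Build a GRanges from 0-based half-open coordinates.
granges_from0 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0)
  )
}

# Default genotype naming: one reference, one deeply sequenced hub line and
# n_test - 1 minor lines, mirroring a NAM-panel design.
panel_genotypes <- function(n_test = 41L, reference = "Wm82",
                            hub = "IA3023") {
  n_test <- check_count(n_test, "n_test", min = 1L)
  tests <- c(hub, sprintf("NAM%02d", seq_len(n_test - 1L)))[seq_len(n_test)]
  list(reference = reference, tests = tests, all = c(reference, tests))
}

# The six structural-variant categories.
SV_CLASSES <- c("DownCNV/PAV", "UpPAV", "UpPAV+UpCNV", "UpCNV+DownCNV",
                "UpCNV", "Multi-Allelic UpCNV")
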