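# Hypergeometric domain enrichment with min-p resampling correction, and
# the retained-paralog contrast.

#' Upper-tail hypergeometric enrichment test
#'
#' For a gene universe of size `N`, `K` genes carrying a domain and a list
#' of `n` genes of which `obs` carry the domain: expected overlap
#' `K * n / N` and `p = P(X >= obs)` for X hypergeometric.
#'
#' @param N universe size.
#' @param K genes with the domain.
#' @param n list size.
#' @param obs observed overlap.
#' @return list with `exp` and `p_raw`.
#' @export
#' @examples
#' hypergeom_test(53833, 1110, 1100, 168)$exp  # ~22.68
hypergeom_test <- function(N, K, n, obs) {
  if (K > N || n > N || obs > min(K, n) || obs < 0) {
    stop("infeasible counts for hypergeometric test", call. = FALSE)
  }
  list(exp = K * n / N,
       p_raw = stats::phyper(obs - 1, K, N - K, n, lower.tail = FALSE))
}

#' Family-wise adjustment of enrichment p-values by min-p resampling
#'
#' For each of `n_sims` simulations a random gene list of the same size is
#' drawn from the universe and the minimum raw hypergeometric p over all
#' domains recorded; the adjusted p of a domain is the fraction of
#' simulations whose minimum p is at or below the domain's raw p. This is
#' the classic Westfall-Young style family-wise correction and is monotone
#' in the raw p.
#'
#' @param p_raw named numeric vector of raw p-values per domain.
#' @param domain_sets list (domain -> character vector of member genes).
#' @param universe character vector of all genes.
#' @param n list size used for the observed p-values.
#' @param n_sims simulations (default 10000).
#' @param seed random seed.
#' @return named numeric vector of adjusted p-values (`>= p_raw`).
#' @export
resample_adjust <- function(p_raw, domain_sets, universe, n,
                            n_sims = 10000L, seed = 1L) {
  stopifnot(all(names(p_raw) %in% names(domain_sets)), n <= length(universe))
  set.seed(seed)
  N <- length(universe)
  membership <- vapply(domain_sets[names(p_raw)], function(g) {
    universe %in% g
  }, logical(N))
  K <- colSums(membership)
  min_p <- vapply(seq_len(n_sims), function(b) {
    idx <- sample.int(N, n)
    obs <- colSums(membership[idx, , drop = FALSE])
    min(stats::phyper(obs - 1, K, N - K, n, lower.tail = FALSE))
  }, numeric(1))
  ecdf_min <- stats::ecdf(min_p)
  adj <- pmax(ecdf_min(p_raw), p_raw * 0)  # fraction of sims with min-p <= p
  adj <- pmin(pmax(adj, p_raw), 1)         # adjusted p never below raw p
  stats::setNames(adj, names(p_raw))
}

#' Domain enrichment of one gene list
#'
#' Runs [hypergeom_test()] for every domain and adjusts family-wise via
#' [resample_adjust()]. Significance stars: `*` adjusted p < 0.01, `**`
#' adjusted p < 0.001.
#'
#' @param gene_list character vector of genes (e.g. one SV category).
#' @param pfam data.frame with columns gene_id, domain (clan aggregation,
#'   if any, applied upstream in this table).
#' @param universe all assessed genes.
#' @param n_sims,seed resampling controls.
#' @return data.frame of class `enrichment_result`: domain, N, K, n, obs,
#'   exp, exp_rounded, p_raw, p_adj, stars.
#' @export
enrich_domains <- function(gene_list, pfam, universe, n_sims = 10000L,
                           seed = 1L) {
  stopifnot(all(c("gene_id", "domain") %in% names(pfam)))
  domain_sets <- split(pfam$gene_id, pfam$domain)
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(domain_sets), function(d) {
    K <- length(unique(domain_sets[[d]]))
    obs <- length(intersect(gene_list, domain_sets[[d]]))
    ht <- hypergeom_test(N, K, n, obs)
    data.frame(domain = d, N = N, K = K, n = n, obs = obs, exp = ht$exp,
               p_raw = ht$p_raw, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- resample_adjust(
    stats::setNames(res$p_raw, res$domain), domain_sets, universe, n,
    n_sims = n_sims, seed = seed)
  res$exp_rounded <- round(res$exp)
  res$stars <- ifelse(res$p_adj < 0.001, "**",
                      ifelse(res$p_adj < 0.01, "*", ""))
  res <- res[order(res$p_adj, res$p_raw), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' SV depletion among genes with retained syntenic paralogs
#'
#' Contrasts the SV rate between genes with and without a retained paralog:
#' rates, the fold difference (`rate_without / rate_with`) and a two-sided
#' Fisher exact p on the 2x2 table.
#'
#' @param sv_with,total_with SV genes and total genes with a retained
#'   paralog.
#' @param sv_without,total_without same for genes without one.
#' @return object of class `paralog_contrast`: list with the four counts,
#'   `rate_with`, `rate_without` (fractions), `fold`, `fisher_p`.
#' @export
#' @examples
#' paralog_contrast_counts(244, 32464, 1284, 21369)$fold  # ~8
paralog_contrast_counts <- function(sv_with, total_with, sv_without,
                                    total_without) {
  stopifnot(total_with > 0, total_without > 0, sv_with <= total_with,
            sv_without <= total_without)
  rate_with <- sv_with / total_with
  rate_without <- sv_without / total_without
  if (rate_with == 0) stop("zero SV rate among paralog-retaining genes",
                           call. = FALSE)
  tab <- matrix(c(sv_with, total_with - sv_with,
                  sv_without, total_without - sv_without), 2, byrow = TRUE)
  structure(list(sv_with = sv_with, total_with = total_with,
                 sv_without = sv_without, total_without = total_without,
                 rate_with = rate_with, rate_without = rate_without,
                 fold = rate_without / rate_with,
                 fisher_p = stats::fisher.test(tab)$p.value),
            class = "paralog_contrast")
}

#' @rdname paralog_contrast_counts
#' @param sv_genes character vector of SV gene ids.
#' @param genes gene data.frame with `gene_id` and `paralog` columns (or an
#'   `sv_genome`).
#' @export
paralog_contrast <- function(sv_genes, genes) {
  if (inherits(genes, "sv_genome")) genes <- genes$genes
  with_par <- !is.na(genes$paralog)
  is_sv <- genes$gene_id %in% sv_genes
  paralog_contrast_counts(sum(is_sv & with_par), sum(with_par),
                          sum(is_sv & !with_par), sum(!with_par))
}

#' @export
print.paralog_contrast <- function(x, ...) {
  cat("Retained-paralog SV contrast\n")
  cat(sprintf("  with paralog:    %d / %d (%.2f%%)\n", x$sv_with,
              x$total_with, 100 * x$rate_with))
  cat(sprintf("  without paralog: %d / %d (%.2f%%)\n", x$sv_without,
              x$total_without, 100 * x$rate_without))
  cat(sprintf("  fold difference: %.2f (Fisher p = %.3g)\n", x$fold,
              x$fisher_p))
  invisible(x)
}
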