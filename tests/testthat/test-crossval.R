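# Cross-platform validation, copy estimation and the six-category rules.

test_that("candidate set is segment genes plus the probe/seq intersection", {
  genes <- data.frame(
    gene_id = c("gSeg", "gBoth", "gSeqOnly", "gNone"),
    chrom = "chr01", start = c(0, 2000, 4000, 6000),
    end = c(1000, 3000, 5000, 7000), length = 1000,
    stringsAsFactors = FALSE)
  seg_calls <- data.frame(genotype = "A", chrom = "chr01", start = 0,
                          end = 900, mean = -2, direction = "Down",
                          stringsAsFactors = FALSE)
  probe <- dir_matrix(genes$gene_id, c("A", "B"))
  seqd <- dir_matrix(genes$gene_id, c("A", "B"))
  probe["gBoth", "A"] <- "Down"
  seqd["gBoth", "B"] <- "Down"   # any-genotype logic across platforms
  seqd["gSeqOnly", "A"] <- "Down"
  expect_setequal(candidate_set(genes, seg_calls, probe, seqd),
                  c("gSeg", "gBoth"))
  # neutral segments do not nominate candidates
  seg_calls$direction <- "neutral"
  expect_setequal(candidate_set(genes, seg_calls, probe, seqd), "gBoth")
})

test_that("copy estimates round half away from zero on the mean log-score", {
  pts <- data.frame(
    genotype = c("A", "B", "C"),
    cgh_score = c(1.0, -4, 3.3), seq_score = c(1.0, -Inf, 3.4),
    cgh_copy = 2^c(1.0, -4, 3.3), seq_copy = c(2, 0, 2^3.4),
    seq_count_zero = c(FALSE, TRUE, FALSE), ref_copies = 1L,
    row.names = c("A", "B", "C"), stringsAsFactors = FALSE)
  thr <- fixed_thresholds(-0.45, 0.3, c("A", "B", "C"), mean = 0, sd = 0.15)
  est <- estimate_copies(pts, thr)
  expect_equal(unname(est$copies), c(2L, 0L, 10L))  # 2^1, deletion, Rhg1-like
  expect_false(any(est$disagree))

  # platform disagreement beyond tolerance suppresses the integer call
  pts2 <- pts
  pts2[1, c("cgh_score", "seq_score")] <- c(-4, 0)
  est2 <- estimate_copies(pts2, thr)
  expect_true(is.na(est2$copies["A"]))
  expect_true(est2$disagree["A"])
})

test_that("allele clustering cross-validates only two-axis splits", {
  mk <- function(cgh, seq) {
    n <- length(cgh)
    data.frame(genotype = sprintf("G%02d", seq_len(n)),
               cgh_score = log2(pmax(cgh, 1e-3)),
               seq_score = log2(pmax(seq, 1e-3)),
               cgh_copy = cgh, seq_copy = seq,
               seq_count_zero = FALSE, ref_copies = 1L,
               row.names = sprintf("G%02d", seq_len(n)),
               stringsAsFactors = FALSE)
  }
  thr <- function(n) fixed_thresholds(-0.45, 0.3, sprintf("G%02d", 1:n),
                                      mean = 0, sd = 0.15)
  # all 41 at (1, 1): single cluster, no cross-validation
  pts <- mk(rep(1, 41), rep(1, 41))
  cl <- cluster_alleles(pts, thr(41), thr(41))
  expect_equal(cl$n_clusters, 1L)
  expect_false(cl$cross_validated)

  # 38 at (1,1), 3 near (0,0): two clusters, cross-validated
  pts2 <- mk(c(rep(1, 38), rep(0.06, 3)), c(rep(1, 38), rep(0, 3)))
  cl2 <- cluster_alleles(pts2, thr(41), thr(41))
  expect_equal(cl2$n_clusters, 2L)
  expect_true(cl2$cross_validated)

  # split on the CGH axis only: platform discordance, not cross-validated
  pts3 <- mk(c(rep(1, 38), rep(0.06, 3)), rep(1, 41))
  cl3 <- cluster_alleles(pts3, thr(41), thr(41))
  expect_false(cl3$cross_validated)
})

test_that("the six-category rules follow the decision order", {
  expect_equal(classify_pattern(1L, c(0L, 1L, 1L)), "DownCNV/PAV")
  expect_equal(classify_pattern(0L, c(0L, 1L, 1L)), "UpPAV")
  expect_equal(classify_pattern(0L, c(0L, 1L, 3L)), "UpPAV+UpCNV")
  expect_equal(classify_pattern(1L, c(0L, 1L, 3L)), "UpCNV+DownCNV")
  expect_equal(classify_pattern(1L, c(1L, 2L, 2L)), "UpCNV")
  expect_equal(classify_pattern(1L, c(1L, 3L, 10L)), "Multi-Allelic UpCNV")
  expect_equal(classify_pattern(1L, c(1L, 1L)), "unclassifiable")
  expect_equal(classify_pattern(0L, c(0L, 0L)), "unclassifiable")
  # NAs (discordant genotypes) are ignored
  expect_equal(classify_pattern(1L, c(NA, 0L, 1L)), "DownCNV/PAV")
})

test_that("heterogeneity flags require one platform beyond, one null", {
  pts <- data.frame(
    genotype = c("A", "B", "C"),
    cgh_score = c(-4, -4, 0), seq_score = c(0, -4, -0.2),
    cgh_copy = 2^c(-4, -4, 0), seq_copy = c(1, 2^-4, 2^-0.2),
    seq_count_zero = FALSE, ref_copies = 1L,
    row.names = c("A", "B", "C"), stringsAsFactors = FALSE)
  thr <- fixed_thresholds(-0.45, 0.3, c("A", "B", "C"), mean = 0, sd = 0.15)
  fl <- flag_heterogeneity(pts, thr, thr)
  expect_true(fl[["A"]])    # CGH beyond, seq null
  expect_false(fl[["B"]])   # both beyond: a real variant
  expect_false(fl[["C"]])   # both null
})

test_that("noise-free runs recover every planted category exactly", {
  ex <- noise_free_experiment(seed = 5, n_events = 6)
  run <- run_sv_pipeline(fixed_cfg(seed = 5), experiment = ex,
                         run_neutral = FALSE, run_enrichment = FALSE)
  cv <- run$classification$genes
  ge <- ex$truth$gene_events
  for (id in rownames(ex$truth$events)) {
    gids <- names(ge)[ge == id]
    expect_true(any(cv[gids, "cross_validated"] &
                      cv[gids, "category"] == ex$truth$events[id, "class"],
                    na.rm = TRUE),
                label = paste("event", id, ex$truth$events[id, "class"]))
  }
  # partition property: every cross-validated gene has exactly one category
  cvg <- cv[cv$cross_validated, ]
  expect_true(all(!is.na(cvg$category)))
  expect_true(all(table(cvg$gene_id) == 1L))
})

test_that("classification is invariant to genotype ordering", {
  ex <- noise_free_experiment(seed = 8, n_events = 6)
  run <- run_sv_pipeline(fixed_cfg(seed = 8), experiment = ex,
                         run_neutral = FALSE, run_enrichment = FALSE)
  gene <- run$classification$genes$gene_id[
    run$classification$genes$cross_validated][1]
  pts <- platform_points(gene, run$cgh_scores, run$seq)
  thr <- run$cgh_thresholds
  base_cat <- classify_pattern(pts$ref_copies[1],
                               estimate_copies(pts, thr)$copies)
  for (i in 1:5) {
    perm <- sample(nrow(pts))
    pts_p <- pts[perm, ]
    cat_p <- classify_pattern(pts_p$ref_copies[1],
                              estimate_copies(pts_p, thr)$copies)
    expect_identical(cat_p, base_cat)
  }
})
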