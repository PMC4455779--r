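# Segment collapsing and the reference-based frequency spectrum.

# Hand-built classification over five genes on one chromosome.
mk_classification <- function(categories) {
  genes <- names(categories)
  df <- data.frame(gene_id = genes, category = unname(categories),
                   cross_validated = !is.na(categories),
                   n_clusters = 2L, ref_copies = 1L, n_het_flags = 0L,
                   stringsAsFactors = FALSE)
  rownames(df) <- genes
  structure(list(genes = df,
                 copies = matrix(NA_integer_, length(genes), 0),
                 het = matrix(FALSE, length(genes), 0),
                 points = list()),
            class = "sv_classification")
}

mk_genome5 <- function() {
  genes <- data.frame(
    gene_id = sprintf("g%d", 1:5), chrom = "chr01",
    start = seq(0, 8000, by = 2000),
    end = seq(0, 8000, by = 2000) + 1000, length = 1000,
    stringsAsFactors = FALSE)
  rownames(genes) <- genes$gene_id
  structure(list(genes = genes,
                 probes = data.frame(probe_id = character(0),
                                     chrom = character(0), start = numeric(0),
                                     end = numeric(0)),
                 pfam = data.frame(gene_id = character(0),
                                   domain = character(0)),
                 chrom_lengths = c(chr01 = 10000),
                 config = NULL), class = "sv_genome")
}

guide_segment <- function(start, end, direction = "Down", genotype = "A") {
  data.frame(genotype = genotype, chrom = "chr01", start = start, end = end,
             first_probe = 1, last_probe = 2, n_probes = 2, mean = -3,
             direction = direction, stringsAsFactors = FALSE)
}

test_that("adjacent member genes under one guide segment collapse", {
  genome <- mk_genome5()
  cls <- mk_classification(c(g1 = "DownCNV/PAV", g2 = "DownCNV/PAV",
                             g3 = "DownCNV/PAV", g4 = NA, g5 = NA))
  guide <- guide_segment(0, 5200)
  segs <- collapse_segments(cls, genome, guide, "Down")
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_genes, 3L)
  expect_setequal(explode_segments(segs), c("g1", "g2", "g3"))
  expect_equal(segs$start, 0)
  expect_equal(segs$end, 5000)
})

test_that("an intervening non-SV gene or missing guide splits the run", {
  genome <- mk_genome5()
  # g1, g3 are Down but g2 is retained non-SV: two segments
  cls <- mk_classification(c(g1 = "DownCNV/PAV", g2 = NA,
                             g3 = "DownCNV/PAV", g4 = NA, g5 = NA))
  guide <- guide_segment(0, 5200)
  segs <- collapse_segments(cls, genome, guide, "Down")
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$n_genes, c(1L, 1L))

  # adjacent genes without a shared covering guide segment stay separate
  cls2 <- mk_classification(c(g1 = "DownCNV/PAV", g2 = "DownCNV/PAV",
                              g3 = NA, g4 = NA, g5 = NA))
  guide2 <- guide_segment(0, 900)  # covers g1 only
  segs2 <- collapse_segments(cls2, genome, guide2, "Down")
  expect_equal(nrow(segs2), 2L)
})

test_that("Up segments take only the UpCNV and Multi-Allelic subclasses", {
  genome <- mk_genome5()
  cls <- mk_classification(c(g1 = "UpCNV", g2 = "Multi-Allelic UpCNV",
                             g3 = "UpPAV", g4 = NA, g5 = NA))
  guide <- guide_segment(0, 5200, direction = "Up")
  segs <- collapse_segments(cls, genome, guide, "Up")
  expect_equal(nrow(segs), 1L)
  expect_setequal(explode_segments(segs), c("g1", "g2"))  # UpPAV excluded
})

test_that("carriers must exceed both platform thresholds at one gene", {
  genome <- mk_genome5()
  cls <- mk_classification(c(g1 = "DownCNV/PAV", g2 = "DownCNV/PAV",
                             g3 = NA, g4 = NA, g5 = NA))
  guide <- guide_segment(0, 3200)
  segs <- collapse_segments(cls, genome, guide, "Down")
  gts <- sprintf("G%02d", 1:6)
  probe <- dir_matrix(genome$genes$gene_id, gts)
  seqd <- dir_matrix(genome$genes$gene_id, gts)
  probe["g1", c("G01", "G02", "G03")] <- "Down"
  seqd["g1", c("G01", "G02", "G04")] <- "Down"
  probe["g2", "G05"] <- "Down"
  seqd["g2", "G05"] <- "Down"
  k <- segment_frequency(segs, probe, seqd)
  # carriers: G01, G02 (both platforms at g1), G05 (both at g2);
  # G03 and G04 exceed one platform only
  expect_equal(unname(k[segs$segment_id]), 3L)

  # a segment with no dual-platform carrier is dropped with a warning
  probe["g1", ] <- "neutral"; probe["g2", ] <- "neutral"
  expect_warning(k2 <- segment_frequency(segs, probe, seqd), "dropped")
  expect_equal(length(k2), 0L)
})

test_that("the spectrum tabulates carrier counts and conserves totals", {
  sp <- build_rsfs(c(1, 1, 2), n_test = 5, label = "empirical-Down")
  expect_equal(as.integer(sp), c(2L, 1L, 0L, 0L, 0L))
  expect_equal(sum(sp), 3L)
  sp0 <- build_rsfs(integer(0), n_test = 5)
  expect_equal(sum(sp0), 0L)
  expect_error(build_rsfs(c(0, 2), n_test = 5))
  expect_error(build_rsfs(c(6), n_test = 5))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, path)
  back <- read_spectrum(path)
  expect_equal(as.integer(back), as.integer(sp))
})

test_that("planted carrier counts follow the requested 1/k spectrum", {
  g <- generate_annotation(genome_config(seed = 31))
  tr <- plant_events(g, n_events = 150, carrier_spectrum = "onebyk",
                     class_probs = c("DownCNV/PAV" = 1), het_prob = 0,
                     seed = 31)
  k <- tr$events$n_carriers
  p <- (1 / 1:41) / sum(1 / 1:41)
  # coarse bins keep expected counts reasonable for a chi-square GOF
  bins <- cut(k, c(0, 1, 2, 4, 8, 41))
  pb <- c(p[1], p[2], sum(p[3:4]), sum(p[5:8]), sum(p[9:41]))
  gof <- suppressWarnings(chisq.test(table(bins), p = pb))
  expect_gt(gof$p.value, 1e-3)
})
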