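# CGH calling: normalization, thresholds, segmentation, gene scoring.

make_panel <- function(ratios, spacing = 500) {
  n <- nrow(ratios)
  probes <- data.frame(probe_id = sprintf("p%04d", seq_len(n)),
                       chrom = "chr01",
                       start = seq(0, by = spacing, length.out = n),
                       end = seq(0, by = spacing, length.out = n) + 60,
                       stringsAsFactors = FALSE)
  structure(list(probes = probes, ratios = ratios, normalized = FALSE),
            class = "sv_panel")
}

test_that("median centering normalizes each genotype and is idempotent", {
  m <- cbind(A = c(0.1, 0.1, 0.1), B = c(-1, 0, 3))
  p <- normalize_ratios(make_panel(m))
  expect_equal(unname(p$ratios[, "A"]), c(0, 0, 0))
  expect_equal(unname(p$ratios[, "B"]), c(-1, 0, 3))  # median already 0
  p2 <- normalize_ratios(p)
  expect_equal(p$ratios, p2$ratios)
  expect_warning(normalize_ratios(make_panel(cbind(A = rep(0.2, 5)))),
                 "constant")
})

test_that("thresholds are mean - 3 SD and mean + 2 SD per genotype", {
  set.seed(1)
  m <- cbind(A = rnorm(500, 0, 0.1), B = rnorm(500, 0.05, 0.2))
  thr <- compute_thresholds(make_panel(m))
  expect_equal(thr["A", "lower"], mean(m[, "A"]) - 3 * sd(m[, "A"]))
  expect_equal(thr["A", "upper"], mean(m[, "A"]) + 2 * sd(m[, "A"]))
  expect_equal(thr["B", "lower"], mean(m[, "B"]) - 3 * sd(m[, "B"]))
  expect_true(all(thr$lower < thr$mean & thr$mean < thr$upper))
  expect_error(compute_thresholds(make_panel(cbind(A = rep(0, 10),
                                                   B = rep(0, 10)))),
               "degenerate")
})

test_that("null panels put ~Phi(-3) of probes below the lower threshold", {
  set.seed(7)
  n <- 60000
  x <- rnorm(n, 0, 0.15)
  thr <- compute_thresholds(make_panel(cbind(A = x)))
  p_down <- mean(x < thr["A", "lower"])
  p_up <- mean(x > thr["A", "upper"])
  se3 <- 3 * sqrt(pnorm(-3) * (1 - pnorm(-3)) / n)
  se2 <- 3 * sqrt(pnorm(-2) * (1 - pnorm(-2)) / n)
  expect_lt(abs(p_down - pnorm(-3)), se3 + 2e-4)
  expect_lt(abs(p_up - pnorm(-2)), se2 + 2e-4)
})

test_that("segmentation finds exact changepoints and respects min_len", {
  prm <- segmentation_params(seed = 1)
  x <- c(rep(0, 20), rep(-3, 20))
  segs <- svpanel:::segment_vector(x, prm)
  expect_equal(length(segs), 2L)
  expect_equal(segs[[1]], c(1L, 20L))
  expect_equal(segs[[2]], c(21L, 40L))

  # constant signal: one segment
  expect_equal(length(svpanel:::segment_vector(rep(0.3, 50), prm)), 1L)

  # two-probe dip flanked by zeros is isolated (min_len = 2 satisfied)
  x2 <- c(rep(0, 19), -3, -3, rep(0, 19))
  segs2 <- svpanel:::segment_vector(x2, prm)
  expect_true(any(vapply(segs2, function(p) {
    p[1] == 20L && p[2] == 21L
  }, logical(1))))

  # fewer probes than 2 * min_len: single segment
  expect_equal(length(svpanel:::segment_vector(c(0, -3), prm)), 1L)
})

test_that("segmentation is symmetric under sign flip and conserves means", {
  set.seed(3)
  x <- rnorm(800, 0, 0.15)
  x[301:330] <- x[301:330] - 2
  prm <- segmentation_params(seed = 4)
  set.seed(4)
  a <- svpanel:::segment_vector(x, prm)
  set.seed(4)
  b <- svpanel:::segment_vector(-x, prm)
  expect_identical(a, b)

  p <- make_panel(cbind(A = x))
  segs <- segment_probes(p, "A", prm)
  for (i in seq_len(nrow(segs))) {
    expect_equal(segs$mean[i],
                 mean(x[segs$first_probe[i]:segs$last_probe[i]]))
  }
  expect_true(all(segs$n_probes >= 2))
  # adjacent segments differ by at least min_diff
  if (nrow(segs) > 1) expect_true(all(abs(diff(segs$mean)) >= 0.1))
})

test_that("segment and gene calls use strict threshold inequalities", {
  thr <- fixed_thresholds(-0.3, 0.2, c("A"))
  segs <- data.frame(genotype = "A", chrom = "chr01", start = 0,
                     end = 1000, first_probe = 1, last_probe = 3,
                     n_probes = 3, mean = c(-0.5, 0.25, -0.3, 0.2, 0))
  out <- call_segment_cnv(segs, thr)
  expect_equal(out$direction, c("Down", "Up", "neutral", "neutral",
                                "neutral"))
})

test_that("gene scores fall back from probes to segments to neighbours", {
  probes <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                       chrom = "chr01",
                       start = c(100, 200, 5000, 6000),
                       end = c(160, 260, 5060, 6060),
                       stringsAsFactors = FALSE)
  ratios <- cbind(A = c(-2.9, -3.1, 0.2, 0.4))
  rownames(ratios) <- probes$probe_id
  panel <- structure(list(probes = probes, ratios = ratios,
                          normalized = TRUE), class = "sv_panel")
  genes <- data.frame(
    gene_id = c("gProbe", "gSeg", "gNear"),
    chrom = "chr01",
    start = c(90, 1000, 8000), end = c(300, 2000, 9000),
    length = c(210, 1000, 1000), stringsAsFactors = FALSE)
  rownames(genes) <- genes$gene_id
  segs <- data.frame(genotype = "A", chrom = "chr01", start = 900,
                     end = 2100, first_probe = 1, last_probe = 2,
                     n_probes = 2, mean = -2.0, direction = "Down",
                     stringsAsFactors = FALSE)
  sc <- score_genes_cgh(genes, panel, segs)
  expect_equal(sc$score["gProbe", "A"], -3.0)
  expect_equal(sc$source["gProbe", "A"], "probe-average")
  expect_equal(sc$score["gSeg", "A"], -2.0)
  expect_equal(sc$source["gSeg", "A"], "segment-average")
  expect_equal(sc$score["gNear", "A"], 0.3)  # mean of the two nearest
  expect_equal(sc$source["gNear", "A"], "nearest-two-probes")

  thr <- fixed_thresholds(-0.3, 0.2, "A")
  calls <- call_probe_cnv(sc, thr)
  expect_equal(unname(calls[, "A"]), c("Down", "Down", "Up"))

  # gene on a chromosome with neither probes nor segments errors by name
  genes2 <- rbind(genes, data.frame(gene_id = "gLost", chrom = "chr09",
                                    start = 0, end = 100, length = 100,
                                    row.names = "gLost"))
  expect_error(score_genes_cgh(genes2, panel, segs), "gLost")
})
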