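# Generator: annotation, planted truth and the two simulated platforms.

test_that("annotation places non-overlapping genes and a ~500 bp probe grid", {
  g <- generate_annotation(genome_config(seed = 3))
  expect_equal(nrow(g$genes), 200L)

  # Non-overlap within each chromosome (0-based half-open).
  for (ch in names(g$chrom_lengths)) {
    gg <- g$genes[g$genes$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
    expect_true(all(gg$start >= 0 & gg$end <= g$chrom_lengths[[ch]]))
    pp <- g$probes[g$probes$chrom == ch, ]
    expect_true(all(pp$start >= 0 & pp$end <= g$chrom_lengths[[ch]]))
    # ~2000 probes per 1 Mb chromosome at 500 bp spacing
    expect_gt(nrow(pp), 1800)
    expect_lt(nrow(pp), 2200)
    expect_equal(median(diff(pp$start)), 500, tolerance = 0.05)
  }
  expect_true(all(g$probes$end - g$probes$start >= 50 &
                    g$probes$end - g$probes$start <= 70))

  # Independent oracle: direct interval scan for probe overlap counts.
  ov <- vapply(seq_len(nrow(g$genes)), function(i) {
    sum(g$probes$chrom == g$genes$chrom[i] &
          g$probes$start < g$genes$end[i] &
          g$probes$end > g$genes$start[i])
  }, integer(1))
  expect_identical(sum(ov == 0L),
                   attr(g, "n_genes_without_probes"))
})

test_that("paralog pairing is symmetric, 1:1 and rounded down to even", {
  g <- generate_annotation(genome_config(n_genes = 100L,
                                         paralog_fraction = 0.60, seed = 2))
  paired <- g$genes[!is.na(g$genes$paralog), ]
  expect_equal(nrow(paired), 60L)  # 30 symmetric pairs
  # symmetry: partner-of-partner is self
  expect_identical(g$genes[paired$paralog, "paralog"], paired$gene_id)
  expect_false(any(paired$paralog == paired$gene_id))
})

test_that("annotation is deterministic and errors on infeasible sizing", {
  cfg <- tiny_genome_config(seed = 11)
  a <- generate_annotation(cfg)
  b <- generate_annotation(cfg)
  expect_identical(a$genes, b$genes)
  expect_identical(a$probes, b$probes)
  expect_error(
    generate_annotation(genome_config(chrom_length_bp = 1e4,
                                      n_genes = 100L)),
    "infeasible")
})

test_that("pfam catalog assigns the requested number of genes per domain", {
  g <- generate_annotation(tiny_genome_config())
  tab <- table(g$pfam$domain)
  expect_equal(as.integer(tab[["DOM1"]]), 6L)
  expect_equal(as.integer(tab[["DOM2"]]), 4L)
  expect_false(any(duplicated(paste(g$pfam$gene_id, g$pfam$domain))))
})

test_that("planted events obey their category copy patterns", {
  g <- generate_annotation(tiny_genome_config())
  gt <- panel_genotypes(41L)
  tr <- plant_events(g, n_events = 10L,
                     class_probs = c("DownCNV/PAV" = 1), genotypes = gt,
                     het_prob = 0, seed = 7)
  expect_equal(nrow(tr$events), 10L)
  expect_true(all(tr$copies[, gt$reference] == 1L))
  expect_true(all(apply(tr$copies[, gt$tests] == 0L, 1, any)))
  expect_true(all(tr$copies[, gt$tests] <= 1L))

  trm <- plant_events(g, n_events = 6L,
                      class_probs = c("Multi-Allelic UpCNV" = 1),
                      genotypes = gt, het_prob = 0, seed = 8)
  for (i in seq_len(nrow(trm$events))) {
    cps <- trm$copies[i, gt$tests]
    expect_setequal(unique(cps[cps > 1]), c(3L, 10L))
    expect_equal(trm$copies[i, gt$reference], 1L)
  }
})

test_that("event planting is deterministic and round-trips losslessly", {
  g <- generate_annotation(tiny_genome_config())
  a <- plant_events(g, n_events = 8L, seed = 9)
  b <- plant_events(g, n_events = 8L, seed = 9)
  expect_identical(a$events, b$events)
  expect_identical(a$copies, b$copies)
  expect_identical(a$gene_events, b$gene_events)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(a, path)
  back <- read_truth(path, genotypes = a$genotypes)
  expect_identical(back$events$event_id, a$events$event_id)
  expect_equal(back$events$start, a$events$start)
  expect_identical(unname(back$copies), unname(a$copies))
  expect_identical(unname(back$het), unname(a$het))
  expect_identical(sort(names(back$gene_events)), sort(names(a$gene_events)))
})

test_that("events sum their class proportions and validate inputs", {
  g <- generate_annotation(tiny_genome_config())
  expect_error(plant_events(g, class_probs = c("DownCNV/PAV" = 0.5)),
               "sum to 1")
  expect_error(plant_events(g, class_probs = c(Bogus = 1)), "unknown")
})

test_that("CGH signal model hits its closed-form values", {
  g <- generate_annotation(tiny_genome_config())
  gt <- panel_genotypes(5L)
  # No events, no noise: exactly zero everywhere.
  tr0 <- plant_events(g, n_events = 0L, genotypes = gt, seed = 1)
  p0 <- simulate_cgh(tr0, g, cgh_noise_sd = 0, seed = 1)
  expect_true(all(p0$ratios == 0))

  # Planted duplication (2/1) -> 1.0; deletion (0/1) with floor 1/16 -> -4.
  tr <- plant_events(g, n_events = 4L,
                     class_probs = c("DownCNV/PAV" = 0.5, "UpCNV" = 0.5),
                     genotypes = gt, het_prob = 0, seed = 3)
  p <- simulate_cgh(tr, g, cgh_noise_sd = 0, deletion_floor = 1 / 16,
                    seed = 1)
  for (id in rownames(tr$events)) {
    ev <- tr$events[id, ]
    pin <- which(p$probes$chrom == ev$chrom & p$probes$start < ev$end &
                   p$probes$end > ev$start)
    if (!length(pin)) next
    for (gtest in gt$tests) {
      cp <- tr$copies[id, gtest]
      want <- log2(max(cp, 1 / 16) / 1)
      expect_true(all(abs(p$ratios[pin, gtest] - want) < 1e-12))
    }
  }
})

test_that("read counts follow depth x length x copy / read-length", {
  g <- generate_annotation(tiny_genome_config())
  gt <- panel_genotypes(5L)
  tr <- plant_events(g, n_events = 3L, class_probs = c("DownCNV/PAV" = 1),
                     genotypes = gt, het_prob = 0, seed = 2)
  cov <- coverage_config(noise = "none", seed = 1)
  cnt <- simulate_counts(tr, g, cov)
  depths <- attr(cnt, "depths")
  cp <- svpanel:::truth_gene_copies(tr, g)$bulk
  lambda <- sweep(cp, 1, g$genes$length, `*`)
  lambda <- sweep(lambda, 2, depths[colnames(cp)] / 150, `*`)
  expect_equal(matrix(cnt, nrow(cnt)), unname(round(lambda)))
  # deleted genes have hard zero counts in carriers
  ev <- rownames(tr$events)[1]
  carriers <- names(which(tr$copies[ev, gt$tests] == 0L))
  gid <- names(tr$gene_events)[tr$gene_events == ev][1]
  expect_true(all(cnt[gid, carriers] == 0L))

  # Poisson mean: depth 8, len 1500, reads 150, copy 1 -> 80 expected.
  set.seed(42)
  draws <- rpois(400, 8 * 1500 / 150)
  expect_equal(mean(draws), 80, tolerance = 0.05)
})

test_that("expected RPKM is invariant to sequencing depth", {
  g <- generate_annotation(tiny_genome_config())
  gt <- panel_genotypes(3L)
  tr <- plant_events(g, n_events = 0L, genotypes = gt, seed = 1)
  lens <- stats::setNames(g$genes$length, g$genes$gene_id)
  rp <- function(depth, seed) {
    cov <- coverage_config(hub_depth = depth, ref_depth = depth,
                           minor_depth_range = c(depth, depth), seed = seed)
    cnt <- simulate_counts(tr, g, cov)
    colMeans(compute_rpkm(cnt, lens))
  }
  m1 <- rowMeans(vapply(1:20, function(s) rp(4, s), numeric(4)))
  m2 <- rowMeans(vapply(1:20, function(s) rp(8, s + 100), numeric(4)))
  expect_equal(unname(m1), unname(m2), tolerance = 0.02)
})

test_that("heterogeneous carriers split the two platform channels", {
  g <- generate_annotation(tiny_genome_config())
  gt <- panel_genotypes(4L)
  tr <- plant_events(g, n_events = 2L, class_probs = c("DownCNV/PAV" = 1),
                     genotypes = gt, het_prob = 1, seed = 3)
  expect_true(any(tr$het))
  cp <- svpanel:::truth_gene_copies(tr, g)
  ev <- rownames(tr$events)[1]
  gid <- names(tr$gene_events)[tr$gene_events == ev][1]
  hets <- colnames(tr$het)[tr$het[ev, ]]
  carr <- names(which(tr$copies[ev, gt$tests] == 0L))
  hc <- intersect(hets, carr)
  expect_true(length(hc) > 0)
  # single plant sees the full deletion, the bulk a 50:50 mixture
  expect_equal(unname(cp$single_plant[gid, hc]), rep(0, length(hc)))
  expect_equal(unname(cp$bulk[gid, hc]), rep(0.5, length(hc)))
})
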