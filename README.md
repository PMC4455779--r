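# svpanel

Genic structural-variant (CNV/PAV) discovery across a panel of inbred
lines compared with one reference genotype, from two complementary
platforms: array-CGH log2 ratios and resequencing read depth.

The package is aimed at plant and crop genomicists who screen diversity
panels (e.g. the 41 parents of a nested association mapping population
against the reference cultivar) for deletions, presence–absence variants
and tandem copy-number gains, and who want the whole discovery chain —
calling, cross-platform validation, classification, population frequency
spectra against a neutral null, and gene-family enrichment — as tested,
reproducible code with a synthetic-data generator that plants known truth.

## What it computes

Per genotype *g*, probe log2 ratios are thresholded at

    lower_g = mean_g − 3·SD_g        upper_g = mean_g + 2·SD_g

both for recursively segmented probe runs ("CGH Segment CNV"; parameters:
minimum mean difference 0.1, minimum 2 probes, acceptance percentile 0.99
over 10 permutations) and for per-gene probe averages ("CGH Probe CNV").
Read counts become RPKM = count·10⁹ / (gene length · total mapped reads),
and log2(RPKM_test / RPKM_ref) is thresholded with the same 3-SD/2-SD
rule; zero-read genes run in dedicated streams. Genes supported by both
platforms are cross-validated across the 41 genotypes in the
(CGH, sequence) copy plane, given integer copy calls
`round(ref × 2^mean(scores))`, and placed into one of six categories
(DownCNV/PAV, UpPAV, UpPAV+UpCNV, UpCNV+DownCNV, UpCNV, Multi-Allelic
UpCNV). Adjacent calls collapse into segments whose carrier counts
k ∈ 1..41 form reference-ascertained site frequency spectra, compared
with a built-in neutral coalescent (infinite sites, recombination via the
ancestral recombination graph, reference-based ascertainment dropping
sites where the reference carries the derived state, so the expected
spectrum is ∝ (n−k)/(n·k)). Domain enrichment is hypergeometric with
min-p resampling family-wise correction; paralog retention is a 2×2
Fisher contrast.

## Worked example

Simulate a panel (200 genes, 41 test genotypes + reference, probe noise
SD 0.15, depths 2–31×, 25 planted events) and run everything:

```r
library(svpanel)
cfg <- sv_config(events = list(n_events = 25L,
                               carrier_spectrum = "onebyk",
                               het_prob = 0.05),
                 seed = 7)
run <- run_sv_pipeline(cfg)
run
summary(run)
```

```
svpanel pipeline run (seed 7)
  candidates: 29; cross-validated SV genes: 28
  Down segments: 19; Up segments: 7
SV category counts (cross-validated genes)
                DownCNV/PAV UpPAV UpPAV+UpCNV UpCNV+DownCNV UpCNV
with paralog             14     0           0             0     3
without paralog           7     0           0             0     3
total                    21     0           0             0     6
                Multi-Allelic UpCNV
with paralog                      0
without paralog                   1
total                             1
-- Up spectrum vs neutral --
Spectrum comparison (empirical vs simulated neutral)
  singleton excess: +0.5143 (proportion units)
  chi-square distance: 13.21, resampling p = 0.0031
```

The category table is the survey's standard layout: cross-validated gene
counts per category, split by retained-paralog status. The spectrum
comparison reports how far each empirical carrier-frequency spectrum sits
from the neutral expectation; a positive singleton excess for the Up
spectrum (here +0.51 in proportion units) is the signature of rare,
recent duplications. `write_sv_outputs(run, "out/")` emits every
intermediate table (probe panel, thresholds, segment BED, gene scores,
classification, scatter points, spectra, GFF3 gene models).

Published-survey arithmetic is available directly:

```r
paralog_contrast_counts(244, 32464, 1284, 21369)
#> Retained-paralog SV contrast
#>   with paralog:    244 / 32464 (0.75%)
#>   without paralog: 1284 / 21369 (6.01%)
#>   fold difference: 7.99 (Fisher p = 1.35e-287)
estimate_ne(8.3e-4)   # theta_W = 4 Ne mu with mu = 7e-9  ->  29642
```

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/svpanel-run.R --seed 7 --out-dir svpanel-out
```

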