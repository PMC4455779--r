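---
title: "Methods: dual-platform genic structural-variant discovery"
author: "svpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-platform genic structural-variant discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpanel)
```

## The problem

A panel of inbred crop lines (here modelled after a soybean NAM parent
panel: 41 test lines, one deeply-studied hub line, one reference cultivar)
is screened for genic structural variation — deletions, presence–absence
variants and tandem copy-number gains — with two complementary platforms:

* **array CGH**: a tiling two-dye microarray; each probe reports the log2
  intensity ratio of test over reference DNA;
* **whole-genome resequencing**: uniquely-mapped read counts per gene
  model, converted to RPKM (reads per kilobase per million mapped reads)
  and compared against the reference genotype as a log2 ratio.

Neither platform is trustworthy alone at low coverage: the array suffers
cross-hybridization and segmentation artifacts; read depth at 2–8×
coverage is noisy and is distorted for genes missing from the reference
assembly. The pipeline therefore calls each platform independently,
cross-validates per gene across all 41 test genotypes, assigns integer
copy numbers and one of six structural-variant categories, collapses
adjacent calls into segments, and compares the segment carrier-frequency
spectrum against a neutral coalescent expectation.

## Calling model

**CGH.** Ratios are median-centred per genotype (a documented stand-in for
vendor spatial correction and qspline normalization, which are not
re-implemented). For each genotype the calling thresholds are `mean − 3·SD`
(lower) and `mean + 2·SD` (upper) of that genotype's probe ratio
distribution — the asymmetry reflects the physics of two-dye arrays, where
deletions produce a stronger, more reliable signal than duplications.
Thresholds are strict inequalities; equality is neutral. The same
thresholds are reused for segment means and gene-level probe averages;
whether the original procedure computed them on a different unit is not
decidable from the published description, so one definition is used
consistently.

**Segmentation.** Probes are segmented per genotype and chromosome by
recursive changepoint splitting with the published parameter set
(minimum mean difference 0.1, minimum segment length 2 probes, acceptance
percentile 0.99, 10 permutations). Each recursion step scans for the
candidate interval (length between `min_len` and `max_len`, flanks empty
or at least `min_len`) that maximizes the absolute difference between the
interval mean and the mean of its complement, and accepts it only when the
difference exceeds both `min_diff` and the acceptance percentile of the
within-window permutation null; accepted intervals split the window into
up to three children. A single-cut binary split was tried first and
rejected: a short dip in the middle of a long window never dominates its
own permutation null under a single-cut statistic, so two-probe events —
which the parameter set explicitly allows — would be undetectable. The
bounded interval scan is the smallest generalization that fixes this, and
it degenerates to the single cut at window edges. After splitting,
neighbouring segments whose means differ by less than `min_diff` are
merged so the output satisfies the parameter's contract. `max_len`
defaults to 100 probes (~50 kb at the default spacing); longer events are
still recovered because flanking remainders are recursed and re-merged.

**Gene-level CGH score.** Each gene's score per genotype is the mean of
probes intersecting it (any bp overlap, half-open intervals); probe-less
genes inherit the covering segment's mean, and failing that the mean of
the two nearest probes. The source of each score is recorded. This probe
pathway exists because segmentation deliberately favours large events and
merges gene-sized ones away — the motivation for calling small CNVs at
the gene level in the first place.

**Sequence calls.** Genes with zero reads in every genotype are removed.
Three streams mirror the all-by-one design: genes with reference reads are
called from log2 RPKM ratios with the same 3-SD/2-SD rule (thresholds from
each genotype's finite ratios); genes with a zero-read reference and more
than one read in some test line cannot form a ratio and are handled by
absolute RPKM; genes with a zero-read reference and no informative test
count are logged and kept only as flags. A count of one read in every test
line is deliberately ambiguous in the rule "more than one read"; such
genes go to the flag stream. Zero test counts for reference-present genes
are flagged as potential deletions and enter the Down calls (a `-Inf`
ratio is below every finite threshold).

**Cross-validation and classification.** Candidate genes (within a
significant CGH segment in any genotype, or on both the gene-level CGH and
sequence lists) get per-genotype copy estimates:
`ref_copies × 2^mean(cgh_score, seq_score)` rounded half-away-from-zero,
floored at zero, with zero assigned outright when the gene has zero reads
and a below-threshold CGH score. For reference-absent genes both axes are
converted to absolute copies first (CGH via the deletion floor, sequence
via the genotype's single-copy RPKM, estimated as the median RPKM of
normal-stream genes). Genotypes whose platforms disagree by more than 2
log2 units receive no integer call and are flagged. Cross-validation uses
one-dimensional gap clustering per axis (a new cluster opens at gaps above
0.75 copy units) intersected across axes; a gene is cross-validated when
two joint clusters separate by at least the gap on *both* axes, or when
every genotype exceeds the thresholds on both platforms. The published
procedure validated clusters visually; 0.75 copies is the smallest gap
that still separates one- from two-copy states given the platforms'
noise, and being a fixed rule it is auditable. The six categories follow
the decision order: reference copy (0 vs 1), presence of zero-copy test
lines, then the number of distinct (integer-rounded) multi-copy groups.

**Heterogeneity.** The resequencing DNA is a bulk of ~40 seeds while the
array samples one plant, so within-line heterogeneity makes the platforms
disagree honestly. The generator models this by drawing the count channel
from a 50:50 copy mixture for flagged carriers; the caller flags genotypes
where one platform is beyond threshold while the other sits within 1 SD
of its mean (for reference-absent genes, the analogous presence/absence
logic on the copy scale).

## Segments and the reference-based SFS

Adjacent cross-validated genes of compatible classes (Down: DownCNV/PAV
only; Up: UpCNV and Multi-Allelic UpCNV) are collapsed into segments when
no retained gene of another status intervenes and some genotype's
significant CGH segment covers both genes of a junction — gene-order
adjacency, not bp distance, defines "adjacent", because segments-as-guide
is the only notion of adjacency the design supports. A genotype carries a
segment when at least one member gene exceeds both platform thresholds in
that genotype (the same gene on both platforms — the stricter reading).
Carrier counts k ∈ 1..41 define the reference-based site frequency
spectrum (rSFS).

## Neutral model

The null is a standard neutral coalescent with recombination at
independent unit loci, each representing one CGH segment (~14 kb).
Parameters: μ = 7×10⁻⁹ per bp per generation; effective population size
from `θ_W = 4 Ne μ`; per-locus population recombination rate 21.54
(taken as a constant — the genetic-map rate that produced it is cited,
not printed, in the source material); sample size 42 haploid chromosomes
with the reference as row 1. θ per locus comes from Watterson's estimator
applied to the observed number of SV segments (`θ = S / a_n`,
`a_n = Σ_{i=1}^{n−1} 1/i`), uncorrected for ascertainment, spread evenly
over the simulated loci. Reference-based ascertainment discards every
site at which the reference chromosome carries the derived (absent)
state; the ascertained spectrum has expectation proportional to
`(n−k)/(n·k)`, which the implementation reproduces (the unascertained
spectrum matches θ/k). Recombination uses the ancestral-recombination-
graph construction with interval-carrying lineages; mutation placement is
Poisson on branch "area", so E[S] is independent of ρ — a property the
tests check. Empirical and simulated spectra are compared as proportions,
with the singleton excess and a chi-square distance whose p-value comes
from 10,000 multinomial resamples of the simulated spectrum.

## Enrichment and paralog retention

Domain enrichment per category is an upper-tail hypergeometric test
(`exp = K·n/N`), with family-wise correction by min-p resampling: 10,000
random gene lists of the same size, recording the minimum raw p across
domains; a domain's adjusted p is the fraction of simulations whose
minimum is at or below its raw p. This is the documented behaviour of the
correction tool named in the source material, re-specified here because
the tool's internals are not published. Significance stars use adjusted
p < 0.01 (*) and < 0.001 (**). The leucine-rich-repeat clan aggregation
is an input mapping in the domain catalog, not a computation. The
retained-paralog contrast is a 2×2 Fisher exact test with the fold
difference reported as `rate_without / rate_with`.

## Synthetic data: what it emulates, what it does not

The generator produces a miniature genome (default 2 × 1 Mb, 200
non-overlapping gene models), a tiling probe panel (50–70 bp probes,
median spacing 500 bp with log-normal jitter), symmetric 1:1 syntenic
paralog pairing for 60% of genes, a domain catalog, and planted events:

* category mix defaulting to the proportions typical of such surveys
  (72% deletion/PAV, gains in the minority);
* event sizes log-normal with median ~2.8 kb and a heavy right tail
  (`sdlog = 1.2`), matching the observed skew between median and mean
  segment sizes at a scale the miniature genome can hold;
* carrier counts drawn uniformly or ∝ 1/k (neutral-like);
* whole genes as event members, so the probe and count channels see the
  same dosage — partial-gene events would make the two simulated channels
  contradict each other, which is a breakpoint-modelling question outside
  this package's scope;
* copy 0 represented on the array as a 1/16 residual cross-hybridization
  floor (log2 = −4): the absent-state intensity is not published, and a
  finite floor is what real arrays show;
* per-probe Gaussian noise (SD 0.15) and Poisson read counts at
  hub 31×, reference 13×, minor lines uniform 2–8×;
* intra-line heterogeneity at 5% of carriers (bulk channel samples the
  mixture, array the single plant).

Passing tests on these panels demonstrate the pipeline's logic —
threshold calibration, stream handling, classification, spectra — under
the noise structure it assumes. They do not demonstrate robustness to
alignment artifacts, GC and mappability bias, probe cross-hybridization
between paralogs, partial-gene breakpoints, or segmental duplications in
the reference — all absent from the generator by design.

One interaction deserves note: RPKM couples every gene to every other
gene through the per-genotype total. In very small simulated genomes with
many planted events the totals shift enough to bias all ratios of a
genotype; the test fixtures therefore keep planted events below ~20% of
genes, which is also far denser than any realistic survey.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 output is 1-based.
* Copy rounding is half-away-from-zero (2.5 → 3), so allele classes
  cannot collapse downward by banker's rounding.
* Threshold comparisons are strict; boundary equality is neutral.
* `compute_thresholds()` refuses zero-variance panels; noise-free runs
  pass fixed thresholds through the pipeline config instead (that is the
  supported way to analyze degenerate panels).
* Windows shorter than `2 × min_len` probes return a single segment.
* All randomness derives from one master seed via fixed sub-streams;
  identical config + seed gives identical output tables.
* Ne is reported truncated (not rounded), matching how the published
  value was derived from its inputs.

## Problem sizes

Default test-scale runs use 200-gene genomes with 42 genotypes (~4,000
probes), 25 planted events, 10⁴ coalescent loci at n = 42 for spectrum
calibration and 500 ARG loci for the in-pipeline neutral comparison.
These sizes were chosen so that every spectrum class keeps an expected
count well above one and recovery proportions have Monte-Carlo error of a
few percent.

## Known limitations

* The segmentation stand-in shares parameters, not code, with the
  proprietary vendor algorithm; boundary placement may differ.
* Zero-in-reference copy estimation assumes the genotype's median RPKM is
  a faithful single-copy unit; strong aneuploidy would violate this.
* The neutral comparison treats segments as independent loci; linked
  segments shared by descent inflate apparent spectrum counts.
* "Clearly split" cross-validation is necessarily a fixed numeric rule
  here (0.75-copy gaps); borderline two-copy singletons at low coverage
  are the main casualties, and they are reported as candidates without a
  category rather than silently dropped.
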