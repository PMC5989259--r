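---
title: "Methods: a pool-seq population-differentiation scan with a known-truth simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a pool-seq population-differentiation scan with a known-truth simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Selective-breeding and adaptation studies in aquaculture species often
contrast phenotypically selected populations by pooled whole-genome
resequencing (pool-seq): one sequencing library per population, allele
frequencies estimated from read counts rather than genotypes. The analysis
this package implements contrasts two salinity-selected oyster pools with an
unselected control and asks which genes carry unusually differentiated
variation. Evidence comes from three streams:

1. an **allele-frequency-difference (AFD) scan** selecting SNPs whose
   between-pool frequency difference strictly exceeds 0.6,
2. a **windowed F_ST scan** ranking non-overlapping 1-kb windows and
   selecting the highest 1%, with genes extracted from the selected windows
   plus 5 kb of flank on each side, and
3. a **differential-expression (DE) gene list** from an accompanying
   expression experiment, supplied as an input file.

Genes supported at the DNA level (AFD or F_ST) *and* the expression level
form the candidate set; candidates are tested for annotation-term
enrichment. Larval phenotype assays (production, survival, growth,
adhesion rates) are compared across groups by one-way ANOVA.

Because the original resequencing data are not publicly deposited, the
package validates the whole scan on synthetic pool-seq studies with known
truth instead of attempting to reproduce the published counts.

## Allele frequencies and filtering

The pooled estimate of a site's alternate-allele frequency is
`alt / (alt + ref)`; for individually genotyped validation panels it is the
allele dose `(2*hom_alt + het) / (2*n)`.

Sites are filtered before any scan. A site passes when, in **every** pool:

* depth >= 2 reads (>= 3 when the pool shows reads for both alleles — the
  only observable analogue of "heterozygous" in pooled counts);
* depth <= 3x the pool's mean depth, with the mean computed per pool over
  the pre-filter sites (the conservative reading of "the average depth");
* base quality >= 20 (sites with unknown quality pass);
* the position lies outside the simple-sequence-repeat (SSR) mask.

Removals are attributed to the *first* failing rule in the fixed order
depth, het-depth, max-depth, quality, SSR, so filter reports are
deterministic and always conserve the input count. Whether such filters
should be applied per pool or jointly is not fixed by convention; per pool
is the stricter choice and is what is implemented.

## The F_ST estimator

No particular estimator is canonical for pooled data; the package uses a
Hudson-type estimator with finite-sample correction, which is robust for
frequency-based data and does not require genotypes:

* numerator: `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`
* denominator: `p1(1-p2) + p2(1-p1)`

with the effective sample size per pool `n = min(2 * pool_size, depth)` —
pooled reads cannot carry more information than the chromosomes in the
pool. A window's F_ST is the **ratio of summed numerators to summed
denominators** over its SNPs (ratio of averages), which is much less noisy
than averaging per-site ratios. Negative site numerators are retained in
the sums so the ranking stays unbiased; written tables carry an additional
display column floored at zero. A Nei/Wright-style estimator
(`(p1-p2)^2/4` over `pbar*qbar`) is available behind the `estimator` flag
for sensitivity checks, never as the default.

Windows are non-overlapping tiles with boundaries at multiples of the
window size from the scaffold start (the simpler reading of "all 1000-bp
windows"; nothing in the procedure requires sliding windows). Windows
without SNPs are never ranked; the top selection takes
`ceiling(fraction * n_ranked)` windows, with ties at the cutoff broken by
(scaffold, start) order so reruns are identical. The 1% cut is applied per
pairwise comparison, not genome-wide across comparisons.

## Thresholds and conventions

* The AFD rule is **strictly** "above 0.6". The comparison is guarded by a
  1e-9 epsilon so a count ratio that equals the threshold exactly in
  rational arithmetic (e.g. |8/10 - 2/10|) never passes through
  floating-point noise.
* AFD-based gene assignment uses the gene span with no flank by default
  (`flank_bp` and a nearest-gene mode are available; the 5-kb flank
  belongs to the *window*-based extraction, where the procedure specifies
  it).
* Intervals are held internally as `GRanges` (1-based, closed), the native
  convention of the R/Bioconductor interval stack; BED's 0-based half-open
  and GFF3's 1-based inclusive coordinates are converted exactly once, at
  the file boundary, by rtracklayer. Half-open exclusivity at window
  boundaries is preserved: a gene starting on the first base after an
  extended window does not overlap it.
* SNP genomic areas are `CDS` (in any exon), `Intron` (in a gene span but
  no exon) and `Intergenic`, with CDS taking precedence when overlapping
  genes disagree; strand is ignored throughout, and UTR resolution is out
  of scope.
* Enrichment uses the one-sided hypergeometric tail `P(X >= k)` with the
  **whole annotated gene set as the background** (configurable), BH
  adjustment across terms, and a reporting threshold of adjusted p < 0.05.
  Term tables are plain two-column inputs; no live GO/COG/KEGG lookups.

## The synthetic study generator

`simulate_poolseq_study()` emulates the study design end to end: three
pools of 46 diploids, mean depth 35x (zero-truncated Poisson per site and
pool), a multi-scaffold toy genome (default 10 x 100 kb = 1,000 one-kb
windows, 5,000 SNPs), an SSR mask, multi-exon gene models, a term
annotation, a DE list and larval phenotype tables, plus truth tables for
every planted signal.

**Background loci** follow the Balding–Nichols model: an ancestral
frequency uniform on (0.05, 0.95) and, per population, an independent
Beta draw with divergence `F` (default 0.05). This is the standard neutral
null for F_ST simulation, and the estimator is required (and tested) to
recover `F` within 0.02 at the study's depth and pool size.

**Planted outlier loci** model directional selection, not extra drift. A
symmetric Balding–Nichols draw at a higher `F` cannot represent what the
scan targets: it leaves the ancestral frequency mid-range half the time,
so even extreme divergence parameters rarely produce the near-fixed
contrasts (AFD 0.6–0.9) that this kind of scan reports. Instead each
planted locus is a sweep of a low-frequency standing variant: the
unselected (ancestral/control) frequency is uniform on (0.02, 0.12)
(mirrored to the other allele with probability 1/2), and the treatment
pool is displaced by at least `outlier_divergence` — the parameter is a
**floor on the true planted displacement**, with the realised displacement
drawn on `(outlier_divergence, 1)` tilted toward fixation (Beta(2, 1)).
Only large standing-variant sweeps produce the high-AFD outliers the scan
is designed to find, which is exactly what a positive control should
plant. The other treatment pool and the control stay at background
divergence.

Planted loci are **clustered into linked regions** (default five loci per
region, each region inside a single 1-kb tile, always hosted by a gene):
a sweep elevates divergence across its linked footprint, not at one
isolated SNP, and clustering is what makes window-level recovery a
meaningful test. The SSR mask is laid down clear of the planted regions —
a positive control erased by its own mask would test nothing.

**Pooled read sampling is two-stage**: the pool's sample frequency is
first drawn from `2 * pool_size` chromosome draws, then read counts
binomially at that frequency. Pooling finitely many individuals leaves a
variance floor of `pq / (2 * pool_size)` no matter how deep the
sequencing; consequently per-locus convergence of observed to true
frequencies is only tested in the joint limit of deep sequencing *and*
large pools, while at study scale the estimates are tested for
unbiasedness.

Determinism: every generator output draws from a named RNG substream
derived from the master seed by fixed offsets, so identical parameters
give byte-identical files and any single output is reproducible in
isolation.

What the generator does **not** emulate: read-level errors and mapping
artefacts, indels, linkage/coalescent structure beyond the planted
clusters, library-size or GC biases, and any real oyster genome sequence.
Passing the recovery tests therefore shows the scan's logic and
calibration are sound under its stated sampling model — not that the
published gene lists would be reproduced on real data.

## Phenotype statistics

Rates are production = D-larvae/eggs, survival = survivors/starting
D-larvae, adhesion = adherent/eye-spot larvae, and growth = relative mean
shell-height gain `(after - before)/before` (the relative-change form is a
documented choice; an absolute-gain mode exists). Groups are compared by
classical one-way ANOVA with `*`/`**` stars at 0.05/0.01; the
degenerate case of zero within-group variance is an explicit error rather
than an infinite F. Post-hoc pairwise comparisons use Welch t-tests with
BH adjustment — pairwise annotations in this kind of figure imply post-hoc
tests even when only the omnibus ANOVA is named. qPCR fold changes use
the standard `2^-ddCt`. The published "upregulated by 0.23/9.91" values
are not reproduced: their exact definition is not stated, and no raw Ct
data are available.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
studies: calibration uses 10,000 loci; recovery uses the default study
(1,000 windows, 5,000 SNPs, 50 planted loci in 10 regions, 200 genes);
oracle-equivalence checks use instances of at most 20 sites, backgrounds
of at most 200 genes and ANOVA tables of at most 30 observations, where
brute-force enumeration is exact. These sizes were chosen so every claim
is checked by an independent oracle or a known truth table in seconds.

## Known limitations

* The AFD scan has no significance machinery (by design — the procedure
  is a plain threshold); CMH/Fisher-style tests are out of scope.
* F_ST outlier status is a ranking, not a test against a coalescent null.
* The effective-sample-size cap `min(2N, depth)` slightly under-corrects
  the two-stage sampling variance, biasing window F_ST upward by about
  0.005–0.01 at study depth; this is visible, documented, and well within
  the calibration tolerance.
* GO-graph propagation, KEGG topology and COG hierarchies are not
  implemented; terms are opaque labels.
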