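---
title: "Relating gene-body DNA methylation to intragenic histone marks on tiling arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating gene-body DNA methylation to intragenic histone marks on tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genebodymarks)
```

## The analysis problem

Affinity enrichment of methylated DNA (MIRA) and of unmethylated DNA
(UMC), hybridised against input on a tiling array, yields one log2
enrichment ratio per probe; ChIP-on-chip gives comparable tracks for
histone marks (H3K36me3, H3K9me3, H3K27me3, H3 acetylation, H4K20me3).
On a gene-dense chromosome these signals organise genes into distinct
epigenetic classes: actively transcribed genes with CpG-rich,
methylated bodies carrying H3K36me3; zinc-finger (ZNF) genes whose
CpG-poor bodies carry H3K9me3 *and* H3K36me3 simultaneously;
Polycomb-repressed genes under H3K27me3 with partially methylated
bodies; and genes with no body marks at all. `genebodymarks`
implements the complete probe-to-biology pipeline: region definitions,
coverage-based mark classification, co-occupancy statistics, composite
(metagene) profiles, exon-level summaries, and wild-type versus
DNMT-knockout differential analysis — together with a deterministic
synthetic-data generator that plants this class structure so every
stage can be validated end to end.

## Regions, coverage, and classification

All coordinates are 0-based, half-open (BED convention); refFlat input
is already in this convention and BED12 blocks are resolved on read.
For each transcript:

* **gene body** — the full transcribed span, TSS to transcript end;
* **promoter** — TSS −500/+500 bp in transcriptional orientation
  (both extents configurable; e.g. −1000/+500 for promoter-correlation
  variants);
* **flanks** — 5 kb immediately 5′ of the TSS and 3′ of the transcript
  end, clipped at chromosome position 0.

A probe belongs to a region when its midpoint, `floor((start+end)/2)`,
falls inside the half-open interval. The midpoint rule avoids
double-counting probes that span bin or region boundaries and matches
common tiling-array practice; an any-overlap mode is available via
`analysis_params(probe_assign = "any_overlap")`. Region summaries are
length-unweighted probe means (NimbleGen probes are near-uniform in
length), and a region with fewer than `min_probes` probes is *missing*,
never zero; genes missing a mark are excluded from that mark's
classification denominator.

A probe is **positive** when its log2 ratio is strictly greater than
`theta_pos = 1`; a value of exactly 1 is not positive. A gene is
**marked** when the positive fraction of its gene-body probes is at
least `theta_cov = 0.20` (inclusive). Coverage is defined as a
fraction of *probes* rather than of gene-body length; on a uniform
probe grid the two coincide. CpG density is the count of CpG
dinucleotides divided by region length, scaled to counts per kilobase;
CpG is self-complementary, so density is strand-independent.

## Co-occupancy statistics

Marked-gene vectors for two marks are cross-tabulated over their
shared universe (genes excluded for either mark are dropped from
both). The 2×2 table is tested with the Pearson chi-square statistic
without continuity correction; when any expected cell falls below 5
the package logs a recommendation to use the Fisher exact test, which
is also provided. The Fisher two-tailed p-value follows the
probability-mass rule — the sum of hypergeometric probabilities of all
tables with the observed margins that are no more probable than the
observed table (relative tolerance 1e−7, the convention of
`stats::fisher.test`); other two-sided conventions can differ in the
third decimal. Pearson correlations between per-gene signal summaries
use a two-sided t-test with n−2 degrees of freedom and, by default,
admit only genes with at least 5 probes in the summarised region.
Group-level signal comparisons use all pairwise two-sided
Mann–Whitney U tests with Bonferroni correction over the number of
pairs; the multiple-comparison procedure is a package decision, since
several reasonable choices exist.

## Binned profiles and composites

Each gene contributes a 40-bin vector: 10 bins over the 5 kb upstream
flank, 20 equal-sized bins over the gene body, 10 bins over the 5 kb
downstream flank, ordered 5′→3′. Bin values are unweighted means of
the probes (by midpoint) in each bin; empty bins are missing, not
zero.

When the body length is not divisible by 20, the remainder bases are
distributed one per bin. The package lays bins out **in genomic
space**, remainder to the leftmost bins, and then reverses the whole
vector for minus-strand genes. The alternative — distributing the
remainder from the transcriptional 5′ end — would give plus- and
minus-strand genes different genomic partitions, so flipping a gene's
annotated strand could move probes across bin boundaries. With the
genomic layout, reversing a gene's strand reverses its profile vector
*exactly*, a property the test suite asserts probe-for-probe. Flank
windows (5000/10) divide evenly, so their layout is identical under
either convention.

Composite profiles average each bin over the genes with a defined
value there, excluding missing bins from numerator and denominator
alike, and report per-bin contributing counts and standard errors —
so a composite over any partition of a group merges back (weighted by
per-bin n) to the composite of the whole group.

Heatmap matrices concatenate per-mark bin vectors and order genes by
agglomerative hierarchical clustering (average linkage, Euclidean
distance), with missing bins imputed by column means for the distance
computation only; displayed values are the original bins. Rows are
pre-sorted by gene id so leaf order is deterministic under input
permutation. Average linkage was chosen for determinism and stability;
the linkage is configurable through the returned `hclust` object.
Display scaling centres each mark at its chromosome-wide mean probe
signal and saturates at ±2 log2 units; it never feeds statistics.

## Exon-level and differential analyses

Exon expression strata take the top and bottom `exon_quantile = 15%`
of the log2 intensity distribution by order statistics: with
k = ⌈q·n⌉, "low" is intensity ≤ the k-th smallest and "high" ≥ the
k-th largest, ties included on the extreme side; if the two thresholds
collide (e.g. all intensities equal) the distribution is degenerate
and no strata are assigned. First/last exons and introns are
transcriptional (the first exon of a minus-strand gene is the
rightmost); introns are the gaps between consecutive exons, so exons
and introns tile the transcript exactly. Coding exons are exons
intersected with the CDS; genes need at least two CDS-overlapping
exons to contribute first/last coding-exon rows.

Differential expression between two conditions is threshold-only:
Δ = log2(b) − log2(a), "up" when Δ ≥ 0.5 and "down" when Δ ≤ −0.5,
both inclusive. The exon arrays this emulates carry no usable
replicate structure, so no variance moderation is attempted — the
classification mirrors the simple fold-change rule, and significance
testing of expression changes is deliberately out of scope.

## The synthetic generator

`synthetic_config()` plants four gene classes (defaults: 55%
methylated-active, 20% ZNF-like, 15% Polycomb, 10% inert) on a single
chromosome: genes of 2–10 kb with 2–12 exons placed left-to-right with
1–3 kb gaps, random strands, and a 50 bp probe every 100 bp. Class
amplitudes are target probe log2 ratios — 2.0 for planted body marks
against a 0 baseline with Gaussian noise (sd 0.5), so planted marks
sit ~4 noise sd above the positivity threshold and per-probe
misclassification is Φ(−2) ≈ 0.023, far below the 20% coverage rule.
Expression draws a per-gene baseline once (shared across conditions,
class mean ± sd) and adds independent per-condition noise (sd 0.1);
exon values scatter around the gene value with sd 0.3. The knockout
condition applies per-class deltas: body MIRA ×0.4 everywhere,
ZNF-like promoters demethylated (MIRA to baseline), H3K9me3 ×0.3 and
expression +0.8 on ZNF-like genes.

Promoter features (H3 acetylation at active promoters, promoter
methylation of repressed classes, the unmethylated-promoter UMC
signal) are planted over 500 bp upstream of the TSS plus the first
gene-body bin (1/20 of the body) downstream. The length-scaled
downstream extent keeps TSS features in exactly the two
composite-profile bins flanking the TSS while contributing only ~5% of
gene-body probes — so body-coverage classification reflects planted
*body* marks rather than promoter geometry, for every gene length. A
fixed ±500 bp window would instead place every short gene's
promoter-only marks near the 20% classification boundary, where probe
noise makes classification intrinsically unstable. Polycomb-class
bodies are planted with both MIRA and UMC enrichment, encoding partial
methylation as dual positive signals.

Chromosome sequence is drawn CpG-free and CpG dinucleotides are then
planted at disjoint even offsets — per-gene-body counts matching a
density drawn from the class distribution, CpG-island density over
island-flagged upstream promoters, and a background density elsewhere
— so realized densities match their targets up to rounding and
planting can never create unintended CpGs. Everything downstream of
the config is a pure function of the seed; identical configs produce
byte-identical bundles, which the suite verifies through a full
write/re-read round trip.

What the generator does **not** emulate: array heteroscedasticity and
dye effects (noise is homoscedastic Gaussian on the log2 scale),
masked repeats and probe-density gaps (the grid is uniform),
realistic nucleotide composition beyond CpG control, overlapping or
nested genes, and alternative promoters. Passing end-to-end tests
therefore demonstrates correctness of the analysis machinery under
the planted model, not robustness to these unmodelled features of
real arrays.

## Problem sizes and numerical choices

The test suite exercises the binning against a closed-form per-base
oracle on 200 random genes × 10,000 random probes; the chi-square and
Fisher implementations against exhaustive enumeration over all 2×2
tables with margins ≤ 12 (tolerances 1e−9 and 1e−7); correlation
recovery on 800 genes with a planted ρ = 0.4; and the full pipeline on
a 1,000-gene flagship chromosome, sizes chosen to keep the default run
comfortably on a single CPU. Planted-truth comparisons classify the
noise-free signal of the same configuration, so recovery rates measure
exactly the effect of probe noise.

Remaining numerical conventions: duplicate probe intervals collapse to
their mean with a warning; unsorted input tracks are sorted silently;
ties at classification thresholds follow the stated inclusivity rules
(`> theta_pos`, `>= theta_cov`, inclusive Δ thresholds, ties included
on the extreme side of expression strata); RefSeq-style transcripts
are kept per-record, not collapsed by symbol; overlapping genes each
receive all probes independently (per-gene summaries are independent,
so no deduplication is attempted); and ZNF identification defaults to
the case-sensitive symbol prefix "ZNF" with a user-supplied override
list for exactness.

## Known limitations

The pipeline starts from normalised log2 ratios — array normalisation,
probe remapping and peak calling are out of scope, as are genome
liftover, CpG-island calling (density only), and gene-ontology
analysis. Expression inputs are taken as provided (no RMA or probe-set
summarisation). The heatmap and composite exports are deliberately
plain tables; rendering is left to the analysis scripts.
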