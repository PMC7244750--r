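---
title: "Methods: deconvolving co-activator binding by conditional knockout"
author: "chromident"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deconvolving co-activator binding by conditional knockout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromident)
```

## The inference and its assumptions

Bulk chromatin profiles of a tissue are mixtures. If a fraction $f$ of
cells are neurons and a co-activator binds a site with per-cell
intensity $\mu_n$ in neurons and $\mu_{nn}$ elsewhere, the expected bulk
ChIP signal at that site is

$$E[\text{signal}] = f\,\mu_n\,\mathbb{1}[\text{bound in neurons}] +
  (1-f)\,\mu_{nn}\,\mathbb{1}[\text{bound elsewhere}] + b,$$

with $b$ a small background. A knockout restricted to neurons removes
exactly the first term at neuron-specific sites and (by assumption)
leaves shared sites detectable through the second term. `chromident`
turns this into a decision table: a consensus peak whose
knockout-vs-control differential binding is *down* (FDR < 0.05,
|log2FC| ≥ 1) and which overlaps neuron-sorted (NeuN+) ATAC consensus
regions is *neuronal*; a persistent peak is *pancellular* if accessible
in neurons and *non-neuronal* otherwise. Peaks that are lost but
inaccessible, or gained, do not fit the model and are flagged
*ambiguous* rather than forced into a class.

Assumptions worth stating: the knockout is complete and cell-type
restricted; accessibility in sorted neuronal nuclei is a faithful
indicator of neuronal chromatin use; and at shared sites the
non-neuronal contribution alone keeps the peak above the differential
threshold (true when $(1-f)\mu_{nn}$ is well above background, i.e. for
any tissue that is not almost purely neuronal).

## Differential testing

All differential calls (RNA, co-activator binding, acetylation,
accessibility) use one two-group negative-binomial test:

1. median-of-ratios size factors, rescaled to geometric mean 1, with an
   optional add-1 pseudo-reference for matrices in which no feature is
   positive everywhere;
2. `log2FC = log2((mean_KO + 0.5) / (mean_ctrl + 0.5))` on normalized
   counts, the 0.5 pseudo-count stabilizing low-count fold-changes;
3. a per-feature dispersion by pooled method of moments under
   `Var = mu/s + alpha * mu^2`, floored at `1e-8`;
4. a Wald statistic for the log fold-change with a delta-method
   standard error.

The Wald statistic is referred to a *t* distribution with
$n_1 + n_2 - 2$ degrees of freedom rather than a standard normal. With
the replicate numbers this design uses (2-5 per genotype) the
method-of-moments variance estimate is noisy, and the normal reference
is measurably anti-conservative (about 8-9% rejections at nominal 5% in
our null simulations at $n = 5 + 5$); the *t* reference restores the
nominal level (the suite asserts a type-I error inside [0.03, 0.07] on
2000 null features) while converging to the same test as replication
grows. The test deliberately omits dispersion shrinkage, Cook's
filtering and independent filtering: its role is a calibrated,
transparent two-group test whose validity is established by simulation,
not equivalence to any published tool (the suite does, however, check
that its fold-changes track DESeq2's MLE estimates on a common
fixture).

Deregulation uses FDR < 0.05 and |log2FC| ≥ 1, with the boundary
|log2FC| = 1 counting as significant; the strict `>` variant is
available via the `comparator` argument.

## Intervals, features and closest genes

Coordinates are 0-based half-open in memory (GTF converts on I/O).
Merging/stitching joins intervals transitively whenever the gap is
*strictly* smaller than the threshold ("closer than 5 kb"), so bookended
intervals merge at any positive threshold and a gap equal to the
threshold never merges. Feature assignment (promoter > exon > intron >
intergenic) and closest-gene annotation both evaluate the region
*midpoint*: peaks are narrow relative to genes, and a midpoint rule
makes every label single-valued without overlap-fraction parameters.
Ties in TSS distance break toward the lexicographically smaller gene id,
which keeps results independent of annotation order. Replicate
consistency is enforced by a per-base consensus filter (a region is kept
when some base is covered by peaks from `minSupport` replicates) in
place of IDR, which needs per-peak score distributions that region
lists do not carry.

## Regulatory typing and super-enhancers

Active promoters are H3K4me3-rich regions at promoters; enhancers are
H3K4me1-rich regions in introns or intergenic space. Because the source
data only say "rich"/"enriched", the implementation uses the sign of
`log2((me3 + 1)/(me1 + 1))` on library-normalized (CPM) control
signal — a balanced region types as neither. Enhancer-typed regions are
stitched at 5 kb and a stitched domain is a super-enhancer when it is
longer than 5 kb (strictly) and its closest-TSS gene is highly
expressed. The published expression gate is "one order of magnitude
above average, 100 RPKM"; the absolute form is kept as the default of
`callSuperEnhancers()`, but on a toy genome of a few hundred genes the
RPKM denominator (total mapped reads) is mechanically small and every
RPKM inflates, so the pipeline and the synthetic analysis apply the
relative form, `10 * mean(control RPKM)`, which is the definition the
absolute number encodes. Expression is averaged over control samples
only, since knockout expression is the phenotype under explanation.

## Association, enrichment, overlap

The regulatory potential of a gene is
$\sum_{\text{peaks}} e^{-(0.5 + 4d)}$ over peaks whose midpoint lies
within 100 kb of the TSS, $d$ the distance as a fraction of the window —
$e^{-0.5} \approx 0.61$ at the TSS, $e^{-4.5} \approx 0.011$ at the
edge. Both window and decay constants are arguments. Association with
expression change is a one-sided two-sample KS test of potentials of
*down* genes against *ns* genes, oriented so that stochastically larger
potentials in the regulated class give small p; classes below 20 genes
are flagged rather than tested. Marker-set enrichment is the exact
hypergeometric upper tail; the universe defaults to genes with positive
baseline expression. The overlap report maps each significantly
hypoacetylated region to its closest gene and returns both conditional
fractions (downregulated genes with hypoacetylation; hypoacetylated
genes that are downregulated).

## What the generator emulates — and what it does not

`simConfig()` defaults describe the study conditions end to end: 300
genes on 3 toy chromosomes (30% neuronal, 30% housekeeping), 150
regulatory elements per class, three replicates per genotype, NB counts
with dispersion 0.05 around a baseline mean of 200, a -2.5 log2
fold-change on neuronal genes in the knockout with a 10-gene
inflammatory-like upregulated set (so downregulations dominate, as in
the tissue), per-sample size factors log-uniform in [0.7, 1.4] so
normalization is genuinely exercised, background counts with mean 5 so
thresholds compete with noise, and a neuron fraction of f = 0.4 — a
realistic excitatory-neuron share of hippocampal tissue; the source
data do not pin this number down, so it is a free parameter. Twelve
neuronal identity genes carry clusters of 4-6 enhancers chained by
gaps under 5 kb (ground-truth super-enhancers) and an 80-fold
expression boost, placing them an order of magnitude above the mean as
the super-enhancer gate requires. Gene bodies sit in disjoint
territories with >10 kb spacing, so closest-gene assignment is
unambiguous by construction (an `overlappingGenes` switch removes the
guarantee for tie-break stress tests). Replicate peak sets jitter
element boundaries by ±50 bp, drop each peak with probability 0.08 and
add spurious peaks, so consensus filtering works against realistic
disagreement.

The generator does not emulate per-gene baseline heterogeneity beyond
the identity-gene boost, fragment-level coverage, copy-number or
mappability artifacts, correlated dispersion, more than two cell
populations, or single-nucleus data. Passing recovery tests on this
world therefore demonstrates the *logic* of the pipeline under its own
model — not performance on real libraries, where dispersion estimation
and peak calling are harder. One behavior seen at synthetic scale is
worth noting for real use: when replicate dropout removes a middle
member of an enhancer cluster from the consensus, the stitched domain
can split and fall under the length gate, costing recall — a known
sensitivity of stitching approaches.

## Numerical and degenerate-input choices

All randomness flows from one integer seed through named substreams
(one per stage), so any stage is reproducible in isolation and whole
runs are byte-identical. Dispersion estimates are floored at `1e-8`;
all-zero features return p = 1 and log2FC = 0; empty worlds produce
valid empty files; stitched domains whose assigned gene lacks an
expression value are skipped with a warning; correlation requires at
least three domains. The fold-change pseudo-count makes the test's
scale invariance exact only up to the geometric-mean normalization
convention (differences at the third decimal), which the suite checks
at that tolerance.

## Scale of the validation runs

The test suite and the acceptance script run the full analysis on
default worlds (300 genes, 450 elements, 3 + 3 replicates), use 2000
features for calibration checks, 200 random instances per brute-force
oracle, and 200 permutations for the null-uniformity check of the
association test — sizes at which every claim above is testable in a
few minutes on one CPU.
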