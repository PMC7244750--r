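# chromident

Cell-type deconvolution of transcriptional co-activator binding and
regulatory-element typing from conditional-knockout multi-omics.

## The problem

CBP and p300 (the KAT3 family of lysine acetyltransferases) are
transcriptional co-activators that bind tens of thousands of sites in
brain chromatin and deposit H3K27ac at active promoters and enhancers.
Bulk ChIP-seq of heterogeneous tissue, however, mixes binding from every
cell type. When both KAT3 genes are knocked out *only in excitatory
neurons*, the binding signal that disappears must have been neuronal,
while persistent signal belongs to other cell types — and chromatin
accessibility in sorted NeuN+ (neuronal) nuclei separates the persistent
sites into pancellular (shared) and non-neuronal ones. `chromident`
implements this deconvolution and the downstream analyses that link
binding loss to the collapse of the neuronal gene-expression program:

- **Differential testing** (`nbTest`, `bhAdjust`, `callSignificant`):
  a two-group negative-binomial Wald test with median-of-ratios
  normalization and Benjamini–Hochberg correction, applied uniformly to
  RNA counts and region read counts. Deregulation thresholds are
  FDR < 0.05 and |log2FC| ≥ 1.
- **Peak classification** (`consensusPeaks`, `classifyKat3Peaks`):
  replicate-consensus peaks labelled *neuronal* (binding lost in the KO
  and accessible in NeuN+ ATAC), *pancellular* (persistent and
  accessible) or *non-neuronal* (persistent and inaccessible).
- **Regulatory typing** (`annotateFeature`, `typeRegion`,
  `stitchEnhancers`, `callSuperEnhancers`): active promoters
  (H3K4me3-rich, within 1 kb of a TSS) versus enhancers (H3K4me1-rich,
  intronic/intergenic); enhancers chained by gaps under 5 kb are
  stitched, and stitched domains longer than 5 kb whose closest gene is
  highly expressed are called super-enhancers.
- **Binding–expression association** (`regulatoryPotential`,
  `betaAssociation`): each gene receives a regulatory potential
  `sum(exp(-(0.5 + 4*d)))` over peaks with midpoint within 100 kb of the
  TSS (`d` = distance/window); a one-sided two-sample Kolmogorov–Smirnov
  test asks whether downregulated genes carry larger potentials than
  unchanged genes.
- **Gene-set enrichment and overlap reporting**
  (`hypergeomEnrichment`, `overlapReport`): exact hypergeometric
  enrichment of regulated genes in cell-type marker sets, and the
  fraction of downregulated genes with hypoacetylated regions nearby
  (and the reciprocal).
- **A synthetic-data generator** (`simConfig`, `generateTruth`,
  `simulateRnaCounts`, `simulateRegionCounts`, `simulatePeakSets`,
  `writeFixtures`): a seeded toy genome whose chromatin signal follows
  the mixture model `f*mu_neuronal + (1-f)*mu_non_neuronal` with known
  element classes, so every stage can be validated against ground truth
  without any download.

`runPipeline()` drives the file-based pipeline from a YAML or
programmatic configuration; `runSyntheticAnalysis()` runs everything
in memory on a synthetic world and scores the results against truth.

## Worked example

```r
library(chromident)

cfg <- simConfig(seed = 1)     # 300 genes, 450 elements, f = 0.4
res <- runSyntheticAnalysis(cfg)

table(res$de$status)
#>   up down   ns
#>    9   88  203

table(res$classes$label)
#> ambiguous neuronal non_neuronal pancellular
#>         9      144          141         142

round(res$classAccuracy, 3)
#> [1] 0.97

res$association[res$association$comparison == "down_vs_ns", c("class", "D", "p")]
#>          class     D    p
#>            all 0.109 0.23
#>       neuronal 0.984 0.00
#>   non_neuronal 0.000 1.00
#>    pancellular 0.000 1.00

unlist(res$overlap[1:2])
#>  frac_down_with_hypo frac_hypo_genes_down
#>                0.989                0.978
```

Downregulations dominate the differential calls (88 down vs 9 up), the
three peak classes are recovered at 97% accuracy, only the
neuronal-class peaks associate with downregulation (KS p ~ 0 versus 1
for the persistent classes), and nearly all downregulated genes carry a
hypoacetylated region — the coupling the analysis is designed to
expose.

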