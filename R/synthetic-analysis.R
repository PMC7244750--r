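#' Run the full analysis on a synthetic world, scored against truth
#'
#' Generates a [TruthWorld-class] from `config` and drives every pipeline
#' stage in memory: RNA differential expression; consensus co-activator
#' peaks from replicate peak sets with differential binding;
#' NeuN+ ATAC consensus and cell-type classification;
#' promoter/enhancer typing from H3K4me1/me3; enhancer stitching with
#' super-enhancer calling (relative expression gate, 10x the mean control
#' RPKM); per-class regulatory-potential association; marker-set
#' enrichment; and the downregulation-hypoacetylation overlap report.
#' Because the ground truth is known, recovery metrics are returned
#' alongside the stage outputs.
#'
#' @param config a [SimConfig-class].
#' @param minSupport replicate support for consensus peaks.
#' @return list with stage outputs (`de`, `classes`, `typing`,
#'   `superEnhancers`, `association`, `enrichment`, `overlap`,
#'   `lengthExpression`) and truth metrics (`classAccuracy`,
#'   `sePrecision`, `seRecall`, `nTrueSuperEnhancers`).
#' @export
runSyntheticAnalysis <- function(config, minSupport = 2L) {
  world <- generateTruth(config)
  ann <- annotation(world)
  el <- elements(world)

  rna <- simulateRnaCounts(world, config)
  de <- runDiffTest(rna$counts, rna$sampleSheet)

  cons <- consensusPeaks(simulatePeakSets(world, config, "KAT3"),
                         minSupport)
  if (length(cons))
    mcols(cons)$name <- sprintf("kat3_peak_%04d", seq_along(cons))
  kat3 <- simulateRegionCounts(world, config, "KAT3", regions = cons)
  kat3Diff <- runDiffTest(kat3$counts, kat3$sampleSheet)
  atacCons <- consensusPeaks(simulatePeakSets(world, config, "ATAC"),
                             minSupport)
  classes <- classifyKat3Peaks(cons, kat3Diff, atacCons)

  hits <- GenomicRanges::findOverlaps(cons, el, ignore.strand = TRUE)
  trueClass <- rep(NA_character_, length(cons))
  trueClass[S4Vectors::queryHits(hits)] <-
    as.character(mcols(el)$class[S4Vectors::subjectHits(hits)])
  matched <- !is.na(trueClass)
  classAccuracy <- mean(classes$label[matched] == trueClass[matched])

  cpmCtrl <- function(x) {
    ctrl <- x$sampleSheet$genotype == "control"
    sub <- x$counts[, ctrl, drop = FALSE]
    rowMeans(sweep(sub, 2, colSums(sub) / 1e6, "/"))
  }
  me1 <- cpmCtrl(simulateRegionCounts(world, config, "H3K4me1",
                                      regions = cons))
  me3 <- cpmCtrl(simulateRegionCounts(world, config, "H3K4me3",
                                      regions = cons))
  feature <- annotateFeature(cons, ann)
  rtype <- typeRegion(me3, me1, feature)
  typing <- data.frame(feature = classes$feature, label = classes$label,
                       genomic_feature = feature, type = rtype)

  expr <- geneRpkm(rna$counts, rna$sampleSheet, ann)
  seGate <- 10 * mean(expr)
  enh <- cons[rtype == "enhancer" & classes$label == "neuronal"]
  stitched <- stitchEnhancers(enh)
  se <- callSuperEnhancers(stitched, expr, ann, minExpression = seGate)

  trueClusters <- unique(mcols(el)$se_cluster[!is.na(mcols(el)$se_cluster)])
  spans <- if (length(trueClusters)) {
    sp <- lapply(trueClusters, function(k)
      range(granges(el[!is.na(mcols(el)$se_cluster) &
                         mcols(el)$se_cluster == k])))
    unlist(GenomicRanges::GRangesList(sp))
  } else GRanges()
  seGr <- if (nrow(se)) bedRanges(se$chrom, se$start, se$end) else GRanges()
  sePrecision <- if (length(seGr))
    mean(IRanges::overlapsAny(seGr, spans)) else NA_real_
  seRecall <- if (length(spans))
    mean(IRanges::overlapsAny(spans, seGr)) else NA_real_
  lec <- if (length(stitched) >= 3L)
    lengthExpressionCorrelation(stitched, expr, ann)
  else list(pearson = NA_real_, spearman = NA_real_, n = length(stitched))

  assoc <- do.call(rbind, lapply(
    c("all", "neuronal", "non_neuronal", "pancellular"), function(lab) {
      sel <- if (lab == "all") rep(TRUE, length(cons))
             else classes$label == lab
      rp <- regulatoryPotential(ann, cons[sel])
      cbind(class = lab, betaAssociation(rp, de))
    }))

  universe <- de$feature[de$baseMean > 0]
  regulated <- intersect(de$feature[de$status != "ns"], universe)
  enrich <- do.call(rbind, lapply(names(markerSets(world)), function(nm) {
    gs <- intersect(markerSets(world)[[nm]], universe)
    hypergeomEnrichment(gs, regulated, universe, de = de, setName = nm)
  }))

  acCons <- consensusPeaks(simulatePeakSets(world, config, "H3K27ac"),
                           minSupport)
  if (length(acCons))
    mcols(acCons)$name <- sprintf("h3k27ac_%04d", seq_along(acCons))
  ac <- simulateRegionCounts(world, config, "H3K27ac", regions = acCons)
  acDiff <- runDiffTest(ac$counts, ac$sampleSheet)
  hypo <- acCons[mcols(acCons)$name %in%
                   acDiff$feature[acDiff$status == "down"]]
  overlap <- overlapReport(de, hypo, ann)

  list(world = world, de = de, consensus = cons, kat3Diff = kat3Diff,
       classes = classes, typing = typing, stitched = stitched,
       superEnhancers = se, expression = expr, seGate = seGate,
       association = assoc, enrichment = enrich, overlap = overlap,
       lengthExpression = lec, classAccuracy = classAccuracy,
       sePrecision = sePrecision, seRecall = seRecall,
       nTrueSuperEnhancers = length(trueClusters))
}
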