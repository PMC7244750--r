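#' Pipeline configuration
#'
#' Assembles and validates the inputs and thresholds of a full run. All
#' paths must exist at run time; thresholds default to the published
#' analysis parameters.
#'
#' @param annotation path to the gene annotation GTF.
#' @param rnaCounts,rnaSamples RNA count TSV and sample sheet TSV.
#' @param kat3Regions,kat3Counts,kat3Samples consensus co-activator peak
#'   BED with matching count TSV and sample sheet.
#' @param atacPeakSets character vector of replicate NeuN+ ATAC peak BEDs.
#' @param h3k27acRegions,h3k27acCounts,h3k27acSamples acetylation region
#'   BED, counts and samples.
#' @param me1Counts,me3Counts H3K4me1/me3 count TSVs at the co-activator
#'   regions.
#' @param geneSets path to a GMT of marker gene sets.
#' @param externalDeTable optional pre-computed RNA differential table
#'   (TSV with columns `feature`, `baseMean`, `log2FC`, `p`); bypasses the
#'   internal test.
#' @param alpha,minAbsLfc deregulation thresholds (FDR 0.05, |log2FC| 1).
#' @param lfcComparator `">="` or `">"` for the fold-change boundary.
#' @param stitchGap,minSeLength enhancer stitching gap and minimum
#'   super-enhancer length (bp).
#' @param minSeRpkm absolute super-enhancer expression gate; `NULL`
#'   (default) uses the relative definition, 10x the mean control RPKM.
#' @param promoterWindow promoter half-window (bp).
#' @param rpWindow regulatory-potential window (bp).
#' @param atacMinSupport replicate support for the ATAC consensus.
#' @param seed integer seed recorded in the manifest.
#' @param outDir output directory.
#' @return a validated list of class `chromident_config`.
#' @export
pipelineConfig <- function(annotation, rnaCounts, rnaSamples,
                           kat3Regions, kat3Counts, kat3Samples,
                           atacPeakSets,
                           h3k27acRegions, h3k27acCounts, h3k27acSamples,
                           me1Counts, me3Counts, geneSets,
                           externalDeTable = NULL,
                           alpha = 0.05, minAbsLfc = 1,
                           lfcComparator = ">=",
                           stitchGap = 5000L, minSeLength = 5000L,
                           minSeRpkm = NULL, promoterWindow = 1000L,
                           rpWindow = 1e5, atacMinSupport = 2L,
                           seed = 1L, outDir = "chromident_out") {
  cfg <- list(annotation = annotation, rnaCounts = rnaCounts,
              rnaSamples = rnaSamples, kat3Regions = kat3Regions,
              kat3Counts = kat3Counts, kat3Samples = kat3Samples,
              atacPeakSets = atacPeakSets,
              h3k27acRegions = h3k27acRegions,
              h3k27acCounts = h3k27acCounts,
              h3k27acSamples = h3k27acSamples,
              me1Counts = me1Counts, me3Counts = me3Counts,
              geneSets = geneSets, externalDeTable = externalDeTable,
              alpha = alpha, minAbsLfc = minAbsLfc,
              lfcComparator = lfcComparator, stitchGap = stitchGap,
              minSeLength = minSeLength, minSeRpkm = minSeRpkm,
              promoterWindow = promoterWindow, rpWindow = rpWindow,
              atacMinSupport = atacMinSupport,
              seed = as.integer(seed), outDir = outDir)
  if (alpha <= 0 || alpha >= 1) .stopf("alpha must be in (0, 1)")
  if (!lfcComparator %in% c(">=", ">"))
    .stopf("lfcComparator must be '>=' or '>'")
  pathFields <- c("annotation", "rnaCounts", "rnaSamples", "kat3Regions",
                  "kat3Counts", "kat3Samples", "h3k27acRegions",
                  "h3k27acCounts", "h3k27acSamples", "me1Counts",
                  "me3Counts", "geneSets")
  for (f in pathFields)
    if (!file.exists(cfg[[f]])) .stopf("missing input file (%s): %s", f, cfg[[f]])
  for (p in atacPeakSets)
    if (!file.exists(p)) .stopf("missing ATAC peak set: %s", p)
  if (!is.null(externalDeTable) && !file.exists(externalDeTable))
    .stopf("missing external DE table: %s", externalDeTable)
  class(cfg) <- "chromident_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Field names mirror the [pipelineConfig()] arguments; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return a `chromident_config`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  pathFields <- c("annotation", "rnaCounts", "rnaSamples", "kat3Regions",
                  "kat3Counts", "kat3Samples", "h3k27acRegions",
                  "h3k27acCounts", "h3k27acSamples", "me1Counts",
                  "me3Counts", "geneSets", "externalDeTable")
  for (f in intersect(pathFields, names(y))) y[[f]] <- resolve(y[[f]])
  if ("atacPeakSets" %in% names(y))
    y$atacPeakSets <- vapply(y$atacPeakSets, resolve, character(1))
  do.call(pipelineConfig, y)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full integration pipeline
#'
#' Executes, in order: RNA differential expression; differential
#' co-activator binding and differential acetylation on region counts;
#' ATAC consensus and peak classification into neuronal / non-neuronal /
#' pancellular; promoter/enhancer typing by H3K4me1/me3; enhancer
#' stitching and super-enhancer calling; regulatory-potential association
#' per peak class; marker-set enrichment; and the
#' downregulation-hypoacetylation overlap report. All stage tables are
#' written as TSV (regions additionally as BED) under `config$outDir`,
#' plus a JSON manifest echoing the configuration. Identical
#' configuration and seed give byte-identical outputs.
#'
#' @param config a `chromident_config` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param verbose log stage progress to standard error.
#' @return invisibly, a list with the in-memory stage results and the
#'   output file paths.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "chromident_config"))
  say <- function(...) if (verbose) message("[chromident] ", ...)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outDir, f)
  files <- character()

  say("reading inputs")
  ann <- readGtfAnnotation(config$annotation)
  rnaCounts <- readCountMatrix(config$rnaCounts)
  rnaSamples <- readSampleSheet(config$rnaSamples)
  kat3Regions <- readBed(config$kat3Regions)
  kat3Counts <- readCountMatrix(config$kat3Counts)
  kat3Samples <- readSampleSheet(config$kat3Samples)
  h3k27acRegions <- readBed(config$h3k27acRegions)
  h3k27acCounts <- readCountMatrix(config$h3k27acCounts)
  h3k27acSamples <- readSampleSheet(config$h3k27acSamples)
  me1Counts <- readCountMatrix(config$me1Counts)
  me3Counts <- readCountMatrix(config$me3Counts)
  geneSets <- readGmt(config$geneSets)

  say("RNA differential expression")
  externalTable <- if (!is.null(config$externalDeTable))
    utils::read.delim(config$externalDeTable, stringsAsFactors = FALSE)
  else NULL
  de <- runDiffTest(rnaCounts, rnaSamples, alpha = config$alpha,
                    minAbsLfc = config$minAbsLfc,
                    comparator = config$lfcComparator,
                    externalTable = externalTable)
  files["de_rna"] <- .writeTsv(de, out("de_rna.tsv"))

  say("differential region signal")
  kat3Diff <- runDiffTest(kat3Counts, kat3Samples, alpha = config$alpha,
                          minAbsLfc = config$minAbsLfc,
                          comparator = config$lfcComparator)
  files["diff_kat3"] <- .writeTsv(kat3Diff, out("diff_kat3.tsv"))
  acDiff <- runDiffTest(h3k27acCounts, h3k27acSamples, alpha = config$alpha,
                        minAbsLfc = config$minAbsLfc,
                        comparator = config$lfcComparator)
  files["diff_h3k27ac"] <- .writeTsv(acDiff, out("diff_h3k27ac.tsv"))

  say("ATAC consensus and peak classification")
  atacSets <- lapply(config$atacPeakSets, readBed)
  atacConsensus <- consensusPeaks(atacSets,
                                  minSupport = config$atacMinSupport)
  writeBed(atacConsensus, out("atac_consensus.bed"))
  files["atac_consensus"] <- out("atac_consensus.bed")
  classes <- classifyKat3Peaks(kat3Regions, kat3Diff, atacConsensus)
  files["peak_classes"] <- .writeTsv(classes, out("peak_classes.tsv"))
  classBed <- kat3Regions
  mcols(classBed)$name <- paste(classes$feature, classes$label, sep = "|")
  writeBed(classBed, out("peak_classes.bed"))
  files["peak_classes_bed"] <- out("peak_classes.bed")

  say("promoter/enhancer typing")
  cpm <- function(m, samples) {
    ctrl <- samples$genotype == "control"
    sub <- m[, ctrl, drop = FALSE]
    rowMeans(sweep(sub, 2, colSums(sub) / 1e6, "/"))
  }
  ids <- mcols(kat3Regions)$name
  me1 <- cpm(me1Counts, readSampleSheet(config$kat3Samples))[ids]
  me3 <- cpm(me3Counts, readSampleSheet(config$kat3Samples))[ids]
  feature <- annotateFeature(kat3Regions, ann,
                             promoterWindow = config$promoterWindow)
  rtype <- typeRegion(me3, me1, feature)
  typing <- cbind(classes[, c("feature", "chrom", "start", "end", "label")],
                  genomic_feature = feature, me1_cpm = unname(me1),
                  me3_cpm = unname(me3), type = rtype)
  files["regulatory_types"] <- .writeTsv(typing, out("regulatory_types.tsv"))

  say("super-enhancers")
  expr <- geneRpkm(rnaCounts, rnaSamples, ann)
  seGate <- if (is.null(config$minSeRpkm)) 10 * mean(expr)
            else config$minSeRpkm
  enh <- kat3Regions[rtype == "enhancer" & classes$label == "neuronal"]
  stitched <- stitchEnhancers(enh, stitchGap = config$stitchGap)
  se <- callSuperEnhancers(stitched, expr, ann,
                           minLength = config$minSeLength,
                           minExpression = seGate)
  files["superenhancers"] <- .writeTsv(se, out("superenhancers.tsv"))
  if (nrow(se))
    writeBed(bedRanges(se$chrom, se$start, se$end, name = se$gene),
             out("superenhancers.bed"))
  else writeBed(GRanges(), out("superenhancers.bed"))
  files["superenhancers_bed"] <- out("superenhancers.bed")
  lec <- if (length(stitched) >= 3L)
    lengthExpressionCorrelation(stitched, expr, ann)
  else list(pearson = NA_real_, spearman = NA_real_, n = length(stitched))
  files["length_expression"] <- .writeTsv(
    data.frame(pearson = lec$pearson, spearman = lec$spearman, n = lec$n),
    out("length_expression.tsv"))

  say("binding-expression association")
  assoc <- do.call(rbind, lapply(
    c("all", "neuronal", "non_neuronal", "pancellular"), function(cl) {
      sel <- if (cl == "all") rep(TRUE, length(kat3Regions))
             else classes$label == cl
      rp <- regulatoryPotential(ann, kat3Regions[sel],
                                window = config$rpWindow)
      res <- betaAssociation(rp, de)
      cbind(class = cl, res)
    }))
  files["association"] <- .writeTsv(assoc, out("association.tsv"))

  say("marker-set enrichment")
  universe <- de$feature[de$baseMean > 0]
  regulated <- de$feature[de$status != "ns"]
  enrich <- do.call(rbind, lapply(names(geneSets), function(nm) {
    gs <- intersect(geneSets[[nm]], universe)
    hypergeomEnrichment(gs, intersect(regulated, universe), universe,
                        de = de, setName = nm)
  }))
  files["enrichment"] <- .writeTsv(enrich, out("enrichment.tsv"))

  say("overlap report")
  acDown <- acDiff$feature[acDiff$status == "down"]
  hypo <- h3k27acRegions[mcols(h3k27acRegions)$name %in% acDown]
  ov <- overlapReport(de, hypo, ann)
  files["overlap_report"] <- .writeTsv(
    data.frame(frac_down_with_hypo = ov$frac_down_with_hypo,
               frac_hypo_genes_down = ov$frac_hypo_genes_down,
               n_down = ov$n_down, n_hypo_genes = ov$n_hypo_genes),
    out("overlap_report.tsv"))

  manifest <- list(
    package = "chromident",
    version = as.character(utils::packageVersion("chromident")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "outDir")],
    outputs = as.list(files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  files["manifest"] <- out("manifest.json")

  invisible(list(de = de, kat3Diff = kat3Diff, acDiff = acDiff,
                 atacConsensus = atacConsensus, classes = classes,
                 typing = typing, stitched = stitched,
                 superEnhancers = se, lengthExpression = lec,
                 association = assoc, enrichment = enrich,
                 overlap = ov, expression = expr, seGate = seGate,
                 files = files))
}
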