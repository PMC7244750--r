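#' Construct a simulation configuration
#'
#' Defaults describe the study design the package targets: bulk hippocampal
#' tissue in which excitatory neurons (a fraction `f` of cells) lose both
#' KAT3 co-activators upon conditional knockout, three replicates per
#' genotype, a neuronal gene program strongly downregulated in the KO with
#' a small inflammatory-like upregulated set, and regulatory elements whose
#' ChIP signal mixes neuronal and non-neuronal contributions. See the
#' methods vignette for the rationale behind each default.
#'
#' @param nChromosomes,chromLength toy genome shape.
#' @param nGenes,fracNeuronalGenes,fracHousekeeping gene program sizes.
#' @param nElementsPerClass regulatory elements per cell-type class.
#' @param neuronFraction neuron fraction `f` of the bulk tissue.
#' @param baselineMean,dispersion NB parameters (`Var = mu + alpha mu^2`).
#' @param koLog2fcNeuronal log2 fold-change of neuronal genes in KO.
#' @param nReplicates replicates per genotype.
#' @param backgroundMean mean count at unbound/closed regions.
#' @param signalMean mean count contributed by a fully represented, bound
#'   cell population.
#' @param nUpregulated,upLog2fc inflammatory-analogue upregulated set.
#' @param nSuperEnhancers,seExpressionBoost ground-truth super-enhancer
#'   clusters and the expression boost of their target genes.
#' @param sizeFactorRange log-uniform range of per-sample size factors.
#' @param peakDropout per-replicate peak miss probability.
#' @param overlappingGenes drop the gene-spacing guarantee (stress mode).
#' @param seed master seed; every stage derives a named substream from it.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(nChromosomes = 3L, chromLength = 1.2e7,
                      nGenes = 300L, fracNeuronalGenes = 0.3,
                      fracHousekeeping = 0.3, nElementsPerClass = 150L,
                      neuronFraction = 0.4, baselineMean = 200,
                      dispersion = 0.05, koLog2fcNeuronal = -2.5,
                      nReplicates = 3L, backgroundMean = 5,
                      signalMean = 150, nUpregulated = 10L, upLog2fc = 1.5,
                      nSuperEnhancers = 12L, seExpressionBoost = 80,
                      sizeFactorRange = c(0.7, 1.4), peakDropout = 0.08,
                      overlappingGenes = FALSE, seed = 1L) {
  new("SimConfig",
      nChromosomes = as.integer(nChromosomes), chromLength = chromLength,
      nGenes = as.integer(nGenes), fracNeuronalGenes = fracNeuronalGenes,
      fracHousekeeping = fracHousekeeping,
      nElementsPerClass = as.integer(nElementsPerClass),
      neuronFraction = neuronFraction, baselineMean = baselineMean,
      dispersion = dispersion, koLog2fcNeuronal = koLog2fcNeuronal,
      nReplicates = as.integer(nReplicates), backgroundMean = backgroundMean,
      signalMean = signalMean, nUpregulated = as.integer(nUpregulated),
      upLog2fc = upLog2fc, nSuperEnhancers = as.integer(nSuperEnhancers),
      seExpressionBoost = seExpressionBoost,
      sizeFactorRange = sizeFactorRange, peakDropout = peakDropout,
      overlappingGenes = overlappingGenes, seed = as.integer(seed))
}

# upstream-of-TSS placement: returns 0-based half-open (start, end)
.placeUpstream <- function(tss, strandChar, offset, width) {
  if (strandChar == "+") c(tss - offset - width, tss - offset)
  else c(tss + offset + 1, tss + offset + 1 + width)
}

#' Generate the ground-truth world
#'
#' Lays out non-overlapping gene bodies (one per ~`chromLength / n` slot,
#' spacing far above 10 kb so closest-gene assignment is unambiguous),
#' assigns gene programs, and places regulatory elements: every neuronal
#' gene carries at least one neuronal element (a promoter or an upstream
#' enhancer); `nSuperEnhancers` neuronal identity genes instead carry a
#' cluster of 4-6 enhancers chained by gaps under 5 kb (a ground-truth
#' super-enhancer); housekeeping genes carry pancellular promoters; the
#' non-neuronal class consists of enhancers at genes outside the neuronal
#' program. Marker gene sets for simulated cell types are drawn from the
#' programs. Deterministic for a fixed `seed`.
#'
#' @param config a [SimConfig-class].
#' @return a [TruthWorld-class].
#' @export
generateTruth <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(.substreamSeed(config@seed, "truth"))

  chroms <- paste0("chr", seq_len(config@nChromosomes))
  cl <- stats::setNames(rep(config@chromLength, config@nChromosomes), chroms)
  nG <- config@nGenes

  if (nG == 0L) {
    ann <- new("GenomeAnnotation", chromLengths = cl,
               genes = GRanges(), exons = S4Vectors::split(GRanges(), factor()))
    return(new("TruthWorld", annotation = ann, elements = GRanges(),
               genePrograms = character(), markerSets = list(),
               config = config))
  }

  perChrom <- ceiling(nG / config@nChromosomes)
  slot <- floor(config@chromLength / perChrom)
  if (!config@overlappingGenes && slot < 70000)
    .stopf("chromosomes too short for %d non-overlapping gene territories (need >= 70 kb each, got %d bp)",
           perChrom, slot)

  gid <- sprintf("gene_%04d", seq_len(nG))
  chromOf <- chroms[((seq_len(nG) - 1L) %/% perChrom) + 1L]
  slotIdx <- (seq_len(nG) - 1L) %% perChrom
  gStart <- slotIdx * slot + 45000 + floor(stats::runif(nG, 0, 10000))
  gLen <- round(stats::runif(nG, 4000, 10000))
  gStrand <- sample(c("+", "-"), nG, replace = TRUE)
  gEnd <- gStart + gLen
  tss <- ifelse(gStrand == "+", gStart, gEnd - 1)

  genesGr <- GRanges(chromOf, IRanges(gStart + 1, gEnd), strand = gStrand)
  mcols(genesGr)$gene_id <- gid
  mcols(genesGr)$tss <- tss

  # 2-4 exons per gene, first exon anchored at the TSS end of the body
  exList <- lapply(seq_len(nG), function(i) {
    nEx <- sample(2:4, 1)
    chunk <- floor(gLen[i] / nEx)
    exS <- gStart[i] + (seq_len(nEx) - 1L) * chunk
    exE <- exS + pmax(200L, floor(chunk / 2))
    GRanges(chromOf[i], IRanges(exS + 1, pmin(exE, gEnd[i])))
  })
  exons <- S4Vectors::split(
    unlist(GenomicRanges::GRangesList(exList)),
    factor(rep(gid, lengths(exList)), levels = gid))

  ann <- new("GenomeAnnotation", chromLengths = cl, genes = genesGr,
             exons = exons)

  # gene programs
  nNeu <- round(config@fracNeuronalGenes * nG)
  nHk <- round(config@fracHousekeeping * nG)
  shuffled <- sample(gid)
  neuGenes <- sort(shuffled[seq_len(nNeu)])
  hkGenes <- sort(shuffled[nNeu + seq_len(nHk)])
  otherGenes <- sort(setdiff(gid, c(neuGenes, hkGenes)))
  programs <- stats::setNames(rep("other", nG), gid)
  programs[neuGenes] <- "neuronal"
  programs[hkGenes] <- "housekeeping"

  nSE <- min(config@nSuperEnhancers, length(neuGenes))
  seGenes <- sort(sample(neuGenes, nSE))

  tssOf <- stats::setNames(tss, gid)
  strandOf <- stats::setNames(gStrand, gid)
  chromOfGene <- stats::setNames(chromOf, gid)

  rows <- list()
  addEl <- function(gene, se0, se1, class, type, cluster = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chromOfGene[[gene]], start = se0, end = se1,
      class = class, type = type, target_gene = gene,
      se_cluster = cluster, stringsAsFactors = FALSE)
  }
  promoterAt <- function(gene, class) {
    t0 <- tssOf[[gene]]
    addEl(gene, t0 - 300, t0 + 300, class, "promoter")
  }
  # grid of upstream offsets; spacing keeps single enhancers of one gene
  # from chaining at the 5-kb stitch gap
  enhancerGrid <- c(4000, 11000, 18000)

  # neuronal class
  usedOffsets <- list()
  neuCount <- 0L
  for (gi in seq_along(seGenes)) {
    g <- seGenes[gi]
    nEnh <- sample(4:6, 1)
    pos <- 2500
    for (k in seq_len(nEnh)) {
      w <- sample(600:1000, 1)
      se <- .placeUpstream(tssOf[[g]], strandOf[[g]], pos, w)
      addEl(g, se[1], se[2], "neuronal", "enhancer", cluster = gi)
      pos <- pos + w + sample(1500:3500, 1)
    }
    neuCount <- neuCount + nEnh
  }
  singles <- setdiff(neuGenes, seGenes)
  for (g in singles) {
    if (stats::runif(1) < 0.3) {
      promoterAt(g, "neuronal")
    } else {
      off <- sample(enhancerGrid, 1)
      w <- sample(600:1000, 1)
      se <- .placeUpstream(tssOf[[g]], strandOf[[g]], off, w)
      addEl(g, se[1], se[2], "neuronal", "enhancer")
      usedOffsets[[g]] <- off
    }
    neuCount <- neuCount + 1L
  }
  topUp <- config@nElementsPerClass - neuCount
  if (topUp < 0L)
    .stopf("nElementsPerClass (%d) too small for %d neuronal genes plus %d super-enhancer clusters",
           config@nElementsPerClass, length(neuGenes), nSE)
  pool <- singles
  while (topUp > 0L && length(pool)) {
    g <- sample(pool, 1)
    free <- setdiff(enhancerGrid, usedOffsets[[g]])
    if (!length(free)) { pool <- setdiff(pool, g); next }
    off <- if (length(free) == 1L) free else sample(free, 1)
    w <- sample(600:1000, 1)
    se <- .placeUpstream(tssOf[[g]], strandOf[[g]], off, w)
    addEl(g, se[1], se[2], "neuronal", "enhancer")
    usedOffsets[[g]] <- c(usedOffsets[[g]], off)
    topUp <- topUp - 1L
  }

  # pancellular class: promoters of housekeeping genes, topped up with
  # promoters of genes outside the neuronal program
  if (length(hkGenes) > config@nElementsPerClass)
    .stopf("nElementsPerClass (%d) smaller than the %d housekeeping genes",
           config@nElementsPerClass, length(hkGenes))
  for (g in hkGenes) promoterAt(g, "pancellular")
  panTop <- config@nElementsPerClass - length(hkGenes)
  panPool <- otherGenes
  if (panTop > 0L && length(panPool)) {
    extra <- sample(panPool, min(panTop, length(panPool)))
    for (g in extra) promoterAt(g, "pancellular")
  }

  # non-neuronal class: enhancers at genes outside the neuronal program
  nnUsed <- list()
  nnLeft <- config@nElementsPerClass
  nnPool <- otherGenes
  while (nnLeft > 0L && length(nnPool)) {
    g <- sample(nnPool, 1)
    free <- setdiff(enhancerGrid, nnUsed[[g]])
    if (!length(free)) { nnPool <- setdiff(nnPool, g); next }
    off <- if (length(free) == 1L) free else sample(free, 1)
    w <- sample(600:1000, 1)
    se <- .placeUpstream(tssOf[[g]], strandOf[[g]], off, w)
    addEl(g, se[1], se[2], "non_neuronal", "enhancer")
    nnUsed[[g]] <- c(nnUsed[[g]], off)
    nnLeft <- nnLeft - 1L
  }

  df <- do.call(rbind, rows)
  el <- bedRanges(df$chrom, pmax(df$start, 0), df$end,
                  class = df$class, type = df$type,
                  target_gene = df$target_gene, se_cluster = df$se_cluster)
  ord <- order(factor(as.character(seqnames(el)), levels = chroms), start(el))
  el <- el[ord]
  mcols(el)$element_id <- sprintf("el_%04d", seq_along(el))
  mcols(el) <- mcols(el)[, c("element_id", "class", "type", "target_gene",
                             "se_cluster")]

  markers <- list(
    pyramidal_neuron = sort(sample(neuGenes, max(1L, round(2 / 3 * length(neuGenes))))),
    microglia = if (length(otherGenes))
      sort(sample(otherGenes, min(30L, length(otherGenes)))) else character(),
    astrocyte = if (length(otherGenes))
      sort(sample(otherGenes, min(30L, length(otherGenes)))) else character(),
    housekeeping = hkGenes
  )

  new("TruthWorld", annotation = ann, elements = el,
      genePrograms = programs, markerSets = markers, config = config)
}

#' Simulate RNA-seq counts
#'
#' Negative-binomial counts per gene and sample. Control samples have mean
#' `mu0 * s_j` (size factor `s_j` log-uniform in the configured range);
#' in KO samples neuronal genes are scaled by `2^koLog2fcNeuronal` and a
#' small inflammatory-analogue set (drawn from the microglia marker set)
#' by `2^upLog2fc`; housekeeping and remaining genes are unchanged.
#' Super-enhancer target genes carry a constitutive expression boost in
#' both genotypes.
#'
#' @param world a [TruthWorld-class].
#' @param config the [SimConfig-class] the world was generated from.
#' @return list with `counts` (integer matrix genes x samples),
#'   `sampleSheet` (columns `sample`, `genotype`, `replicate`,
#'   `size_factor` -- the true factors, exposed for calibration tests) and
#'   `upregulated` (the gene ids of the planted up set).
#' @export
simulateRnaCounts <- function(world, config) {
  stopifnot(is(world, "TruthWorld"))
  set.seed(.substreamSeed(config@seed, "rna"))
  g <- genes(world)
  gid <- mcols(g)$gene_id
  nG <- length(gid)
  nRep <- config@nReplicates
  samples <- data.frame(
    sample = c(paste0("ctrl_", seq_len(nRep)), paste0("ko_", seq_len(nRep))),
    genotype = rep(c("control", "KO"), each = nRep),
    replicate = rep(seq_len(nRep), 2),
    stringsAsFactors = FALSE)
  sf <- exp(stats::runif(nrow(samples), log(config@sizeFactorRange[1]),
                         log(config@sizeFactorRange[2])))
  samples$size_factor <- sf
  if (nG == 0L) {
    m <- matrix(0L, 0, nrow(samples),
                dimnames = list(character(), samples$sample))
    return(list(counts = m, sampleSheet = samples, upregulated = character()))
  }

  seGenes <- unique(mcols(elements(world))$target_gene[
    !is.na(mcols(elements(world))$se_cluster)])
  baseMu <- stats::setNames(rep(config@baselineMean, nG), gid)
  baseMu[seGenes] <- baseMu[seGenes] * config@seExpressionBoost

  mg <- markerSets(world)$microglia
  up <- if (config@nUpregulated > 0L && length(mg))
    mg[seq_len(min(config@nUpregulated, length(mg)))] else character()
  neu <- names(genePrograms(world))[genePrograms(world) == "neuronal"]

  koMu <- baseMu
  koMu[neu] <- koMu[neu] * 2^config@koLog2fcNeuronal
  koMu[up] <- baseMu[up] * 2^config@upLog2fc

  m <- matrix(0L, nG, nrow(samples), dimnames = list(gid, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- if (samples$genotype[j] == "KO") koMu else baseMu
    m[, j] <- .rnb(nG, mu * sf[j], config@dispersion)
  }
  list(counts = m, sampleSheet = samples, upregulated = up)
}

.assayMeans <- function(cls, type, assay, config) {
  f <- config@neuronFraction
  mu <- config@signalMean
  bg <- config@backgroundMean
  neuOn <- cls %in% c("neuronal", "pancellular")
  nnOn <- cls %in% c("non_neuronal", "pancellular")
  switch(assay,
    KAT3 = ,
    H3K27ac = list(
      control = f * mu * neuOn + (1 - f) * mu * nnOn + bg,
      KO = f * mu * (neuOn & cls != "neuronal") +
        (1 - f) * mu * nnOn + bg),
    ATAC = list(  # sorted NeuN+ nuclei: purely neuronal signal
      control = mu * neuOn + bg,
      KO = mu * (neuOn & cls != "neuronal") + bg),
    H3K4me1 = {
      v <- mu * (type == "enhancer") + bg
      list(control = v, KO = v)
    },
    H3K4me3 = {
      v <- mu * (type == "promoter") + bg
      list(control = v, KO = v)
    },
    .stopf("unknown assay: %s", assay))
}

#' Simulate region read counts for a chromatin assay
#'
#' Encodes the mixture model of bulk chromatin from heterogeneous tissue:
#' at each element the control mean is
#' `f * mu * 1[class in {neuronal, pancellular}] +
#'  (1 - f) * mu * 1[class in {non_neuronal, pancellular}] + background`,
#' and the knockout removes only the neuronal contribution of
#' neuronal-class elements (cell-type-restricted ablation leaves
#' non-neuronal and pancellular binding intact). ATAC counts represent
#' sorted NeuN+ nuclei: full signal at neuronal and pancellular elements,
#' background at non-neuronal ones, with neuronal accessibility lost in
#' the KO. H3K4me1/H3K4me3 depend on element type (enhancer / promoter)
#' and are genotype-independent.
#'
#' @param world a [TruthWorld-class].
#' @param config the matching [SimConfig-class].
#' @param assay one of `"KAT3"`, `"H3K27ac"`, `"ATAC"`, `"H3K4me1"`,
#'   `"H3K4me3"`.
#' @param regions `GRanges` at which to count (default: the world's
#'   elements). Regions are matched to elements by maximal overlap;
#'   unmatched regions draw background counts in both genotypes.
#' @param nReplicates replicates per genotype (default from config).
#' @return list with `counts` (regions x samples), `sampleSheet`
#'   (with true `size_factor`), and `regions` (the `GRanges` used, with a
#'   `feature` id column matching rownames).
#' @export
simulateRegionCounts <- function(world, config, assay, regions = NULL,
                                 nReplicates = config@nReplicates) {
  stopifnot(is(world, "TruthWorld"))
  assay <- match.arg(assay, c("KAT3", "H3K27ac", "ATAC", "H3K4me1", "H3K4me3"))
  set.seed(.substreamSeed(config@seed, paste0("regions_", assay)))
  el <- elements(world)
  if (is.null(regions)) regions <- el
  ids <- if (!is.null(mcols(regions)$name)) mcols(regions)$name
         else if (!is.null(mcols(regions)$element_id)) mcols(regions)$element_id
         else sprintf("%s_region_%04d", tolower(assay), seq_along(regions))

  cls <- rep("background", length(regions))
  typ <- rep("none", length(regions))
  if (length(el) && length(regions)) {
    hits <- GenomicRanges::findOverlaps(regions, el, ignore.strand = TRUE)
    if (length(hits)) {
      ovw <- width(IRanges::pintersect(
        IRanges::ranges(regions)[S4Vectors::queryHits(hits)],
        IRanges::ranges(el)[S4Vectors::subjectHits(hits)]))
      best <- tapply(seq_along(hits), S4Vectors::queryHits(hits),
                     function(i) i[which.max(ovw[i])])
      qh <- as.integer(names(best))
      sh <- S4Vectors::subjectHits(hits)[unlist(best)]
      cls[qh] <- as.character(mcols(el)$class[sh])
      typ[qh] <- as.character(mcols(el)$type[sh])
    }
  }
  mus <- .assayMeans(cls, typ, assay, config)

  samples <- data.frame(
    sample = c(paste0("ctrl_", seq_len(nReplicates)),
               paste0("ko_", seq_len(nReplicates))),
    genotype = rep(c("control", "KO"), each = nReplicates),
    replicate = rep(seq_len(nReplicates), 2),
    stringsAsFactors = FALSE)
  sf <- exp(stats::runif(nrow(samples), log(config@sizeFactorRange[1]),
                         log(config@sizeFactorRange[2])))
  samples$size_factor <- sf
  m <- matrix(0L, length(regions), nrow(samples),
              dimnames = list(ids, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- if (samples$genotype[j] == "KO") mus$KO else mus$control
    if (length(regions)) m[, j] <- .rnb(length(regions), mu * sf[j],
                                        config@dispersion)
  }
  out <- regions
  mcols(out)$feature <- ids
  list(counts = m, sampleSheet = samples, regions = out)
}

#' Simulate replicate peak sets
#'
#' Emits per-replicate peak calls as jittered copies of the true elements
#' detectable by the assay in the given genotype, with a per-replicate
#' dropout probability and a few spurious noise peaks, so that consensus
#' filtering is exercised against realistic replicate disagreement.
#'
#' @inheritParams simulateRegionCounts
#' @param genotype `"control"` or `"KO"`.
#' @return list of `GRanges`, one per replicate, each with a `name` column
#'   (`element_id` for true peaks, `noise_*` otherwise).
#' @export
simulatePeakSets <- function(world, config, assay, genotype = "control",
                             nReplicates = config@nReplicates) {
  assay <- match.arg(assay, c("KAT3", "H3K27ac", "ATAC"))
  genotype <- match.arg(genotype, c("control", "KO"))
  set.seed(.substreamSeed(config@seed, paste0("peaks_", assay, "_", genotype)))
  el <- elements(world)
  cls <- as.character(mcols(el)$class)
  present <- switch(assay,
    KAT3 = ,
    H3K27ac = if (genotype == "control") rep(TRUE, length(el))
              else cls != "neuronal",
    ATAC = if (genotype == "control") cls %in% c("neuronal", "pancellular")
           else cls == "pancellular")
  base <- el[present]
  chroms <- names(chromLengths(world))
  lapply(seq_len(nReplicates), function(i) {
    keep <- stats::runif(length(base)) >= config@peakDropout
    p <- base[keep]
    j1 <- round(stats::runif(length(p), -50, 50))
    j2 <- round(stats::runif(length(p), -50, 50))
    newStart <- pmax(1L, start(p) + j1)
    newEnd <- pmax(newStart + 100L, end(p) + j2)
    out <- GRanges(seqnames(p), IRanges(newStart, newEnd))
    mcols(out)$name <- mcols(p)$element_id
    nNoise <- 5L
    if (length(chroms)) {
      nch <- sample(chroms, nNoise, replace = TRUE)
      ns <- floor(stats::runif(nNoise, 1, chromLengths(world)[nch] - 600))
      noise <- GRanges(nch, IRanges(ns, ns + 500))
      mcols(noise)$name <- sprintf("noise_%d_%d", i, seq_len(nNoise))
      out <- c(out, noise)
    }
    sort(out)
  })
}

#' Write a complete fixture bundle to disk
#'
#' Emits the annotation (GTF), per-assay replicate peak BEDs, consensus
#' region BEDs with matching count TSVs and sample sheets, the RNA count
#' matrix, marker gene sets (GMT), and the ground-truth element table.
#' Everything round-trips through the package readers.
#'
#' @param world a [TruthWorld-class].
#' @param config the matching [SimConfig-class].
#' @param outDir output directory (created if needed).
#' @param minSupport replicate support required for consensus regions.
#' @return invisibly, a named list of the written file paths.
#' @export
writeFixtures <- function(world, config, outDir, minSupport = 2L) {
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(outDir, ...)
  files <- list()

  writeGtfAnnotation(annotation(world), pth("annotation.gtf"))
  files$annotation <- pth("annotation.gtf")

  rna <- simulateRnaCounts(world, config)
  writeCountMatrix(rna$counts, pth("rna_counts.tsv"))
  writeSampleSheet(rna$sampleSheet, pth("rna_samples.tsv"))
  files$rna_counts <- pth("rna_counts.tsv")
  files$rna_samples <- pth("rna_samples.tsv")

  empty <- length(elements(world)) == 0L
  consensusOf <- function(sets) {
    if (empty) GRanges() else consensusPeaks(sets, minSupport = minSupport)
  }

  for (assay in c("KAT3", "H3K27ac", "ATAC")) {
    lab <- tolower(assay)
    sets <- simulatePeakSets(world, config, assay, "control")
    for (i in seq_along(sets)) {
      f <- pth(sprintf("%s_rep%d.bed", lab, i))
      writeBed(sets[[i]], f)
      files[[sprintf("%s_rep%d", lab, i)]] <- f
    }
    cons <- consensusOf(sets)
    if (length(cons))
      mcols(cons)$name <- sprintf("%s_peak_%04d", lab, seq_along(cons))
    writeBed(cons, pth(sprintf("%s_regions.bed", lab)))
    files[[paste0(lab, "_regions")]] <- pth(sprintf("%s_regions.bed", lab))
    rc <- simulateRegionCounts(world, config, assay, regions = cons)
    writeCountMatrix(rc$counts, pth(sprintf("%s_counts.tsv", lab)))
    writeSampleSheet(rc$sampleSheet, pth(sprintf("%s_samples.tsv", lab)))
    files[[paste0(lab, "_counts")]] <- pth(sprintf("%s_counts.tsv", lab))
    files[[paste0(lab, "_samples")]] <- pth(sprintf("%s_samples.tsv", lab))
    if (assay == "KAT3") {
      for (mark in c("H3K4me1", "H3K4me3")) {
        mlab <- tolower(mark)
        mc <- simulateRegionCounts(world, config, mark, regions = cons)
        writeCountMatrix(mc$counts, pth(sprintf("%s_counts.tsv", mlab)))
        writeSampleSheet(mc$sampleSheet, pth(sprintf("%s_samples.tsv", mlab)))
        files[[paste0(mlab, "_counts")]] <- pth(sprintf("%s_counts.tsv", mlab))
        files[[paste0(mlab, "_samples")]] <- pth(sprintf("%s_samples.tsv", mlab))
      }
    }
  }

  writeGmt(markerSets(world), pth("marker_sets.gmt"))
  files$marker_sets <- pth("marker_sets.gmt")

  truth <- bedCoords(elements(world))
  utils::write.table(truth, pth("truth_elements.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files$truth_elements <- pth("truth_elements.tsv")

  progs <- data.frame(gene_id = names(genePrograms(world)),
                      program = unname(genePrograms(world)))
  utils::write.table(progs, pth("gene_programs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files$gene_programs <- pth("gene_programs.tsv")

  invisible(files)
}
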