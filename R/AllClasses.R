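#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic multi-omic world: a toy genome, a neuronal
#' gene program downregulated upon co-activator knockout, and regulatory
#' elements whose chromatin signal is a mixture of neuronal and
#' non-neuronal contributions weighted by the neuron fraction of the
#' tissue. Counts are negative binomial with `Var = mu + dispersion * mu^2`.
#'
#' @slot nChromosomes number of chromosomes in the toy genome.
#' @slot chromLength length of each chromosome (bp).
#' @slot nGenes total number of genes.
#' @slot fracNeuronalGenes fraction of genes in the neuronal program
#'   (downregulated in the knockout).
#' @slot fracHousekeeping fraction of housekeeping genes (unchanged).
#' @slot nElementsPerClass regulatory elements per cell-type class
#'   (neuronal, non-neuronal, pancellular).
#' @slot neuronFraction fraction `f` of neurons in the bulk tissue; weights
#'   the neuronal component of chromatin signal mixtures.
#' @slot baselineMean expected RNA count per gene in control (`mu0`).
#' @slot dispersion NB dispersion `alpha` shared across features.
#' @slot koLog2fcNeuronal log2 fold-change applied to neuronal genes in the
#'   knockout (non-positive).
#' @slot nReplicates replicates per genotype.
#' @slot backgroundMean expected count at unbound/closed regions.
#' @slot signalMean expected region count contributed by a fully bound,
#'   fully represented cell population.
#' @slot nUpregulated number of upregulated genes (inflammatory analogue).
#' @slot upLog2fc log2 fold-change of the upregulated set.
#' @slot nSuperEnhancers number of neuronal identity genes carrying an
#'   enhancer cluster (ground-truth super-enhancers).
#' @slot seExpressionBoost multiplicative expression boost of
#'   super-enhancer-linked genes.
#' @slot sizeFactorRange range of the log-uniform per-sample size factors.
#' @slot peakDropout per-replicate probability that a true peak is missed
#'   when emitting replicate peak sets.
#' @slot overlappingGenes if `TRUE`, drop the non-overlap spacing guarantee
#'   (stress-tests closest-gene tie-breaking).
#' @slot seed integer seed; all randomness derives from it.
#'
#' @seealso [simConfig()] for the user constructor with defaults.
#' @export
setClass("SimConfig",
  representation(
    nChromosomes = "integer",
    chromLength = "numeric",
    nGenes = "integer",
    fracNeuronalGenes = "numeric",
    fracHousekeeping = "numeric",
    nElementsPerClass = "integer",
    neuronFraction = "numeric",
    baselineMean = "numeric",
    dispersion = "numeric",
    koLog2fcNeuronal = "numeric",
    nReplicates = "integer",
    backgroundMean = "numeric",
    signalMean = "numeric",
    nUpregulated = "integer",
    upLog2fc = "numeric",
    nSuperEnhancers = "integer",
    seExpressionBoost = "numeric",
    sizeFactorRange = "numeric",
    peakDropout = "numeric",
    overlappingGenes = "logical",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  fr <- c(object@fracNeuronalGenes, object@fracHousekeeping)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "gene program fractions must be in [0, 1]")
  if (sum(fr) > 1) msg <- c(msg, "fracNeuronalGenes + fracHousekeeping must be <= 1")
  if (object@neuronFraction <= 0 || object@neuronFraction >= 1)
    msg <- c(msg, "neuronFraction must be in (0, 1)")
  if (object@baselineMean <= 0) msg <- c(msg, "baselineMean must be > 0")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (object@nReplicates < 2L) msg <- c(msg, "nReplicates must be >= 2")
  if (object@koLog2fcNeuronal > 0) msg <- c(msg, "koLog2fcNeuronal must be <= 0")
  if (object@nChromosomes < 1L) msg <- c(msg, "nChromosomes must be >= 1")
  if (object@nGenes < 0L) msg <- c(msg, "nGenes must be >= 0")
  if (object@nElementsPerClass < 0L) msg <- c(msg, "nElementsPerClass must be >= 0")
  if (object@backgroundMean <= 0) msg <- c(msg, "backgroundMean must be > 0")
  if (object@signalMean <= 0) msg <- c(msg, "signalMean must be > 0")
  if (length(object@sizeFactorRange) != 2L ||
      any(object@sizeFactorRange <= 0) ||
      diff(object@sizeFactorRange) < 0)
    msg <- c(msg, "sizeFactorRange must be an increasing positive pair")
  if (object@peakDropout < 0 || object@peakDropout >= 1)
    msg <- c(msg, "peakDropout must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Toy genome annotation
#'
#' Chromosome lengths plus one gene model per gene: strand-aware TSS, gene
#' body and exons. All in-memory coordinates are 0-based half-open (the BED
#' convention); on-disk GTF is converted on read/write.
#'
#' @slot chromLengths named numeric vector of chromosome lengths (bp).
#' @slot genes `GRanges` of gene bodies with metadata columns `gene_id`
#'   and `tss` (0-based position of the transcription start site;
#'   `tss = start` on `+`, `end - 1` on `-`).
#' @slot exons `GRangesList` of exons, one element per gene, parallel to
#'   `genes`.
#'
#' @seealso [genes()], [chromLengths()], [geneTss()], [readGtfAnnotation()]
#' @export
setClass("GenomeAnnotation",
  representation(
    chromLengths = "numeric",
    genes = "GRanges",
    exons = "CompressedGRangesList"
  )
)

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  g <- object@genes
  if (length(g)) {
    if (is.null(mcols(g)$gene_id)) msg <- c(msg, "genes must carry a gene_id column")
    else if (anyDuplicated(mcols(g)$gene_id)) msg <- c(msg, "gene_id values must be unique")
    if (is.null(mcols(g)$tss)) msg <- c(msg, "genes must carry a tss column")
    cl <- object@chromLengths
    bad <- !(as.character(seqnames(g)) %in% names(cl))
    if (any(bad)) msg <- c(msg, "all genes must lie on known chromosomes")
    else if (any(end(g) > cl[as.character(seqnames(g))] | start(g) < 0))
      msg <- c(msg, "gene bodies must lie within chromosome bounds")
    if (length(object@exons) != length(g))
      msg <- c(msg, "exons must be parallel to genes")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic ground truth
#'
#' The generated world against which recovery is measured: the annotation,
#' the regulatory elements with their true cell-type class
#' (neuronal / non_neuronal / pancellular), element type
#' (promoter / enhancer), target gene and super-enhancer cluster id; the
#' gene program labels; and marker gene sets per simulated cell type.
#'
#' @slot annotation a [GenomeAnnotation-class].
#' @slot elements `GRanges` with metadata columns `element_id`, `class`,
#'   `type`, `target_gene` and `se_cluster` (`NA` for elements outside a
#'   ground-truth super-enhancer cluster).
#' @slot genePrograms named character vector, gene id ->
#'   `neuronal` / `housekeeping` / `other`.
#' @slot markerSets named list of character vectors of gene ids.
#' @slot config the [SimConfig-class] the world was generated from.
#'
#' @seealso [generateTruth()]
#' @export
setClass("TruthWorld",
  representation(
    annotation = "GenomeAnnotation",
    elements = "GRanges",
    genePrograms = "character",
    markerSets = "list",
    config = "SimConfig"
  )
)

setValidity("TruthWorld", function(object) {
  msg <- character()
  el <- object@elements
  if (length(el)) {
    need <- c("element_id", "class", "type", "target_gene")
    miss <- setdiff(need, colnames(mcols(el)))
    if (length(miss))
      msg <- c(msg, paste("elements missing columns:", paste(miss, collapse = ", ")))
    else {
      gid <- mcols(genes(object@annotation))$gene_id
      if (!all(mcols(el)$target_gene %in% gid))
        msg <- c(msg, "every element target_gene must exist in the annotation")
      if (!all(mcols(el)$class %in% c("neuronal", "non_neuronal", "pancellular")))
        msg <- c(msg, "element classes must partition into the three labels")
      if (!all(mcols(el)$type %in% c("promoter", "enhancer")))
        msg <- c(msg, "element types must be promoter or enhancer")
    }
  }
  progs <- object@genePrograms
  if (length(progs) && !all(progs %in% c("neuronal", "housekeeping", "other")))
    msg <- c(msg, "gene programs must be neuronal/housekeeping/other")
  if (length(msg)) msg else TRUE
})
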