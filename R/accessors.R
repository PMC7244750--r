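#' Accessors for annotation and truth objects
#'
#' `genes()` and `exonsByGene()` return the gene bodies (`GRanges`) and the
#' per-gene exon list; `chromLengths()` the named chromosome-length vector;
#' `geneTss()` the named 0-based TSS positions; `elements()`,
#' `genePrograms()`, `markerSets()` and `simConfigOf()` the corresponding
#' slots of a [TruthWorld-class].
#'
#' @param x a [GenomeAnnotation-class] or [TruthWorld-class].
#' @return the slot content; see Details per accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname accessors
#' @export
setMethod("genes", "GenomeAnnotation", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("genes", "TruthWorld", function(x) genes(x@annotation))

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname accessors
#' @export
setMethod("chromLengths", "GenomeAnnotation", function(x) x@chromLengths)

#' @rdname accessors
#' @export
setMethod("chromLengths", "TruthWorld", function(x) chromLengths(x@annotation))

#' @rdname accessors
#' @export
setGeneric("exonsByGene", function(x) standardGeneric("exonsByGene"))

#' @rdname accessors
#' @export
setMethod("exonsByGene", "GenomeAnnotation", function(x) x@exons)

#' @rdname accessors
#' @export
setGeneric("geneTss", function(x) standardGeneric("geneTss"))

#' @rdname accessors
#' @export
setMethod("geneTss", "GenomeAnnotation", function(x) {
  g <- x@genes
  stats::setNames(mcols(g)$tss, mcols(g)$gene_id)
})

#' @rdname accessors
#' @param object a [TruthWorld-class] (for `annotation()`).
#' @param ... ignored.
#' @importFrom BiocGenerics annotation
#' @export
setMethod("annotation", "TruthWorld", function(object, ...) object@annotation)

#' @rdname accessors
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))

#' @rdname accessors
#' @export
setMethod("elements", "TruthWorld", function(x) x@elements)

#' @rdname accessors
#' @export
setGeneric("genePrograms", function(x) standardGeneric("genePrograms"))

#' @rdname accessors
#' @export
setMethod("genePrograms", "TruthWorld", function(x) x@genePrograms)

#' @rdname accessors
#' @export
setGeneric("markerSets", function(x) standardGeneric("markerSets"))

#' @rdname accessors
#' @export
setMethod("markerSets", "TruthWorld", function(x) x@markerSets)

#' @rdname accessors
#' @export
setGeneric("simConfigOf", function(x) standardGeneric("simConfigOf"))

#' @rdname accessors
#' @export
setMethod("simConfigOf", "TruthWorld", function(x) x@config)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat("  genome: ", object@nChromosomes, " chromosome(s) x ",
      format(object@chromLength, big.mark = ","), " bp\n", sep = "")
  cat("  genes: ", object@nGenes,
      " (neuronal ", round(100 * object@fracNeuronalGenes), "%, housekeeping ",
      round(100 * object@fracHousekeeping), "%)\n", sep = "")
  cat("  elements per class: ", object@nElementsPerClass,
      "; neuron fraction f = ", object@neuronFraction, "\n", sep = "")
  cat("  NB: mu0 = ", object@baselineMean, ", dispersion = ",
      object@dispersion, "; KO log2FC (neuronal) = ",
      object@koLog2fcNeuronal, "\n", sep = "")
  cat("  replicates per genotype: ", object@nReplicates,
      "; seed: ", object@seed, "\n", sep = "")
})

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation: ", length(object@chromLengths), " chromosome(s), ",
      length(object@genes), " gene(s)\n", sep = "")
})

setMethod("show", "TruthWorld", function(object) {
  cat("TruthWorld\n")
  show(object@annotation)
  if (length(object@elements)) {
    tab <- table(mcols(object@elements)$class)
    cat("  elements: ", length(object@elements), " (",
        paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  } else cat("  elements: none\n")
  if (length(object@genePrograms)) {
    tab <- table(object@genePrograms)
    cat("  gene programs: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
})
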