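#' Consensus peaks across replicates
#'
#' Replicate-consistency filter standing in for IDR selection: candidate
#' regions are the per-base union of all replicate peaks (bookended runs
#' are contiguous), and a candidate is kept when at least one of its bases
#' is covered by peaks from `minSupport` distinct replicates.
#'
#' @param peakSets list of `GRanges`, one per replicate.
#' @param minSupport required replicate support, `1 <= minSupport <=
#'   length(peakSets)`.
#' @return sorted `GRanges` of consensus regions.
#' @export
consensusPeaks <- function(peakSets, minSupport = 2L) {
  if (!length(peakSets)) .stopf("need at least one replicate peak set")
  if (minSupport < 1L || minSupport > length(peakSets))
    .stopf("minSupport must be between 1 and the number of replicates (%d)",
           length(peakSets))
  # count each replicate at most once per base
  sets <- lapply(peakSets, function(g)
    GenomicRanges::reduce(granges(g), ignore.strand = TRUE))
  all <- unlist(GenomicRanges::GRangesList(sets))
  if (!length(all)) return(GRanges())
  union <- GenomicRanges::reduce(all, ignore.strand = TRUE)
  cov <- GenomicRanges::coverage(all)
  maxSupport <- vapply(seq_along(union), function(i) {
    v <- cov[[as.character(seqnames(union)[i])]]
    max(S4Vectors::runValue(IRanges::Views(
      v, start(union)[i], end(union)[i])[[1]]))
  }, numeric(1))
  sort(GenomeInfoDb::sortSeqlevels(union[maxSupport >= minSupport]))
}

#' Classify co-activator peaks by cell type
#'
#' The core inference of the pipeline: because gene ablation is restricted
#' to neurons, a peak whose binding signal is lost in the knockout but
#' which sits in neuron-accessible chromatin must be neuronal; a peak that
#' persists decomposes by accessibility into pancellular (accessible in
#' sorted neuronal nuclei, hence shared) or non-neuronal (inaccessible in
#' neurons). The decision table over
#' (differential-binding `status`, ATAC overlap):
#'
#' | status | accessible | label        |
#' |--------|------------|--------------|
#' | down   | yes        | neuronal     |
#' | ns     | yes        | pancellular  |
#' | ns     | no         | non_neuronal |
#' | down   | no         | ambiguous    |
#' | up     | any        | ambiguous    |
#'
#' Gained peaks have no class in this framework and are flagged ambiguous.
#'
#' @param peaks `GRanges` of consensus co-activator peaks; a `name` or
#'   `feature` metadata column links them to `kat3Diff$feature`.
#' @param kat3Diff `DiffResult` data.frame (with `status`) from the
#'   knockout-vs-control differential binding test on region counts.
#' @param atacConsensus `GRanges` of consensus accessible regions from
#'   sorted NeuN+ nuclei.
#' @param minOverlap minimum bp overlap to call a peak accessible
#'   (default 1).
#' @return data.frame with columns `feature`, `chrom`, `start`, `end`
#'   (0-based half-open), `status`, `log2FC`, `padj`, `atac`, `label`.
#' @export
classifyKat3Peaks <- function(peaks, kat3Diff, atacConsensus,
                              minOverlap = 1L) {
  ids <- mcols(peaks)$name
  if (is.null(ids)) ids <- mcols(peaks)$feature
  if (is.null(ids)) .stopf("peaks need a name or feature metadata column")
  if (is.null(kat3Diff$status))
    .stopf("kat3Diff must carry a status column (run callSignificant)")
  idx <- match(ids, kat3Diff$feature)
  if (any(is.na(idx)))
    .stopf("%d peak(s) missing a differential result", sum(is.na(idx)))
  status <- as.character(kat3Diff$status[idx])
  accessible <- if (length(atacConsensus))
    IRanges::overlapsAny(peaks, atacConsensus, minoverlap = minOverlap,
                         ignore.strand = TRUE)
  else rep(FALSE, length(peaks))

  label <- rep("ambiguous", length(peaks))
  label[status == "down" & accessible] <- "neuronal"
  label[status == "ns" & accessible] <- "pancellular"
  label[status == "ns" & !accessible] <- "non_neuronal"

  data.frame(feature = ids,
             chrom = as.character(seqnames(peaks)),
             start = start(peaks) - 1L, end = end(peaks),
             status = status,
             log2FC = kat3Diff$log2FC[idx],
             padj = kat3Diff$padj[idx],
             atac = accessible,
             label = label,
             row.names = NULL)
}
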