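#' Interval overlap with a minimum-width requirement
#'
#' Two regions overlap when they share a chromosome and at least `minBp`
#' bases under the 0-based half-open convention (a region ending at `x`
#' does not overlap one starting at `x`).
#'
#' @param a,b `GRanges` of equal length (compared element-wise) or with one
#'   of them of length 1 (recycled).
#' @param minBp minimum overlap width in bp (default 1).
#' @return logical vector.
#' @examples
#' a <- bedRanges("chr1", 0, 100)
#' regionOverlaps(a, bedRanges("chr1", 99, 200))   # TRUE, 1 bp shared
#' regionOverlaps(a, bedRanges("chr1", 100, 200))  # FALSE, half-open
#' @export
regionOverlaps <- function(a, b, minBp = 1L) {
  if (minBp < 1L) .stopf("minBp must be >= 1")
  if (length(a) == 1L) a <- rep(a, length(b))
  if (length(b) == 1L) b <- rep(b, length(a))
  if (length(a) != length(b)) .stopf("a and b must have matching lengths")
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  same & ov >= minBp
}

#' Build a GRanges from 0-based half-open coordinates
#'
#' Convenience constructor mirroring the BED convention used throughout the
#' package; converts to the 1-based closed representation `GRanges` stores.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates (`start < end`).
#' @param ... further metadata columns passed to [GenomicRanges::GRanges()].
#' @return `GRanges`.
#' @export
bedRanges <- function(chrom, start, end, ...) {
  if (any(start < 0) || any(start >= end))
    .stopf("require 0 <= start < end for all intervals")
  GRanges(chrom, IRanges(start + 1, end), ...)
}

#' 0-based half-open coordinates of a GRanges
#'
#' @param gr `GRanges`.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) plus any metadata columns.
#' @export
bedCoords <- function(gr) {
  cbind(
    data.frame(chrom = as.character(seqnames(gr)),
               start = start(gr) - 1L, end = end(gr)),
    as.data.frame(mcols(gr))
  )
}

#' Merge intervals chained by small gaps
#'
#' Stitches together intervals on the same chromosome whenever the gap
#' between them is strictly smaller than `maxGap` ("closer than"),
#' transitively. Overlapping and bookended intervals are always merged.
#' With `maxGap = 5000` this is the 5-kb stitching rule used to aggregate
#' acetylation-marked enhancer regions into candidate super-enhancer
#' domains.
#'
#' @param regions `GRanges`; order irrelevant.
#' @param maxGap non-negative gap threshold in bp; two intervals separated
#'   by a gap `< maxGap` end up in the same output interval.
#' @return sorted, non-overlapping `GRanges`; metadata column `revmap`
#'   lists, per merged interval, the indices of the inputs it contains.
#' @examples
#' gr <- bedRanges("chr1", c(0, 3000), c(1000, 4000))
#' mergeRegions(gr, maxGap = 5000)  # one interval chr1:0-4000
#' @export
mergeRegions <- function(regions, maxGap = 0L) {
  if (maxGap < 0) .stopf("maxGap must be >= 0")
  # reduce() merges ranges whose gap is < min.gapwidth, which is exactly
  # the strict "closer than" rule; maxGap = 0 merges overlapping only
  red <- GenomicRanges::reduce(regions, min.gapwidth = maxGap,
                               with.revmap = TRUE, ignore.strand = TRUE)
  sort(GenomeInfoDb::sortSeqlevels(red))
}

#' Closest gene by TSS distance
#'
#' Assigns each region to the gene whose TSS is nearest to the region
#' midpoint, the standard closest-gene annotation for peaks. Distances are
#' signed by gene strand: negative means the region lies upstream of the
#' TSS. Ties are broken by lexicographically smaller `gene_id` so the
#' result is independent of annotation order.
#'
#' @param regions `GRanges`.
#' @param annotation a [GenomeAnnotation-class].
#' @return data.frame with columns `gene_id` (NA when the chromosome has
#'   no genes), `distance` (signed bp, NA likewise) and `abs_distance`.
#' @export
nearestTss <- function(regions, annotation) {
  g <- genes(annotation)
  gid <- mcols(g)$gene_id
  tss <- mcols(g)$tss
  gchr <- as.character(seqnames(g))
  gstr <- as.character(strand(g))
  mid <- .midpoint(regions)
  rchr <- as.character(seqnames(regions))
  n <- length(regions)
  out <- data.frame(gene_id = rep(NA_character_, n),
                    distance = rep(NA_real_, n),
                    abs_distance = rep(NA_real_, n))
  for (ch in unique(rchr)) {
    sel <- which(gchr == ch)
    ri <- which(rchr == ch)
    if (!length(sel)) next
    # order candidate genes so which.min resolves ties lexicographically
    sel <- sel[order(gid[sel])]
    dmat <- abs(outer(mid[ri], tss[sel], "-"))
    best <- apply(dmat, 1L, which.min)
    bi <- sel[best]
    raw <- mid[ri] - tss[bi]
    signed <- ifelse(gstr[bi] == "-", -raw, raw)
    out$gene_id[ri] <- gid[bi]
    out$distance[ri] <- signed
    out$abs_distance[ri] <- abs(raw)
  }
  out
}

#' Genomic feature of a region
#'
#' Labels each region `promoter`, `exon`, `intron` or `intergenic` from its
#' midpoint, with precedence promoter > exon > intron > intergenic. A
#' midpoint within `promoterWindow` bp of any TSS is a promoter; otherwise
#' membership in an exon, then in a gene body (intron), is tested.
#'
#' @param regions `GRanges`.
#' @param annotation a [GenomeAnnotation-class].
#' @param promoterWindow half-width of the promoter window around the TSS
#'   (bp, default 1000: active-promoter marks concentrate within 1 kb of
#'   the TSS).
#' @return character vector of labels, one per region.
#' @export
annotateFeature <- function(regions, annotation, promoterWindow = 1000L) {
  g <- genes(annotation)
  tss <- mcols(g)$tss
  gchr <- as.character(seqnames(g))
  mid <- .midpoint(regions)
  rchr <- as.character(seqnames(regions))
  n <- length(regions)
  lab <- rep("intergenic", n)
  if (!length(g) || !n) return(lab)

  midGr <- GRanges(rchr, IRanges(mid + 1L, mid + 1L))
  ex <- unlist(exonsByGene(annotation), use.names = FALSE)
  inExon <- if (length(ex))
    IRanges::overlapsAny(midGr, ex, ignore.strand = TRUE) else logical(n)
  inGene <- IRanges::overlapsAny(midGr, g, ignore.strand = TRUE)
  lab[inGene] <- "intron"
  lab[inExon] <- "exon"

  for (ch in unique(rchr)) {
    sel <- which(gchr == ch)
    if (!length(sel)) next
    ri <- which(rchr == ch)
    dmin <- apply(abs(outer(mid[ri], tss[sel], "-")), 1L, min)
    lab[ri[dmin <= promoterWindow]] <- "promoter"
  }
  lab
}
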