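#' Type regions into active promoters and enhancers
#'
#' Distinguishes active promoters from enhancers by H3K4me3/H3K4me1
#' balance and genomic position: a region is an `active_promoter` when its
#' log2 me3/me1 ratio (pseudo-count `c0`) is positive and its feature
#' label is `promoter`; an `enhancer` when the ratio is negative and the
#' feature is `intron` or `intergenic`; anything else is `other`. The two
#' signals must be normalized to a common scale (e.g. counts per million
#' averaged over control samples).
#'
#' @param me3Signal,me1Signal non-negative normalized signal vectors.
#' @param feature genomic feature labels from [annotateFeature()].
#' @param pseudoCount ratio stabilizer `c0` (default 1).
#' @return character vector: `active_promoter` / `enhancer` / `other`.
#' @export
typeRegion <- function(me3Signal, me1Signal, feature, pseudoCount = 1) {
  if (any(me3Signal < 0) || any(me1Signal < 0))
    .stopf("signals must be non-negative")
  lr <- log2((me3Signal + pseudoCount) / (me1Signal + pseudoCount))
  out <- rep("other", length(lr))
  out[lr > 0 & feature == "promoter"] <- "active_promoter"
  out[lr < 0 & feature %in% c("intron", "intergenic")] <- "enhancer"
  out
}

#' Reads per kilobase per million (RPKM)
#'
#' `RPKM = count * 1e9 / (librarySize * lengthBp)`.
#'
#' @param count read count(s).
#' @param lengthBp feature length(s) in bp, positive.
#' @param librarySize total mapped reads, positive.
#' @return numeric RPKM.
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(count, lengthBp, librarySize) {
  if (any(lengthBp <= 0)) .stopf("feature length must be > 0")
  if (any(librarySize <= 0)) .stopf("library size must be > 0")
  count * 1e9 / (librarySize * lengthBp)
}

#' Mean control RPKM per gene
#'
#' Exonic-length RPKM per gene averaged over control samples; the
#' expression measure used by the super-enhancer gate and the
#' length-expression correlation.
#'
#' @param counts gene count matrix.
#' @param sampleSheet matching sample sheet.
#' @param annotation a [GenomeAnnotation-class]; exonic length is the sum
#'   of exon widths (gene-body length where a gene has no exons).
#' @return named numeric vector of RPKM, one per annotation gene present
#'   in `counts`.
#' @export
geneRpkm <- function(counts, sampleSheet, annotation) {
  ctrl <- sampleSheet$genotype == "control"
  g <- genes(annotation)
  gid <- mcols(g)$gene_id
  exw <- sum(width(exonsByGene(annotation)))
  len <- ifelse(exw > 0, exw, width(g))
  keep <- intersect(gid, rownames(counts))
  sub <- counts[keep, ctrl, drop = FALSE]
  lib <- colSums(counts[, ctrl, drop = FALSE])
  perSample <- sapply(seq_len(ncol(sub)), function(j)
    rpkm(sub[, j], len[match(keep, gid)], lib[j]))
  stats::setNames(rowMeans(perSample), keep)
}

#' Stitch enhancers into candidate super-enhancer domains
#'
#' Merges enhancer-typed regions chained by gaps under `stitchGap` (5 kb
#' by default, the stitching distance for acetylation-marked regions)
#' via [mergeRegions()], retaining member indices.
#'
#' @param enhancers `GRanges` of enhancer-typed regions.
#' @param stitchGap gap threshold in bp (strict `<`).
#' @return sorted `GRanges` of stitched domains with metadata columns
#'   `revmap` (member indices into `enhancers`) and `n_members`.
#' @export
stitchEnhancers <- function(enhancers, stitchGap = 5000L) {
  st <- mergeRegions(enhancers, maxGap = stitchGap)
  mcols(st)$n_members <- lengths(mcols(st)$revmap)
  st
}

#' Call super-enhancers
#'
#' Keeps stitched domains longer than `minLength` whose assigned gene
#' (closest TSS to the domain midpoint) has expression at or above
#' `minExpression`. The defaults are the published gates: 5 kb (the length
#' at which expression deviates from the linear length correlation) and
#' 100 RPKM (one order of magnitude above the genome-wide average on the
#' study's data); on small synthetic genomes pass the relative form,
#' `10 * mean(expression)`, instead of the absolute default.
#'
#' @param stitched `GRanges` from [stitchEnhancers()].
#' @param expression named numeric vector, gene id -> RPKM (control mean).
#' @param annotation a [GenomeAnnotation-class].
#' @param minLength minimum domain width in bp, strict `>` (default 5000).
#' @param minExpression minimum assigned-gene expression, `>=`
#'   (default 100).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `length`, `n_members`, `gene`, `expression`. Domains
#'   whose assigned gene lacks an expression value are skipped with a
#'   warning.
#' @export
callSuperEnhancers <- function(stitched, expression, annotation,
                               minLength = 5000L, minExpression = 100) {
  if (!length(stitched))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer(),
                      n_members = integer(), gene = character(),
                      expression = numeric()))
  nt <- nearestTss(stitched, annotation)
  nmem <- if (!is.null(mcols(stitched)$n_members)) mcols(stitched)$n_members
          else rep(NA_integer_, length(stitched))
  df <- data.frame(chrom = as.character(seqnames(stitched)),
                   start = start(stitched) - 1L, end = end(stitched),
                   length = width(stitched), n_members = nmem,
                   gene = nt$gene_id,
                   expression = unname(expression[nt$gene_id]),
                   row.names = NULL)
  noExpr <- !is.na(df$gene) & is.na(df$expression)
  if (any(noExpr))
    warning(sum(noExpr), " stitched region(s) skipped: no expression ",
            "value for the assigned gene", call. = FALSE)
  keep <- !is.na(df$gene) & !noExpr &
    df$length > minLength & df$expression >= minExpression
  df[keep, , drop = FALSE]
}

#' Correlation between stitched-domain length and target expression
#'
#' Pearson and Spearman correlation of stitched enhancer-domain length
#' against the expression of the assigned (closest-TSS) gene.
#'
#' @inheritParams callSuperEnhancers
#' @return list with `pearson`, `spearman`, `n`.
#' @export
lengthExpressionCorrelation <- function(stitched, expression, annotation) {
  nt <- nearestTss(stitched, annotation)
  len <- width(stitched)
  expr <- unname(expression[nt$gene_id])
  ok <- !is.na(nt$gene_id) & !is.na(expr)
  if (sum(ok) < 3L) .stopf("need >= 3 stitched regions with expression")
  list(pearson = stats::cor(len[ok], expr[ok], method = "pearson"),
       spearman = stats::cor(len[ok], expr[ok], method = "spearman"),
       n = sum(ok))
}
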