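#' Distance-decayed regulatory potential
#'
#' Per-gene score summarizing nearby binding: each peak whose midpoint
#' lies within `window` bp of the gene TSS contributes
#' `exp(-(0.5 + 4 * d))`, where `d = |midpoint - TSS| / window`, so a peak
#' at the TSS contributes `exp(-0.5)` and one at the window edge
#' `exp(-4.5)` (the decay kernel of binding-and-expression target
#' analysis).
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param peaks `GRanges` of binding peaks.
#' @param window half-width of the contribution window in bp
#'   (default 1e5).
#' @return data.frame with columns `gene_id`, `score`, `n_peaks`; `score`
#'   is 0 exactly when no peak midpoint falls within the window.
#' @export
regulatoryPotential <- function(annotation, peaks, window = 1e5) {
  if (window <= 0) .stopf("window must be > 0")
  g <- genes(annotation)
  gid <- mcols(g)$gene_id
  out <- data.frame(gene_id = gid, score = 0, n_peaks = 0L)
  if (!length(peaks) || !length(g)) return(out)
  mid <- .midpoint(peaks)
  midGr <- GRanges(seqnames(peaks), IRanges(mid + 1L, mid + 1L))
  tssGr <- GRanges(seqnames(g),
                   IRanges(pmax(1L, mcols(g)$tss + 1L - window),
                           mcols(g)$tss + 1L + window))
  hits <- GenomicRanges::findOverlaps(tssGr, midGr, ignore.strand = TRUE)
  if (!length(hits)) return(out)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  d <- abs(mid[sh] - mcols(g)$tss[qh]) / window
  keep <- d <= 1
  qh <- qh[keep]; d <- d[keep]
  contrib <- exp(-(0.5 + 4 * d))
  sc <- tapply(contrib, qh, sum)
  np <- tapply(contrib, qh, length)
  idx <- as.integer(names(sc))
  out$score[idx] <- as.numeric(sc)
  out$n_peaks[idx] <- as.integer(np)
  out
}

#' Binding-expression association (two-sample KS)
#'
#' Tests whether regulated genes carry systematically larger regulatory
#' potentials than unchanged genes: a one-sided two-sample
#' Kolmogorov-Smirnov test of the score distribution of `down` genes
#' (and of `up` genes) against the `ns` background, oriented so that the
#' regulated class having stochastically larger scores yields a small p.
#'
#' @param scores data.frame from [regulatoryPotential()].
#' @param de `DiffResult` data.frame with `feature` and `status`.
#' @param minClassSize smallest class size for which the test is computed
#'   (default 20); smaller classes are flagged `computed = FALSE`.
#' @param twoSided also report the two-sided p-value.
#' @return data.frame with one row per comparison (`down_vs_ns`,
#'   `up_vs_ns`): `comparison`, `n_regulated`, `n_background`, `D`, `p`,
#'   `computed` (and `p_two_sided` if requested).
#' @export
betaAssociation <- function(scores, de, minClassSize = 20L,
                            twoSided = FALSE) {
  idx <- match(scores$gene_id, de$feature)
  status <- as.character(de$status[idx])
  bg <- scores$score[!is.na(status) & status == "ns"]
  oneSide <- function(cls) {
    x <- scores$score[!is.na(status) & status == cls]
    row <- data.frame(comparison = paste0(cls, "_vs_ns"),
                      n_regulated = length(x), n_background = length(bg),
                      D = NA_real_, p = NA_real_, computed = FALSE)
    if (twoSided) row$p_two_sided <- NA_real_
    if (length(x) < minClassSize || length(bg) < minClassSize) return(row)
    # alternative = "less": the CDF of x lies below that of y, i.e. the
    # regulated scores are stochastically larger than background
    kt <- suppressWarnings(stats::ks.test(x, bg, alternative = "less"))
    row$D <- unname(kt$statistic)
    row$p <- kt$p.value
    row$computed <- TRUE
    if (twoSided)
      row$p_two_sided <- suppressWarnings(
        stats::ks.test(x, bg, alternative = "two.sided"))$p.value
    row
  }
  rbind(oneSide("down"), oneSide("up"))
}

#' Hypergeometric gene-set enrichment
#'
#' Exact upper-tail hypergeometric test for the over-representation of
#' regulated genes in a marker set: with universe size `N`, set size `K`,
#' `n` regulated genes in the universe and `k` of them in the set,
#' `p = P[X >= k]` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param geneSet character vector of gene ids (the marker set).
#' @param regulatedSet character vector of regulated gene ids.
#' @param universe character vector of all tested gene ids.
#' @param de optional `DiffResult` with `status`, used to report the
#'   fraction of the set up- and downregulated.
#' @param setName label for the output row.
#' @return one-row data.frame: `set_name`, `universe_size`, `set_size`,
#'   `regulated_in_universe`, `overlap`, `fraction_up`, `fraction_down`,
#'   `p_hypergeom`, `minus_log10_p`.
#' @export
hypergeomEnrichment <- function(geneSet, regulatedSet, universe, de = NULL,
                                setName = "set") {
  geneSet <- unique(geneSet)
  regulatedSet <- unique(regulatedSet)
  universe <- unique(universe)
  if (!all(geneSet %in% universe))
    .stopf("gene set is not a subset of the universe")
  if (!all(regulatedSet %in% universe))
    .stopf("regulated set is not a subset of the universe")
  N <- length(universe); K <- length(geneSet); n <- length(regulatedSet)
  k <- length(intersect(geneSet, regulatedSet))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fracUp <- fracDown <- NA_real_
  if (!is.null(de) && !is.null(de$status) && K > 0) {
    st <- as.character(de$status[match(geneSet, de$feature)])
    fracUp <- sum(st == "up", na.rm = TRUE) / K
    fracDown <- sum(st == "down", na.rm = TRUE) / K
  }
  data.frame(set_name = setName, universe_size = N, set_size = K,
             regulated_in_universe = n, overlap = k,
             fraction_up = fracUp, fraction_down = fracDown,
             p_hypergeom = p, minus_log10_p = -log10(p),
             row.names = NULL)
}

#' Downregulation / hypoacetylation overlap report
#'
#' Links each hypoacetylated region (differentially lost H3K27ac) to its
#' closest-TSS gene and reports (i) the fraction of downregulated genes
#' with at least one hypoacetylated region assigned, and (ii) the
#' reciprocal fraction of hypoacetylation-assigned genes that are
#' downregulated.
#'
#' @param de RNA `DiffResult` data.frame with `feature` and `status`.
#' @param hypoRegions `GRanges` of regions with significantly reduced
#'   acetylation.
#' @param annotation a [GenomeAnnotation-class].
#' @return list with `frac_down_with_hypo` (i), `frac_hypo_genes_down`
#'   (ii, `NA` when no region maps to a gene), `n_down`,
#'   `n_hypo_genes`.
#' @export
overlapReport <- function(de, hypoRegions, annotation) {
  if (!nrow(de)) .stopf("empty differential expression table")
  downGenes <- de$feature[!is.na(de$status) & de$status == "down"]
  hypoGenes <- if (length(hypoRegions)) {
    nt <- nearestTss(hypoRegions, annotation)
    unique(nt$gene_id[!is.na(nt$gene_id)])
  } else character()
  fracI <- if (length(downGenes))
    mean(downGenes %in% hypoGenes) else NA_real_
  fracII <- if (length(hypoGenes))
    mean(hypoGenes %in% downGenes) else NA_real_
  list(frac_down_with_hypo = fracI,
       frac_hypo_genes_down = fracII,
       n_down = length(downGenes),
       n_hypo_genes = length(hypoGenes))
}
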