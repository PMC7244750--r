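#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over features
#' positive in every sample, of the ratio of each sample's count to the
#' feature's geometric mean, then rescaled to geometric mean 1. This is
#' the standard median-of-ratios normalization for sequencing count
#' matrices.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param pseudoReference if `TRUE`, fall back to an add-1 pseudo-reference
#'   when no feature is positive in all samples (otherwise that situation
#'   is an error).
#' @return positive numeric vector, one factor per sample, geometric
#'   mean 1.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
#' computeSizeFactors(m)  # c(2^-0.5, 2^0.5)
#' @export
computeSizeFactors <- function(counts, pseudoReference = FALSE) {
  if (any(counts < 0)) .stopf("counts must be non-negative")
  if (ncol(counts) < 2L) return(stats::setNames(1, colnames(counts)))
  allPos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allPos)) {
    if (!pseudoReference)
      .stopf(paste("no feature has positive counts in every sample;",
                   "set pseudoReference = TRUE to normalize against an",
                   "add-1 pseudo-reference"))
    work <- counts + 1
    allPos <- rep(TRUE, nrow(work))
  } else work <- counts
  sub <- work[allPos, , drop = FALSE]
  gm <- exp(rowMeans(log(sub)))
  s <- apply(sub / gm, 2, stats::median)
  s <- s / exp(mean(log(s)))
  stats::setNames(s, colnames(counts))
}

#' Negative-binomial differential test (two-group Wald)
#'
#' A self-contained NB differential test for a two-genotype design:
#' counts are normalized by median-of-ratios size factors; the effect is
#' `log2FC = log2((mean_KO + c0) / (mean_ctrl + c0))` with pseudo-count
#' `c0 = 0.5`; a per-feature NB dispersion is estimated by pooled
#' method-of-moments (floored at 1e-8); and the Wald statistic for the
#' log fold-change, with its delta-method standard error under
#' `Var = mu/s + alpha * mu^2`, is referred to a t distribution with
#' `n1 + n2 - 2` degrees of freedom (the small-sample correction keeps
#' the type-I error at its nominal level for the replicate numbers this
#' design uses; see the methods vignette). Equivalence to any published
#' differential-expression tool is not claimed; calibration is
#' established by simulation.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param sampleSheet data.frame with columns `sample` and `genotype`
#'   (`control` / `KO`), rows matching `counts` columns.
#' @param sizeFactors optional known factors; estimated when `NULL`.
#' @param pseudoCount fold-change stabilizer `c0` (default 0.5).
#' @param pseudoReference passed to [computeSizeFactors()].
#' @return data.frame (a `DiffResult` table) with columns `feature`,
#'   `baseMean`, `log2FC`, `p`; `padj` and `status` are added by
#'   [bhAdjust()]/[callSignificant()]. All-zero features get `p = 1`,
#'   `log2FC = 0`.
#' @export
nbTest <- function(counts, sampleSheet, sizeFactors = NULL,
                   pseudoCount = 0.5, pseudoReference = FALSE) {
  if (!all(c("sample", "genotype") %in% names(sampleSheet)))
    .stopf("sampleSheet needs columns sample and genotype")
  if (nrow(sampleSheet) != ncol(counts))
    .stopf("sampleSheet rows must match count matrix columns")
  geno <- sampleSheet$genotype
  if (!all(sort(unique(geno)) == c("control", "KO")) &&
      !setequal(unique(geno), c("control", "KO")))
    .stopf("both genotypes (control, KO) must be present")
  A <- geno == "control"
  B <- geno == "KO"
  if (sum(A) < 2L || sum(B) < 2L)
    .stopf("each genotype needs >= 2 replicates")
  if (nrow(counts) == 0L)
    return(data.frame(feature = character(), baseMean = numeric(),
                      log2FC = numeric(), p = numeric()))

  s <- if (is.null(sizeFactors))
    computeSizeFactors(counts, pseudoReference = pseudoReference) else sizeFactors
  Q <- sweep(counts, 2, s, "/")
  nA <- sum(A); nB <- sum(B)
  mA <- rowMeans(Q[, A, drop = FALSE])
  mB <- rowMeans(Q[, B, drop = FALSE])
  vA <- .rowVars(Q[, A, drop = FALSE])
  vB <- .rowVars(Q[, B, drop = FALSE])
  vpool <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  m <- (nA * mA + nB * mB) / (nA + nB)
  ebar <- (nA * mean(1 / s[A]) + nB * mean(1 / s[B])) / (nA + nB)
  disp <- pmax((vpool - m * ebar) / m^2, 1e-8)
  disp[!is.finite(disp)] <- 1e-8

  c0 <- pseudoCount
  lfc <- log2((mB + c0) / (mA + c0))
  varA <- mA * sum(1 / s[A]) / nA^2 + disp * mA^2 / nA
  varB <- mB * sum(1 / s[B]) / nB^2 + disp * mB^2 / nB
  se2 <- (varA / (mA + c0)^2 + varB / (mB + c0)^2) / log(2)^2
  tstat <- lfc / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df = nA + nB - 2)
  zero <- m == 0
  p[zero] <- 1
  lfc[zero] <- 0
  p[!is.finite(p)] <- 1
  feat <- rownames(counts)
  if (is.null(feat)) feat <- sprintf("feature_%d", seq_len(nrow(counts)))
  data.frame(feature = feat, baseMean = m, log2FC = lfc, p = p,
             row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false-discovery-rate adjustment with monotonicity
#' enforcement, as implemented by [stats::p.adjust()]. Accepts either a
#' p-value vector or a `DiffResult` data.frame (adds/overwrites `padj`).
#'
#' @param p numeric vector of p-values in `[0, 1]`, or a data.frame with a
#'   `p` column.
#' @return same shape as the input, with adjusted values.
#' @export
bhAdjust <- function(p) {
  if (is.data.frame(p)) {
    p$padj <- bhAdjust(p$p)
    return(p)
  }
  if (any(is.na(p)) || any(p < 0 | p > 1))
    .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call significance status
#'
#' Applies the study's deregulation thresholds: a feature is `down` when
#' `padj < alpha` and `log2FC <= -minAbsLfc`, `up` when `padj < alpha` and
#' `log2FC >= minAbsLfc`, otherwise `ns`. The boundary `|log2FC| =
#' minAbsLfc` counts as significant (comparator `">="`, the figure-legend
#' convention); set `comparator = ">"` for the strict variant.
#'
#' @param results `DiffResult` data.frame with `log2FC` and `padj`.
#' @param alpha FDR threshold (default 0.05).
#' @param minAbsLfc minimum absolute log2 fold-change (default 1).
#' @param comparator `">="` (default) or `">"` for the fold-change gate.
#' @return the data.frame with a `status` factor column
#'   (`up` / `down` / `ns`).
#' @export
callSignificant <- function(results, alpha = 0.05, minAbsLfc = 1,
                            comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  if (alpha <= 0 || alpha >= 1) .stopf("alpha must be in (0, 1)")
  if (is.null(results$padj)) .stopf("padj not set; run bhAdjust() first")
  pass <- results$padj < alpha
  hitLfc <- if (comparator == ">=") abs(results$log2FC) >= minAbsLfc
            else abs(results$log2FC) > minAbsLfc
  status <- rep("ns", nrow(results))
  status[pass & hitLfc & results$log2FC < 0] <- "down"
  status[pass & hitLfc & results$log2FC > 0] <- "up"
  results$status <- factor(status, levels = c("up", "down", "ns"))
  results
}

#' One-call differential pipeline stage
#'
#' Convenience wrapper: [nbTest()] then [bhAdjust()] then
#' [callSignificant()]; or, when `externalTable` is supplied (a
#' `DiffResult`-shaped data.frame, e.g. produced by another tool),
#' re-thresholds that table instead of testing.
#'
#' @inheritParams nbTest
#' @inheritParams callSignificant
#' @param externalTable optional pre-computed table with columns
#'   `feature`, `baseMean`, `log2FC`, `p` (and optionally `padj`).
#' @return a complete `DiffResult` data.frame with `padj` and `status`.
#' @export
runDiffTest <- function(counts, sampleSheet, alpha = 0.05, minAbsLfc = 1,
                        comparator = c(">=", ">"), sizeFactors = NULL,
                        pseudoReference = FALSE, externalTable = NULL) {
  comparator <- match.arg(comparator)
  res <- if (!is.null(externalTable)) {
    need <- c("feature", "log2FC", "p")
    miss <- setdiff(need, names(externalTable))
    if (length(miss))
      .stopf("external table missing columns: %s", paste(miss, collapse = ", "))
    externalTable
  } else {
    nbTest(counts, sampleSheet, sizeFactors = sizeFactors,
           pseudoReference = pseudoReference)
  }
  if (is.null(res$padj)) res <- bhAdjust(res)
  callSignificant(res, alpha = alpha, minAbsLfc = minAbsLfc,
                  comparator = comparator)
}
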