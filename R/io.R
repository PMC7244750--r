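#' Read and write annotation, region and count files
#'
#' On-disk conventions follow the field standards: GTF is 1-based
#' inclusive (converted to the package's 0-based half-open in-memory
#' representation on read), regions travel as BED6, counts as TSV with the
#' feature id in the first column and sample ids in the header, sample
#' metadata as a TSV with columns `sample`, `genotype`
#' (`control` / `KO`) and `replicate`, and gene sets as GMT.
#'
#' @param path file path.
#' @param annotation a [GenomeAnnotation-class] (for writers).
#' @name chromident-io
NULL

#' @rdname chromident-io
#' @return `readGtfAnnotation()`: a [GenomeAnnotation-class] built from the
#'   `gene` and `exon` features (attribute `gene_id`). Chromosome lengths
#'   are taken from the GTF's sequence info when present, otherwise from
#'   the rightmost feature per chromosome.
#' @export
readGtfAnnotation <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) {
    sl <- numeric()
    sr <- grep("^##sequence-region", lines, value = TRUE)
    if (length(sr)) {
      parts <- strsplit(sr, "\\s+")
      sl <- stats::setNames(as.numeric(vapply(parts, `[`, "", 4)),
                            vapply(parts, `[`, "", 2))
    }
    return(new("GenomeAnnotation", chromLengths = sl, genes = GRanges(),
               exons = S4Vectors::split(GRanges(), factor())))
  }
  gtf <- rtracklayer::import(path, format = "gtf")
  gg <- gtf[gtf$type == "gene"]
  ee <- gtf[gtf$type == "exon"]
  sl <- GenomeInfoDb::seqlengths(gtf)
  if (all(is.na(sl))) {
    sl <- tapply(end(gtf), as.character(seqnames(gtf)), max)
    sl <- stats::setNames(as.numeric(sl), names(sl))
  }
  ord <- order(mcols(gg)$gene_id)
  gg <- gg[ord]
  str <- as.character(strand(gg))
  genes <- GRanges(seqnames(gg), IRanges(start(gg), end(gg)), strand = str)
  mcols(genes)$gene_id <- mcols(gg)$gene_id
  # 0-based TSS: start of the 0-based half-open body on +, end - 1 on -
  mcols(genes)$tss <- ifelse(str == "-", end(gg) - 1L, start(gg) - 1L)
  exl <- S4Vectors::split(granges(ee), factor(mcols(ee)$gene_id,
                                              levels = mcols(genes)$gene_id))
  new("GenomeAnnotation", chromLengths = sl[unique(as.character(seqnames(gtf)))],
      genes = genes, exons = exl)
}

#' @rdname chromident-io
#' @export
writeGtfAnnotation <- function(annotation, path) {
  g <- genes(annotation)
  if (!length(g)) {
    sl <- chromLengths(annotation)
    writeLines(c("##gff-version 2",
                 sprintf("##sequence-region %s 1 %d", names(sl),
                         as.integer(sl))), path)
    return(invisible(path))
  }
  ex <- unlist(exonsByGene(annotation), use.names = TRUE)
  feats <- c(granges(g), granges(ex))
  mcols(feats)$source <- rep("chromident", length(feats))
  mcols(feats)$type <- c(rep("gene", length(g)), rep("exon", length(ex)))
  mcols(feats)$gene_id <- c(mcols(g)$gene_id, names(ex))
  sl <- chromLengths(annotation)
  GenomeInfoDb::seqlevels(feats) <- names(sl)
  GenomeInfoDb::seqlengths(feats) <- sl
  rtracklayer::export(feats, path, format = "gtf")
  invisible(path)
}

#' @rdname chromident-io
#' @param gr `GRanges` to write; the `name` metadata column populates BED
#'   column 4 and `score` column 5 when present.
#' @return `readBed()`: `GRanges` with `name`/`score` columns when present.
#' @export
readBed <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' @rdname chromident-io
#' @export
writeBed <- function(gr, path) {
  out <- granges(gr)
  mc <- mcols(gr)
  mcols(out)$name <- if (!is.null(mc$name)) mc$name else
    sprintf("region_%d", seq_along(gr))
  mcols(out)$score <- if (!is.null(mc$score)) mc$score else
    rep(0, length(gr))
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' @rdname chromident-io
#' @param counts integer matrix, features x samples, with dimnames.
#' @return `readCountMatrix()`: integer matrix with feature rownames and
#'   sample colnames.
#' @export
readCountMatrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname chromident-io
#' @export
writeCountMatrix <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature", colnames(counts)), collapse = "\t"), con)
  if (nrow(counts))
    utils::write.table(data.frame(feature = rownames(counts), counts,
                                  check.names = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  invisible(path)
}

#' @rdname chromident-io
#' @param sampleSheet data.frame with columns `sample`, `genotype`,
#'   `replicate`.
#' @export
writeSampleSheet <- function(sampleSheet, path) {
  utils::write.table(sampleSheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname chromident-io
#' @return `readSampleSheet()`: data.frame with the three columns above.
#' @export
readSampleSheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample", "genotype", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("sample sheet missing columns: %s", paste(miss, collapse = ", "))
  df
}

#' @rdname chromident-io
#' @param geneSets named list of character vectors.
#' @return `readGmt()`: named list of character vectors.
#' @export
readGmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname chromident-io
#' @export
writeGmt <- function(geneSets, path) {
  lines <- vapply(names(geneSets), function(nm) {
    paste(c(nm, "chromident", geneSets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
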