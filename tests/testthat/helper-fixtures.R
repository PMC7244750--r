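library(GenomicRanges)

# hand-built annotation used by the interval/feature tests:
#   chr1 geneA (+) body [10000, 20000), TSS 10000,
#        exons [10000, 12000) and [15000, 16000)
#   chr1 geneB (-) body [50000, 60000), TSS 59999, exon [58000, 60000)
#   chr2 geneC (+) TSS 10000, geneD (+) TSS 30000 (tie fixture at 20000)
#   chr3 has no genes
tinyAnnotation <- function() {
  g <- GRanges(c("chr1", "chr1", "chr2", "chr2"),
               IRanges(start = c(10001, 50001, 10001, 30001),
                       end = c(20000, 60000, 15000, 35000)),
               strand = c("+", "-", "+", "+"))
  mcols(g)$gene_id <- c("geneA", "geneB", "geneC", "geneD")
  mcols(g)$tss <- c(10000, 59999, 10000, 30000)
  ex <- GRangesList(
    geneA = GRanges("chr1", IRanges(c(10001, 15001), c(12000, 16000))),
    geneB = GRanges("chr1", IRanges(58001, 60000)),
    geneC = GRanges("chr2", IRanges(10001, 11000)),
    geneD = GRanges("chr2", IRanges(30001, 31000)))
  new("GenomeAnnotation",
      chromLengths = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
      genes = g, exons = ex)
}

# a small but complete synthetic world (fast to generate)
smallConfig <- function(seed = 11L, ...) {
  simConfig(nChromosomes = 1L, chromLength = 3e6, nGenes = 40L,
            fracNeuronalGenes = 0.25, fracHousekeeping = 0.25,
            nElementsPerClass = 20L, nSuperEnhancers = 2L,
            seed = seed, ...)
}

randomIntervalSet <- function(n, span = 50000, maxLen = 3000,
                              chroms = c("chrA", "chrB")) {
  s <- sample.int(span, n, replace = TRUE)
  w <- sample.int(maxLen, n, replace = TRUE)
  bedRanges(sample(chroms, n, replace = TRUE), s, s + w)
}

# O(n^2) transitive-closure merge: two intervals end up together iff
# chained by gaps < maxGap (0-based half-open arithmetic)
bruteMerge <- function(gr, maxGap) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   s = start(gr) - 1L, e = end(gr))
  n <- nrow(df)
  if (n == 0) return(df[0, ])
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (df$chrom[i] != df$chrom[j] || grp[i] == grp[j]) next
      gap <- max(df$s[i], df$s[j]) - min(df$e[i], df$e[j])
      if (gap < maxGap) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(split(seq_len(n), grp), function(ix)
    data.frame(chrom = df$chrom[ix[1]], s = min(df$s[ix]),
               e = max(df$e[ix]))))
  out[order(out$chrom, out$s), ]
}

# exhaustive per-base consensus: a base is supported by a replicate when
# any of its peaks covers it; contiguous runs form candidate regions and
# a candidate is kept iff some base reaches minSupport
bruteConsensus <- function(peakSets, minSupport, span = 60000,
                           chroms = c("chrA", "chrB")) {
  out <- list()
  for (ch in chroms) {
    support <- integer(span)
    for (g in peakSets) {
      gg <- g[as.character(seqnames(g)) == ch]
      covered <- logical(span)
      for (i in seq_along(gg))
        covered[seq(start(gg)[i], min(end(gg)[i], span))] <- TRUE
      support[covered] <- support[covered] + 1L
    }
    any1 <- support >= 1L
    r <- rle(any1)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      if (max(support[starts[k]:ends[k]]) >= minSupport)
        out[[length(out) + 1L]] <- data.frame(chrom = ch,
                                              s = starts[k] - 1L,
                                              e = ends[k])
    }
  }
  if (!length(out)) return(data.frame(chrom = character(), s = integer(),
                                      e = integer()))
  df <- do.call(rbind, out)
  df[order(df$chrom, df$s), ]
}

# exhaustive linear-scan nearest TSS with lexicographic tie-break
bruteNearestTss <- function(regions, ann) {
  g <- genes(ann)
  gid <- mcols(g)$gene_id
  tss <- mcols(g)$tss
  gchr <- as.character(seqnames(g))
  mid <- floor((start(regions) - 1 + end(regions)) / 2)
  vapply(seq_along(regions), function(i) {
    sel <- which(gchr == as.character(seqnames(regions)[i]))
    if (!length(sel)) return(NA_character_)
    d <- abs(mid[i] - tss[sel])
    cand <- gid[sel[d == min(d)]]
    sort(cand)[1]
  }, character(1))
}

# hypergeometric upper tail by explicit pmf summation (choose-based)
bruteHyperTail <- function(N, K, n, k) {
  i <- seq(from = k, to = min(K, n))
  if (!length(i) || k > min(K, n)) return(if (k <= 0) 1 else 0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# hypergeometric upper tail by enumeration over all n-subsets (tiny N)
enumHyperTail <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  inSet <- seq_len(K)
  hits <- colSums(matrix(subsets %in% inSet, nrow = n))
  mean(hits >= k)
}

# standard world -> classification run used by recovery checks
classifyWorld <- function(cfg, minSupport = 2L) {
  w <- generateTruth(cfg)
  cons <- consensusPeaks(simulatePeakSets(w, cfg, "KAT3"), minSupport)
  if (length(cons))
    mcols(cons)$name <- sprintf("kat3_peak_%04d", seq_along(cons))
  rc <- simulateRegionCounts(w, cfg, "KAT3", regions = cons)
  kd <- runDiffTest(rc$counts, rc$sampleSheet)
  atacCons <- consensusPeaks(simulatePeakSets(w, cfg, "ATAC"), minSupport)
  cl <- classifyKat3Peaks(cons, kd, atacCons)
  el <- elements(w)
  hits <- findOverlaps(cons, el)
  trueClass <- rep(NA_character_, length(cons))
  trueClass[queryHits(hits)] <- as.character(mcols(el)$class[subjectHits(hits)])
  list(world = w, consensus = cons, classes = cl, trueClass = trueClass,
       accuracy = mean(cl$label[!is.na(trueClass)] ==
                         trueClass[!is.na(trueClass)]))
}

# fixture bundle + pipeline config in temp dirs
makePipelineRun <- function(seed = 5L, outName = "out", ...) {
  cfg <- simConfig(seed = seed)
  w <- generateTruth(cfg)
  fixDir <- file.path(tempdir(), paste0("fix_seed", seed))
  if (!dir.exists(fixDir)) writeFixtures(w, cfg, fixDir)
  files <- list(
    annotation = file.path(fixDir, "annotation.gtf"),
    rnaCounts = file.path(fixDir, "rna_counts.tsv"),
    rnaSamples = file.path(fixDir, "rna_samples.tsv"),
    kat3Regions = file.path(fixDir, "kat3_regions.bed"),
    kat3Counts = file.path(fixDir, "kat3_counts.tsv"),
    kat3Samples = file.path(fixDir, "kat3_samples.tsv"),
    atacPeakSets = file.path(fixDir, sprintf("atac_rep%d.bed", 1:3)),
    h3k27acRegions = file.path(fixDir, "h3k27ac_regions.bed"),
    h3k27acCounts = file.path(fixDir, "h3k27ac_counts.tsv"),
    h3k27acSamples = file.path(fixDir, "h3k27ac_samples.tsv"),
    me1Counts = file.path(fixDir, "h3k4me1_counts.tsv"),
    me3Counts = file.path(fixDir, "h3k4me3_counts.tsv"),
    geneSets = file.path(fixDir, "marker_sets.gmt"))
  cfgArgs <- c(files, list(seed = seed,
                           outDir = file.path(tempdir(), outName)), list(...))
  do.call(pipelineConfig, cfgArgs)
}
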