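test_that("config validation rejects impossible parameters", {
  expect_error(simConfig(fracNeuronalGenes = 1.2), "fractions")
  expect_error(simConfig(baselineMean = -1), "baselineMean")
  expect_error(simConfig(nReplicates = 1), "nReplicates")
  expect_error(simConfig(koLog2fcNeuronal = 0.5), "koLog2fcNeuronal")
  expect_error(simConfig(neuronFraction = 0), "neuronFraction")
})

test_that("an empty gene set yields an empty world and empty matrices", {
  cfg <- simConfig(nGenes = 0L)
  w <- generateTruth(cfg)
  expect_length(genes(w), 0)
  expect_length(elements(w), 0)
  rna <- simulateRnaCounts(w, cfg)
  expect_equal(nrow(rna$counts), 0)
  expect_equal(ncol(rna$counts), 2 * cfg@nReplicates)
})

test_that("gene program and element counts match the configuration", {
  cfg <- simConfig(nGenes = 100L, fracNeuronalGenes = 0.4,
                   fracHousekeeping = 0.2, nElementsPerClass = 110L,
                   seed = 21L)
  w <- generateTruth(cfg)
  progs <- genePrograms(w)
  expect_equal(sum(progs == "neuronal"), 40L)
  expect_equal(sum(progs == "housekeeping"), 20L)
  el <- elements(w)
  expect_equal(unname(sum(mcols(el)$class == "neuronal")), 110L)
  # every neuronal gene carries at least one neuronal element
  neuWith <- unique(mcols(el)$target_gene[mcols(el)$class == "neuronal"])
  expect_true(all(names(progs)[progs == "neuronal"] %in% neuWith))
  # housekeeping genes get pancellular promoter elements
  hkEl <- el[mcols(el)$class == "pancellular" &
               mcols(el)$target_gene %in% names(progs)[progs == "housekeeping"]]
  expect_true(all(mcols(hkEl)$type == "promoter"))
  expect_setequal(unique(mcols(hkEl)$target_gene),
                  names(progs)[progs == "housekeeping"])
  # promoter elements sit within 1 kb of their gene's TSS
  tss <- geneTss(annotation(w))
  prom <- el[mcols(el)$type == "promoter"]
  mid <- floor((start(prom) - 1 + end(prom)) / 2)
  expect_true(all(abs(mid - tss[mcols(prom)$target_gene]) <= 1000))
})

test_that("gene bodies do not overlap and respect the spacing guarantee", {
  w <- generateTruth(smallConfig())
  g <- genes(w)
  g <- g[order(start(g))]
  gaps <- start(g)[-1] - end(g)[-length(g)]
  expect_true(all(gaps >= 10000))
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- smallConfig(seed = 77L)
  w1 <- generateTruth(cfg)
  w2 <- generateTruth(cfg)
  expect_identical(bedCoords(elements(w1)), bedCoords(elements(w2)))
  expect_identical(genePrograms(w1), genePrograms(w2))
  r1 <- simulateRnaCounts(w1, cfg)
  r2 <- simulateRnaCounts(w2, cfg)
  expect_identical(r1$counts, r2$counts)
  k1 <- simulateRegionCounts(w1, cfg, "KAT3")
  k2 <- simulateRegionCounts(w2, cfg, "KAT3")
  expect_identical(k1$counts, k2$counts)
})

test_that("null-effect RNA counts center on the baseline mean", {
  cfg <- simConfig(nChromosomes = 1L, chromLength = 2e6, nGenes = 20L,
                   fracNeuronalGenes = 0.3, fracHousekeeping = 0.3,
                   nElementsPerClass = 10L, nSuperEnhancers = 0L,
                   nUpregulated = 0L, dispersion = 0,
                   koLog2fcNeuronal = 0, nReplicates = 10L, seed = 5L)
  w <- generateTruth(cfg)
  rna <- simulateRnaCounts(w, cfg)
  norm <- sweep(rna$counts, 2, rna$sampleSheet$size_factor, "/")
  mu0 <- cfg@baselineMean
  se <- sqrt(mu0 * mean(1 / rna$sampleSheet$size_factor) / ncol(norm))
  expect_true(all(abs(rowMeans(norm) - mu0) < 3 * se))
})

test_that("KO fold-change on neuronal genes matches the NB mean formula", {
  cfg <- simConfig(nChromosomes = 1L, chromLength = 3e6, nGenes = 40L,
                   fracNeuronalGenes = 0.25, fracHousekeeping = 0.25,
                   nElementsPerClass = 20L, nSuperEnhancers = 2L,
                   koLog2fcNeuronal = -2, nReplicates = 10L,
                   nUpregulated = 0L, seed = 9L)
  w <- generateTruth(cfg)
  rna <- simulateRnaCounts(w, cfg)
  norm <- sweep(rna$counts, 2, rna$sampleSheet$size_factor, "/")
  ctrl <- rna$sampleSheet$genotype == "control"
  progs <- genePrograms(w)
  neu <- rownames(norm) %in% names(progs)[progs == "neuronal"]
  # the ratio of mean KO to mean control counts estimates 2^-2 = 0.25
  # regardless of per-gene baselines, since both genotypes share them
  ratio <- mean(norm[neu, !ctrl]) / mean(norm[neu, ctrl])
  expect_equal(ratio, 0.25, tolerance = 0.08)
})

test_that("control region counts converge to the mixture formula", {
  cfg <- simConfig(nReplicates = 1000L, seed = 13L)
  w <- generateTruth(simConfig(seed = 13L))
  rc <- simulateRegionCounts(w, cfg, "KAT3", nReplicates = 1000L)
  norm <- sweep(rc$counts, 2, rc$sampleSheet$size_factor, "/")
  ctrl <- rc$sampleSheet$genotype == "control"
  el <- elements(w)
  f <- cfg@neuronFraction
  mu <- cfg@signalMean
  bg <- cfg@backgroundMean
  expected <- f * mu * (mcols(el)$class %in% c("neuronal", "pancellular")) +
    (1 - f) * mu * (mcols(el)$class %in% c("non_neuronal", "pancellular")) +
    bg
  relErr <- abs(rowMeans(norm[, ctrl]) - expected) / expected
  expect_lt(max(relErr), 0.05)
})

test_that("the KO removes only the neuronal signal component", {
  # non-neuronal elements: KO mean equals control mean at f = 0.5
  cfg <- simConfig(neuronFraction = 0.5, nReplicates = 400L, seed = 23L)
  w <- generateTruth(simConfig(neuronFraction = 0.5, seed = 23L))
  rc <- simulateRegionCounts(w, cfg, "KAT3", nReplicates = 400L)
  norm <- sweep(rc$counts, 2, rc$sampleSheet$size_factor, "/")
  ctrl <- rc$sampleSheet$genotype == "control"
  cls <- mcols(elements(w))$class
  nn <- cls == "non_neuronal"
  expect_equal(mean(norm[nn, !ctrl]) / mean(norm[nn, ctrl]), 1,
               tolerance = 0.05)

  # neuronal elements at f = 0.8: KO mean collapses to background
  cfg8 <- simConfig(neuronFraction = 0.8, nReplicates = 400L, seed = 23L)
  w8 <- generateTruth(simConfig(neuronFraction = 0.8, seed = 23L))
  rc8 <- simulateRegionCounts(w8, cfg8, "KAT3", nReplicates = 400L)
  norm8 <- sweep(rc8$counts, 2, rc8$sampleSheet$size_factor, "/")
  ctrl8 <- rc8$sampleSheet$genotype == "control"
  neu <- mcols(elements(w8))$class == "neuronal"
  expected <- cfg8@backgroundMean /
    (0.8 * cfg8@signalMean + cfg8@backgroundMean)
  expect_equal(mean(norm8[neu, !ctrl8]) / mean(norm8[neu, ctrl8]),
               expected, tolerance = 0.1 * expected + 0.01)
  expect_error(simulateRegionCounts(w8, cfg8, "RNAPII"), "should be one of")
})

test_that("ATAC signal is restricted to neuron-accessible elements", {
  cfg <- simConfig(seed = 3L)
  w <- generateTruth(cfg)
  rc <- simulateRegionCounts(w, cfg, "ATAC")
  ctrl <- rc$sampleSheet$genotype == "control"
  cls <- mcols(elements(w))$class
  open <- rowMeans(rc$counts[, ctrl])
  expect_gt(min(open[cls == "neuronal"]),
            max(open[cls == "non_neuronal"]))
  expect_gt(min(open[cls == "pancellular"]),
            max(open[cls == "non_neuronal"]))
})

test_that("fixtures round-trip and are byte-stable across runs", {
  cfg <- smallConfig(seed = 31L)
  w <- generateTruth(cfg)
  d1 <- file.path(tempdir(), "fixA")
  d2 <- file.path(tempdir(), "fixB")
  unlink(c(d1, d2), recursive = TRUE)
  writeFixtures(w, cfg, d1)
  writeFixtures(w, cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  ann2 <- readGtfAnnotation(file.path(d1, "annotation.gtf"))
  g1 <- genes(w); g2 <- genes(ann2)
  ord <- match(mcols(g1)$gene_id, mcols(g2)$gene_id)
  expect_equal(start(g1), start(g2)[ord])
  expect_equal(end(g1), end(g2)[ord])
  expect_equal(mcols(g1)$tss, mcols(g2)$tss[ord])
  expect_equal(as.character(strand(g1)), as.character(strand(g2))[ord])
  cm <- readCountMatrix(file.path(d1, "rna_counts.tsv"))
  expect_identical(cm, simulateRnaCounts(w, cfg)$counts)
  gs <- readGmt(file.path(d1, "marker_sets.gmt"))
  expect_equal(gs, markerSets(w))
})

test_that("an empty world still writes valid fixture files", {
  cfg <- simConfig(nGenes = 0L)
  w <- generateTruth(cfg)
  d <- file.path(tempdir(), "fixEmpty")
  unlink(d, recursive = TRUE)
  writeFixtures(w, cfg, d)
  expect_true(file.exists(file.path(d, "rna_counts.tsv")))
  cm <- readCountMatrix(file.path(d, "rna_counts.tsv"))
  expect_equal(nrow(cm), 0)
  expect_equal(ncol(cm), 2 * cfg@nReplicates)
})
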