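test_that("regulatory potential matches its closed-form kernel", {
  ann <- tinyAnnotation()
  # no peaks near geneC/geneD
  none <- regulatoryPotential(ann, GRanges())
  expect_equal(none$score, rep(0, 4))
  expect_equal(none$n_peaks, rep(0L, 4))

  # peak midpoint exactly at geneA's TSS (10000)
  at <- bedRanges("chr1", 9800, 10201)  # midpoint 10000
  rp <- regulatoryPotential(ann, at)
  expect_equal(rp$score[rp$gene_id == "geneA"], exp(-0.5), tolerance = 1e-12)
  # peak at the window edge (100 kb away)
  edge <- bedRanges("chr2", 109800, 110201)  # midpoint 110000, geneC TSS 10000
  rp2 <- regulatoryPotential(ann, edge)
  expect_equal(rp2$score[rp2$gene_id == "geneC"], exp(-4.5), tolerance = 1e-12)
  # just outside the window: zero
  out <- bedRanges("chr2", 110802, 111201)
  rp3 <- regulatoryPotential(ann, out)
  expect_equal(rp3$score[rp3$gene_id == "geneC"], 0)
  expect_error(regulatoryPotential(ann, at, window = 0), "window")
})

test_that("regulatory potential is additive and decays with distance", {
  ann <- tinyAnnotation()
  set.seed(55)
  s <- sample.int(150000, 30)
  peaks <- bedRanges("chr1", s, s + 400)
  half1 <- peaks[1:15]
  half2 <- peaks[16:30]
  tot <- regulatoryPotential(ann, peaks)$score
  expect_equal(tot, regulatoryPotential(ann, half1)$score +
                 regulatoryPotential(ann, half2)$score, tolerance = 1e-12)
  # contribution decreases with |midpoint - TSS|
  d <- seq(0, 9, by = 1) * 1e4
  contrib <- vapply(d, function(dd) {
    p <- bedRanges("chr1", 10000 + dd - 200, 10000 + dd + 201)
    r <- regulatoryPotential(ann, p)
    r$score[r$gene_id == "geneA"]
  }, numeric(1))
  expect_true(all(diff(contrib) < 0))
})

test_that("the KS association is null on identical scores and detects planted shifts", {
  scores <- data.frame(gene_id = paste0("g", 1:120),
                       score = rep(c(0.1, 0.4, 0.7, 1.0), 30))
  de <- data.frame(feature = paste0("g", 1:120),
                   status = factor(rep(c("down", "ns"), each = 60),
                                   levels = c("up", "down", "ns")))
  # down scores are the same multiset as ns scores
  r <- betaAssociation(scores, de)
  dn <- r[r$comparison == "down_vs_ns", ]
  expect_equal(dn$D, 0, tolerance = 1e-12)
  expect_equal(dn$p, 1)
  expect_false(r$computed[r$comparison == "up_vs_ns"])  # no up genes

  # planted: down genes carry systematically larger potentials
  set.seed(66)
  planted <- scores
  planted$score <- c(runif(60, 0.5, 1.5), runif(60, 0, 0.5))
  r2 <- betaAssociation(planted, de)
  expect_lt(r2$p[r2$comparison == "down_vs_ns"], 1e-6)

  # class below the floor is flagged not-computed
  r3 <- betaAssociation(planted, de, minClassSize = 100L)
  expect_false(any(r3$computed))
  expect_true(all(is.na(r3$p)))
})

test_that("hypergeometric enrichment is exact", {
  uni <- paste0("g", 1:4)
  r <- hypergeomEnrichment(uni[1:2], uni[1:2], uni)
  expect_equal(r$p_hypergeom, 1 / 6, tolerance = 1e-12)
  r0 <- hypergeomEnrichment(uni[1:2], character(), uni)
  expect_equal(r0$p_hypergeom, 1)
  expect_error(hypergeomEnrichment(c(uni[1], "gX"), uni[1], uni), "subset")

  set.seed(77)
  for (rep in 1:30) {
    N <- sample(5:60, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    uni <- paste0("u", seq_len(N))
    gs <- sample(uni, K)
    reg <- sample(uni, n)
    p <- hypergeomEnrichment(gs, reg, uni)$p_hypergeom
    k <- length(intersect(gs, reg))
    expect_equal(p, bruteHyperTail(N, K, n, k), tolerance = 1e-12)
    if (N <= 10) expect_equal(p, enumHyperTail(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("enrichment reports regulated fractions per set", {
  de <- data.frame(feature = paste0("g", 1:10),
                   status = factor(c(rep("down", 4), "up", rep("ns", 5)),
                                   levels = c("up", "down", "ns")))
  r <- hypergeomEnrichment(paste0("g", 1:5), paste0("g", 1:5),
                           de$feature, de = de, setName = "demo")
  expect_equal(r$fraction_down, 0.8)
  expect_equal(r$fraction_up, 0.2)
  expect_equal(r$set_name, "demo")
})

test_that("the overlap report computes both fractions and degenerates safely", {
  # ten genes on a simple annotation; eight carry hypoacetylated regions
  g <- GRanges("chr1", IRanges(seq(10001, by = 1e5, length.out = 10),
                               width = 5000), strand = "+")
  mcols(g)$gene_id <- sprintf("g%02d", 1:10)
  mcols(g)$tss <- start(g) - 1L
  ann <- new("GenomeAnnotation", chromLengths = c(chr1 = 2e6), genes = g,
             exons = S4Vectors::split(g, mcols(g)$gene_id))
  de <- data.frame(feature = sprintf("g%02d", 1:10),
                   status = factor(rep("down", 10),
                                   levels = c("up", "down", "ns")))
  hypo <- bedRanges("chr1", mcols(g)$tss[1:8] - 200, mcols(g)$tss[1:8] + 200)
  ov <- overlapReport(de, hypo, ann)
  expect_equal(ov$frac_down_with_hypo, 0.8)
  expect_equal(ov$frac_hypo_genes_down, 1)

  empty <- overlapReport(de, GRanges(), ann)
  expect_equal(empty$frac_down_with_hypo, 0)
  expect_true(is.na(empty$frac_hypo_genes_down))
  expect_error(overlapReport(de[0, ], hypo, ann), "empty")
})
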