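test_that("size factors reproduce the median-of-ratios closed forms", {
  m <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(computeSizeFactors(m)), c(1, 1))

  doubled <- cbind(a = c(10L, 20L, 30L), b = c(20L, 40L, 60L))
  expect_equal(unname(computeSizeFactors(doubled)),
               c(2^-0.5, 2^0.5))

  # scaling one sample scales only its factor; ratios are preserved
  set.seed(1)
  base <- matrix(rpois(300, 50), ncol = 3)
  s1 <- computeSizeFactors(base)
  scaled <- base
  scaled[, 2] <- base[, 2] * 5L
  s2 <- computeSizeFactors(scaled)
  expect_equal(s2[2] / s2[1], 5 * s1[2] / s1[1], tolerance = 1e-12)
})

test_that("size factors error without an all-positive feature unless a pseudo-reference is allowed", {
  m <- matrix(c(0L, 5L, 7L, 0L), ncol = 2)
  expect_error(computeSizeFactors(m), "pseudo-reference")
  s <- computeSizeFactors(m, pseudoReference = TRUE)
  expect_equal(exp(mean(log(s))), 1, tolerance = 1e-12)
})

test_that("nbTest handles null, degenerate and scaled inputs", {
  sheet <- data.frame(sample = paste0("s", 1:6),
                      genotype = rep(c("control", "KO"), each = 3),
                      replicate = rep(1:3, 2))
  flat <- matrix(50L, nrow = 4, ncol = 6,
                 dimnames = list(paste0("f", 1:4), sheet$sample))
  r <- nbTest(flat, sheet)
  expect_equal(r$log2FC, rep(0, 4))
  expect_equal(r$p, rep(1, 4))

  withZero <- flat
  withZero[2, ] <- 0L
  r2 <- nbTest(withZero, sheet)
  expect_equal(r2$p[2], 1)
  expect_equal(r2$log2FC[2], 0)

  # scale invariance after normalization
  set.seed(2)
  m <- matrix(rnbinom(1200, mu = 80, size = 10), ncol = 6,
              dimnames = list(paste0("g", 1:200), sheet$sample))
  r3 <- nbTest(m, sheet)
  m2 <- m
  m2[, 4] <- m[, 4] * 3L
  r4 <- nbTest(m2, sheet)
  # invariance is exact up to the fold-change pseudo-count, which shifts
  # slightly with the normalization's geometric-mean convention
  expect_equal(r3$log2FC, r4$log2FC, tolerance = 0.02)
  expect_equal(r3$p, r4$p, tolerance = 0.02)

  expect_error(nbTest(m, transform(sheet, genotype = "control")),
               "both genotypes")
  expect_error(nbTest(m[, 1:3],
                      data.frame(sample = sheet$sample[1:3],
                                 genotype = c("control", "KO", "KO"))),
               ">= 2 replicates")
})

test_that("nbTest is calibrated under the null and powered at log2FC = -2", {
  set.seed(31)
  n <- 5
  sheet <- data.frame(sample = paste0("s", 1:(2 * n)),
                      genotype = rep(c("control", "KO"), each = n))
  sf <- exp(runif(2 * n, log(0.7), log(1.4)))
  nullCounts <- sapply(seq_len(2 * n), function(j)
    rnbinom(1000, mu = 100 * sf[j], size = 1 / 0.1))
  rownames(nullCounts) <- paste0("g", 1:1000)
  colnames(nullCounts) <- sheet$sample
  rateNull <- mean(nbTest(nullCounts, sheet)$p < 0.05)
  expect_gt(rateNull, 0.02)
  expect_lt(rateNull, 0.09)

  eff <- 1:200
  mix <- sapply(seq_len(2 * n), function(j) {
    mu <- rep(200, 2000)
    if (j > n) mu[eff] <- 200 * 2^-2
    rnbinom(2000, mu = mu * sf[j], size = 1 / 0.05)
  })
  dimnames(mix) <- list(paste0("g", 1:2000), sheet$sample)
  power <- mean(nbTest(mix, sheet)$p[eff] < 0.05)
  expect_gt(power, 0.9)
})

test_that("nbTest fold-changes track an independent NB GLM implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(17)
  n <- 4
  sheet <- data.frame(sample = paste0("s", 1:(2 * n)),
                      genotype = rep(c("control", "KO"), each = n))
  lfcTrue <- c(rep(0, 200), runif(100, -3, 3))
  m <- sapply(seq_len(2 * n), function(j) {
    mu <- 150 * ifelse(rep(j > n, 300), 2^lfcTrue, 1)
    rnbinom(300, mu = mu, size = 1 / 0.05)
  })
  dimnames(m) <- list(paste0("g", 1:300), sheet$sample)
  mine <- nbTest(m, sheet)

  dds <- DESeq2::DESeqDataSetFromMatrix(
    m, S4Vectors::DataFrame(condition = factor(sheet$genotype,
                                               levels = c("control", "KO"))),
    ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  ok <- !is.na(ref$log2FoldChange) & !is.na(ref$pvalue)
  expect_gt(cor(mine$log2FC[ok], ref$log2FoldChange[ok]), 0.95)
  expect_gt(cor(rank(mine$p[ok]), rank(ref$pvalue[ok])), 0.9)
})

test_that("bhAdjust matches the step-up closed form and its bounds", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.123), 0.123)
  set.seed(4)
  p <- runif(500)^2
  adj <- bhAdjust(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= 1))
  perm <- sample(500)
  expect_equal(bhAdjust(p[perm]), adj[perm])
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")

  df <- data.frame(feature = "x", log2FC = 1, p = 0.01)
  expect_equal(bhAdjust(df)$padj, 0.01)
})

test_that("significance calls follow the FDR and fold-change gates", {
  tab <- data.frame(
    feature = paste0("f", 1:5),
    log2FC = c(-1.2, 0.5, -3.0, 1.0, -1.0),
    padj = c(0.04, 0.04, 0.2, 0.04, 0.04))
  st <- callSignificant(tab)
  expect_equal(as.character(st$status),
               c("down", "ns", "ns", "up", "down"))
  # strict comparator drops the |log2FC| = 1 boundary cases
  strict <- callSignificant(tab, comparator = ">")
  expect_equal(as.character(strict$status),
               c("down", "ns", "ns", "ns", "ns"))
  expect_error(callSignificant(tab, alpha = 1.5), "alpha")
  expect_error(callSignificant(tab[, 1:2]), "padj")
})
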