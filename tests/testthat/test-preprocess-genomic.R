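test_that("TPM normalization matches the hand-worked two-gene example", {
  gm <- GenomicMatrix(matrix(c(10, 20), 2, 1,
                             dimnames = list(c("gA", "gB"), "s1")),
                      lengthsKb = c(1, 2))
  out <- normalizeExpression(gm, "TPM")
  expect_equal(prepStage(out), "normalized")
  # rates 10 and 10 per kb rescale to 5e5 each; log2(1 + 5e5) = 18.93157
  expect_equal(unname(gmValues(out)[, 1]),
               rep(log2(1 + 5e5), 2), tolerance = 1e-9)
})

test_that("pre-log TPM columns sum to one million and zeros stay zero", {
  g <- generateCounts(120, 6, seed = 51)
  gm <- GenomicMatrix(g$counts, g$gene_lengths_kb)
  out <- normalizeExpression(gm, "TPM")
  prelog <- 2^gmValues(out) - 1
  expect_equal(unname(colSums(prelog)), rep(1e6, 6), tolerance = 1)
  zeros <- g$counts == 0
  expect_true(all(gmValues(out)[zeros] == 0))
})

test_that("FPKM follows counts * 1e9 / (length_bp * library_size)", {
  counts <- matrix(c(10, 20, 5, 15), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  gm <- GenomicMatrix(counts, lengthsKb = c(1, 2))
  out <- normalizeExpression(gm, "FPKM")
  lib <- colSums(counts)
  expected <- log2(1 + sweep(counts / c(1000, 2000), 2, lib, "/") * 1e9)
  expect_equal(gmValues(out), expected, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a zero-library sample is rejected by name", {
  counts <- matrix(c(1, 2, 0, 0), 2, 2,
                   dimnames = list(NULL, c("good", "empty")))
  gm <- GenomicMatrix(counts, lengthsKb = c(1, 1))
  expect_error(normalizeExpression(gm, "TPM"), "empty")
})

test_that("stage transitions are enforced forward-only", {
  g <- generateCounts(20, 4, seed = 52)
  gm <- GenomicMatrix(g$counts, g$gene_lengths_kb)
  norm <- normalizeExpression(gm, "TPM")
  expect_error(normalizeExpression(norm, "TPM"), "stage")
  expect_error(imputeKnn(gm), "stage")
  expect_error(filterAndStandardize(norm), "stage")
})

test_that("kNN imputation reproduces the closed-form neighbour cases", {
  # no missing values: identity apart from the stage tag
  g <- generateCounts(30, 4, seed = 53)
  norm <- normalizeExpression(GenomicMatrix(g$counts, g$gene_lengths_kb),
                              "TPM")
  same <- imputeKnn(norm, k = 2)
  expect_identical(gmValues(same), gmValues(norm))
  expect_equal(prepStage(same), "imputed")

  # 3 samples, k = 1: C's observed profile equals A and is far from B, so
  # the missing gene in C is filled with A's value
  V <- cbind(A = c(1, 2, 9), B = c(8, 9, 3), C = c(1, 2, NA))
  rownames(V) <- c("g1", "g2", "g3")
  m <- GenomicMatrix(V, lengthsKb = rep(1, 3), stage = "normalized")
  filled <- gmValues(imputeKnn(m, k = 1))
  expect_equal(filled["g3", "C"], 9)

  # k = n_samples - 1: the fill equals the gene's observed mean
  V4 <- cbind(A = c(1, 5), B = c(2, 6), C = c(3, 7), D = c(NA, 8))
  rownames(V4) <- c("g1", "g2")
  m4 <- GenomicMatrix(V4, lengthsKb = c(1, 1), stage = "normalized")
  filled4 <- gmValues(imputeKnn(m4, k = 3))
  expect_equal(filled4["g1", "D"], mean(c(1, 2, 3)))

  # a gene observed nowhere is an error naming the gene
  V5 <- cbind(A = c(1, NA), B = c(2, NA))
  rownames(V5) <- c("ok", "ghost")
  expect_error(imputeKnn(GenomicMatrix(V5, c(1, 1), stage = "normalized")),
               "ghost")
})

test_that("variance filtering applies the quantile rule and z-scores the rest", {
  set.seed(54)
  V <- matrix(rnorm(10 * 8), 10, 8)
  V <- (V - rowMeans(V)) / apply(V, 1, sd) * sqrt(1:10)  # variances 1..10
  rownames(V) <- sprintf("g%02d", 1:10)
  m <- GenomicMatrix(V, rep(1, 10), stage = "imputed")
  out <- filterAndStandardize(m, var_quantile = 0.3)
  expect_equal(prepStage(out), "standardized")
  expect_equal(nrow(out), 7L)                     # 3 lowest variances dropped
  expect_setequal(rownames(out), sprintf("g%02d", 4:10))
  Z <- gmValues(out)
  expect_lt(max(abs(rowMeans(Z))), 1e-9)
  expect_lt(max(abs(apply(Z, 1, sd) - 1)), 1e-9)

  # var_quantile = 0 drops only exact zero-variance genes
  V0 <- rbind(V, flat = rep(1, 8))
  m0 <- GenomicMatrix(V0, rep(1, 11), stage = "imputed")
  out0 <- filterAndStandardize(m0, var_quantile = 0)
  expect_equal(nrow(out0), 10L)
  expect_false("flat" %in% rownames(out0))
})

test_that("held-out samples are standardized with training statistics only", {
  g <- generateCounts(40, 10, seed = 55)
  norm <- imputeKnn(normalizeExpression(
    GenomicMatrix(g$counts, g$gene_lengths_kb), "TPM"), k = 3)
  trainM <- GenomicMatrix(gmValues(norm)[, 1:7], geneLengthsKb(norm),
                          stage = "imputed")
  fitTrain <- filterAndStandardize(trainM, 0.1)
  stats <- S4Vectors::metadata(fitTrain)$standardization
  testM <- GenomicMatrix(gmValues(norm)[, 8:10], geneLengthsKb(norm),
                         stage = "imputed")
  fitTest <- filterAndStandardize(testM, 0.1, stats = stats)
  expect_identical(rownames(fitTest), stats$keep)
  # the transform on held-out samples uses the train means/sds verbatim
  gsel <- stats$keep[1]
  expect_equal(gmValues(fitTest)[gsel, 1],
               unname((gmValues(norm)[gsel, 8] - stats$mean[gsel]) /
                        stats$sd[gsel]))
})

test_that("filtering everything is an error", {
  m <- GenomicMatrix(matrix(1, 3, 4), rep(1, 3), stage = "imputed")
  expect_error(filterAndStandardize(m, 0), "all genes removed")
})
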