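test_that("cohort generation is bit-identical under the same config and seed", {
  cfg <- syntheticConfig(n_patients = 120, seed = 7)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(imgFeatures(a), imgFeatures(b))
  expect_identical(genFeatures(a), genFeatures(b))
  expect_identical(cohortLabels(a), cohortLabels(b))
  expect_identical(siteIds(a), siteIds(b))
  expect_identical(plantedTruth(a), plantedTruth(b))
})

test_that("invalid configurations are rejected with the violated bound named", {
  expect_error(syntheticConfig(n_img_features = 4, n_informative_img = 5),
               "n_informative_img")
  expect_error(syntheticConfig(n_informative_img = 2, n_informative_gen = 1,
                               n_redundant = 4), "n_redundant")
  expect_error(syntheticConfig(missing_rate = 1), "missing_rate")
  expect_error(syntheticConfig(class_balance = 0), "class_balance")
})

test_that("label balance stays inside the binomial 99% interval", {
  for (seed in 1:4) {
    cfg <- syntheticConfig(n_patients = 400, class_balance = 0.4, seed = seed)
    co <- generateCohort(cfg)
    phat <- mean(cohortLabels(co))
    half <- qnorm(0.995) * sqrt(0.4 * 0.6 / 400)
    expect_gt(phat, 0.4 - half)
    expect_lt(phat, 0.4 + half)
  }
})

test_that("redundant features correlate with their parents above 0.8", {
  co <- generateCohort(syntheticConfig(n_patients = 250, n_redundant = 4,
                                       missing_rate = 0, seed = 3))
  red <- plantedTruth(co)$redundant
  expect_equal(nrow(red), 4L)
  for (i in seq_len(nrow(red))) {
    child <- if (red$modality[i] == "img") imgFeatures(co)[, red$index[i]]
             else genFeatures(co)[, red$index[i]]
    parent <- if (red$parentModality[i] == "img")
      imgFeatures(co)[, red$parentIndex[i]]
    else genFeatures(co)[, red$parentIndex[i]]
    expect_gt(abs(cor(child, parent)), 0.8)
  }
})

test_that("missing_rate = 0 leaves the genomic table complete", {
  co <- generateCohort(syntheticConfig(n_patients = 50, missing_rate = 0,
                                       seed = 1))
  expect_false(anyNA(genFeatures(co)))
})

test_that("a null effect gives chance-level discrimination for the planted oracle", {
  aucs <- vapply(1:5, function(seed) {
    co <- generateCohort(syntheticConfig(n_patients = 400, effect_size = 0,
                                         site_shift_sd = 0, missing_rate = 0,
                                         seed = seed))
    planted <- plantedPooled(co)
    score <- rowMeans(pooledCohortTable(co)[, planted, drop = FALSE])
    aucScore(score, cohortLabels(co))
  }, numeric(1))
  # Monte-Carlo interval around 0.5 over independent seeds
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("strong effects put every planted feature at the top of the correlation ranking", {
  co <- generateCohort(syntheticConfig(n_patients = 400, effect_size = 2,
                                       n_redundant = 0, seed = 11))
  X <- pooledCohortTable(co)
  r <- abs(as.vector(cor(X, cohortLabels(co))))
  planted <- plantedPooled(co)
  top <- order(r, decreasing = TRUE)[seq_along(planted)]
  expect_setequal(top, planted)
})

test_that("image patches are label-separated, deterministic, and carry a planted quadratic field", {
  p0 <- generateImagePatch(0, 32, bias = FALSE, seed = 5)
  p1 <- generateImagePatch(1, 32, bias = FALSE, seed = 5)
  expect_gt(mean(p1$patch[p1$mask == 1]), mean(p0$patch[p0$mask == 1]))
  expect_identical(p0$patch, generateImagePatch(0, 32, bias = FALSE, seed = 5)$patch)
  expect_true(all(p0$field == 1))
  # flat-field correction with the true field is the identity
  expect_equal(p0$patch / p0$field, p0$patch, tolerance = 0)
  pb <- generateImagePatch(1, 32, bias = TRUE, seed = 9)
  expect_true(all(pb$field >= 0.7 - 1e-9 & pb$field <= 1.3 + 1e-9))
  # the low-frequency component of the log-intensity recovers the planted
  # quadratic: fitted quadratic surface correlates strongly with log(field)
  xs <- rep((seq_len(32) - 16.5) / 15.5, 32)
  ys <- rep((seq_len(32) - 16.5) / 15.5, each = 32)
  D <- cbind(1, xs, ys, xs^2, xs * ys, ys^2)
  fitted <- D %*% qr.solve(D, as.vector(log(pb$patch)))
  expect_gt(cor(fitted, as.vector(log(pb$field)))^2, 0.5)
  expect_error(generateImagePatch(0, size = 8), ">= 16")
})

test_that("count fixtures are nonnegative, reproducible, with a >= 4x library-size span", {
  g <- generateCounts(300, 8, seed = 2)
  expect_true(all(g$counts >= 0))
  expect_identical(g$counts, generateCounts(300, 8, seed = 2)$counts)
  cs <- colSums(g$counts)
  expect_gte(max(cs) / min(cs), 4)
  expect_true(all(g$gene_lengths_kb >= 0.2 & g$gene_lengths_kb <= 20))
})

test_that("cohort round-trips through the CSV/JSON writer", {
  co <- generateCohort(syntheticConfig(n_patients = 40, seed = 13))
  d <- withr::local_tempdir()
  writeCohort(co, d)
  back <- readCohort(d)
  expect_identical(cohortLabels(back), cohortLabels(co))
  expect_identical(patientIds(back), patientIds(co))
  expect_equal(imgFeatures(back), imgFeatures(co), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(plantedTruth(back)$imgInformative,
               plantedTruth(co)$imgInformative)
})

test_that("the 16-bit PNG writer round-trips through a standard reader", {
  m <- matrix(runif(32 * 20), 32, 20)
  f <- withr::local_tempfile(fileext = ".png")
  writePng16(m, f)
  r <- png::readPNG(f)
  expect_lt(max(abs(r - m)), 1 / 65535)
})
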