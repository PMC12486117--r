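test_that("the hybrid loss reduces to cross-entropy at lambda = 0 and matches ln 2", {
  expect_equal(as.numeric(hybridLoss(0.5, 1, lambda = 0)), log(2),
               tolerance = 1e-12)
  set.seed(81)
  p <- runif(30, 0.01, 0.99); y <- rbinom(30, 1, 0.5)
  l0 <- hybridLoss(p, y, lambda = 0)
  expect_equal(as.numeric(l0), -mean(y * log(p) + (1 - y) * log(1 - p)))
  lpos <- hybridLoss(p, y, lambda = 0.5, M = 10)
  expect_equal(as.numeric(lpos),
               attr(lpos, "ce") + 0.5 * attr(lpos, "softEce"))
  expect_warning(hybridLoss(c(0, 0.5), c(0, 1), lambda = 0), "clamped")
  # perfectly confident correct predictions drive the loss to ~0
  tiny <- hybridLoss(c(1 - 1e-7, 1e-7), c(1, 0), lambda = 0.1)
  expect_lt(as.numeric(tiny), 1e-5)
})

test_that("the soft ECE surrogate tracks the hard ECE within 0.02", {
  for (seed in 82:84) {
    set.seed(seed)
    p <- runif(1000)
    y <- rbinom(1000, 1, if (seed %% 2) p else 0.5)
    soft <- qrgfusion:::.softEce(p, y, 10)$value
    hard <- eceScore(p, y, M = 10)
    expect_lt(abs(soft - hard), 0.02)
  }
})

test_that("analytic loss gradients match central finite differences end to end", {
  set.seed(85)
  arch <- fusionArch(d_in_img = 3, n_gen = 5, h_img = 3, d_img = 3,
                     gen = genomicEncoderConfig(token_size = 3, d_model = 4,
                                                n_heads = 2, n_layers = 1,
                                                d_gen = 3, seed = 1),
                     vqc = vqcConfig(Q = 2, L = 1, seed = 2),
                     h_head = 3, seed = 3)
  params <- modelParams(initFusionModel(arch))
  B <- 4
  Ximg <- matrix(rnorm(B * 3), B, 3)
  Glist <- lapply(1:B, function(i) rnorm(5))
  A <- matrix(runif(B * 2, 0.2, 3), B, 2)
  y <- c(1, 0, 1, 0)
  lossAt <- function(pp) {
    fw <- qrgfusion:::.fusionForward(pp, arch, Ximg, Glist, A)
    as.numeric(hybridLoss(fw$p, y, lambda = 0.3, M = 4))
  }
  fw <- qrgfusion:::.fusionForward(params, arch, Ximg, Glist, A,
                                   keepCache = TRUE)
  dlogit <- qrgfusion:::.hybridLossGradLogit(fw$p, y, 0.3, 4)
  grads <- qrgfusion:::.fusionBackward(params, arch, fw, dlogit)
  eps <- 1e-6
  for (nm in names(params)) {
    x <- params[[nm]]
    idxs <- if (length(x) > 6) sort(sample(length(x), 6)) else seq_along(x)
    for (i in idxs) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
      expect_lt(abs(fd - as.numeric(grads[[nm]])[i]) /
                  max(1e-4, abs(fd)), 1e-4)
    }
  }
})

test_that("fusion head outputs are probabilities with the expected fixed points", {
  head <- list(W1 = matrix(0, 5, 3), b1 = numeric(3),
               W2 = matrix(0, 3, 1), b2 = 0)
  expect_equal(fusePredict(rnorm(2), rnorm(2), rnorm(1), head), 0.5)
  set.seed(86)
  head2 <- list(W1 = matrix(rnorm(15), 5, 3), b1 = rnorm(3),
                W2 = matrix(rnorm(3), 3, 1), b2 = 0.2)
  p1 <- fusePredict(c(1, 2), c(0, 1), 0.5, head2)
  p2 <- fusePredict(c(1, 2), c(0, 1), -0.5, head2)
  expect_true(p1 > 0 && p1 < 1)
  expect_false(isTRUE(all.equal(p1, p2)))   # z_q reaches the logit
  expect_error(fusePredict(c(1, 2, 3), c(0, 1), 0.5, head2), "mismatch")
})

test_that("training reduces the loss and the checkpoint round-trips exactly", {
  co <- generateCohort(syntheticConfig(n_patients = 80, effect_size = 1.5,
                                       seed = 87))
  sp <- patientSplit(co, seed = 87)
  arch <- fusionArch(d_in_img = ncol(imgFeatures(co)),
                     n_gen = ncol(genFeatures(co)),
                     gen = genomicEncoderConfig(token_size = 8, d_model = 8,
                                                n_heads = 2, n_layers = 1,
                                                d_gen = 4, seed = 1),
                     vqc = vqcConfig(Q = 3, L = 1, seed = 2), seed = 3)
  fit <- trainFusion(co, sp, arch = arch,
                     train = trainConfig(max_epochs = 4, patience = 4,
                                         seed = 88),
                     qaoa = qaoaConfig(p = 1, restarts = 2, seed = 89),
                     n_candidates = 8)
  h <- fit$history
  expect_equal(nrow(h), 4L)
  expect_lt(h$train_loss[4], h$train_loss[1])
  expect_true(all(h$val_auc >= 0 & h$val_auc <= 1, na.rm = TRUE))

  f <- withr::local_tempfile(fileext = ".json")
  saveCheckpoint(fit$model, f)
  back <- loadCheckpoint(f)
  pa <- predictFusion(fit$model, co)
  pb <- predictFusion(back, co)
  expect_equal(pa, pb, tolerance = 1e-9)

  # determinism of the whole training path
  fit2 <- trainFusion(co, sp, arch = arch,
                      train = trainConfig(max_epochs = 4, patience = 4,
                                          seed = 88),
                      qaoa = qaoaConfig(p = 1, restarts = 2, seed = 89),
                      n_candidates = 8)
  expect_identical(fit$history, fit2$history)
  expect_identical(modelParams(fit$model), modelParams(fit2$model))
})

test_that("empty splits and leakage-guarded scalers are enforced", {
  co <- generateCohort(syntheticConfig(n_patients = 40, seed = 90))
  sp <- patientSplit(co, seed = 90)
  spBad <- sp; spBad$train <- character(0)
  expect_error(trainFusion(co, spBad), "empty split")
  # the angle scaler is fitted on the training rows only
  X <- matrix(rnorm(50), 10, 5)
  sc <- fitAngleScaler(X[1:6, ])
  expect_equal(sc$min, apply(X[1:6, ], 2, min))
  expect_false(isTRUE(all.equal(sc$min, apply(X, 2, min))))
})
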