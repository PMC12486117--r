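test_that("the angle scaler maps the training range onto [0, pi] and clips", {
  X <- matrix(c(0, 5, 10, 3, 3, 3), ncol = 2)   # second feature constant
  sc <- fitAngleScaler(X)
  A <- scaleToAngles(X, sc)
  expect_equal(A[1, 1], 0)
  expect_equal(A[3, 1], pi)
  expect_equal(A[, 2], rep(pi / 2, 3))
  Anew <- scaleToAngles(matrix(c(-5, 20, 3, 3), ncol = 2), sc)
  expect_equal(Anew[1, 1], 0)       # below training minimum: clipped
  expect_equal(Anew[2, 1], pi)      # above training maximum: clipped
})

test_that("angle encoding produces the expected product states", {
  st <- angleEncode(c(0, 0, 0))
  expect_equal(st[1], complex(real = 1))
  expect_equal(sum(Mod(st[-1])), 0)
  st2 <- angleEncode(c(pi, 0))       # qubit 0 exactly |1>
  expect_equal(Mod(st2[2]), 1, tolerance = 1e-12)
  x <- 1.234
  z <- measureExpectations(angleEncode(x))
  expect_equal(z, cos(x), tolerance = 1e-12)
  expect_error(angleEncode(c(0.5, 3.5)), "\\[0, pi\\]")
  expect_true(all(Re(angleEncode(c(0.3, 2, 3))) >= 0))
})

test_that("the circuit matches a dense gate-matrix oracle at Q = 2, L = 1", {
  cfg <- vqcConfig(Q = 2, L = 1, seed = 31)
  th <- initVqcParams(cfg, sd = 0.7)
  x <- c(0.6, 2.2)
  enc <- kronecker(c(cos(x[2] / 2), sin(x[2] / 2)),
                   c(cos(x[1] / 2), sin(x[1] / 2)))
  U <- denseCnot(2, 1, 0) %*% denseCnot(2, 0, 1) %*%
    denseGate1(2, 1, oracleRZ(th[1, 2, 2]) %*% oracleRY(th[1, 2, 1])) %*%
    denseGate1(2, 0, oracleRZ(th[1, 1, 2]) %*% oracleRY(th[1, 1, 1]))
  oracle <- as.vector(U %*% enc)
  mine <- applyVqc(angleEncode(x), th, cfg)
  expect_lt(max(Mod(oracle - mine)), 1e-8)
})

test_that("identity parameters act as the identity on |0...0>", {
  cfg <- vqcConfig(Q = 3, L = 2)
  th <- array(0, dim = c(2, 3, 2))
  st <- applyVqc(angleEncode(c(0, 0, 0)), th, cfg)
  expect_equal(st[1], complex(real = 1), tolerance = 1e-12)
})

test_that("every circuit application preserves the norm", {
  set.seed(32)
  for (i in 1:8) {
    Q <- sample(1:5, 1); L <- sample(0:3, 1)
    cfg <- vqcConfig(Q = Q, L = L,
                     entangler = sample(c("ring", "line"), 1), seed = i)
    th <- initVqcParams(cfg, sd = 1)
    st <- applyVqc(angleEncode(runif(Q, 0, pi)), th, cfg)
    expect_lt(abs(stateNorm2(st) - 1), 1e-9)
  }
})

test_that("Pauli-Z expectations match the textbook fixtures and stay in [-1, 1]", {
  expect_equal(measureExpectations(angleEncode(c(0, 0))), c(1, 1))
  expect_equal(measureExpectations(uniformState(3)), c(0, 0, 0),
               tolerance = 1e-12)
  bell <- complex(real = c(1, 0, 0, 1)) / sqrt(2)
  expect_equal(measureExpectations(bell), c(0, 0), tolerance = 1e-12)
  expect_error(measureExpectations(complex(real = c(1, 1))), "not normalised")
  set.seed(33)
  for (i in 1:5) {
    cfg <- vqcConfig(Q = 4, L = 3, seed = i)
    z <- quantumEmbed(runif(4, 0, pi), initVqcParams(cfg, sd = 2), cfg)
    expect_true(all(z >= -1 - 1e-12 & z <= 1 + 1e-12))
  }
})

test_that("a depth-0 circuit reduces to the cosine closed form", {
  cfg <- vqcConfig(Q = 4, L = 0)
  x <- c(0.2, 1.1, 2.4, 3.0)
  z <- quantumEmbed(x, array(0, dim = c(0, 4, 2)), cfg)
  expect_equal(z, cos(x), tolerance = 1e-12)
})

test_that("embedding is deterministic and batch/single paths agree", {
  cfg <- vqcConfig(Q = 5, L = 2, seed = 34)
  th <- initVqcParams(cfg)
  A <- matrix(runif(3 * 5, 0, pi), 3, 5)
  Z <- quantumEmbedBatch(A, th, cfg)
  for (i in 1:3)
    expect_equal(Z[i, ], quantumEmbed(A[i, ], th, cfg), tolerance = 1e-12)
  expect_identical(Z, quantumEmbedBatch(A, th, cfg))
})

test_that("parameter-shift gradients match central finite differences", {
  set.seed(35)
  cfg <- vqcConfig(Q = 3, L = 2, entangler = "ring", seed = 35)
  th <- initVqcParams(cfg, sd = 0.5)
  x <- runif(3, 0, pi)
  up <- rnorm(3)
  g <- parameterShiftGrad(x, th, cfg, up)
  eps <- 1e-4
  for (l in 1:2) for (q in 1:3) for (a in 1:2) {
    tp <- th; tp[l, q, a] <- tp[l, q, a] + eps
    tm <- th; tm[l, q, a] <- tm[l, q, a] - eps
    fd <- sum(up * (quantumEmbed(x, tp, cfg) - quantumEmbed(x, tm, cfg))) /
      (2 * eps)
    expect_lt(abs(g[l, q, a] - fd), 1e-4)
  }
  # upstream of zero kills the gradient; a depth-0 circuit has no angles
  expect_equal(parameterShiftGrad(x, th, cfg, c(0, 0, 0)),
               array(0, dim = c(2, 3, 2)))
  expect_equal(dim(parameterShiftGrad(x, array(0, c(0, 3, 2)),
                                      vqcConfig(Q = 3, L = 0), up)),
               c(0L, 3L, 2L))
})

test_that("the adjoint gradient sweep equals the parameter-shift rule", {
  set.seed(36)
  for (ent in c("ring", "line")) for (i in 1:3) {
    Q <- sample(2:5, 1); L <- sample(1:3, 1); B <- sample(1:4, 1)
    cfg <- vqcConfig(Q = Q, L = L, entangler = ent, seed = i)
    th <- initVqcParams(cfg, sd = 0.8)
    A <- matrix(runif(B * Q, 0, pi), B, Q)
    up <- matrix(rnorm(B * Q), B, Q)
    expect_equal(vqcGradAdjoint(A, th, cfg, up),
                 parameterShiftGrad(A, th, cfg, up), tolerance = 1e-10)
  }
})

test_that("a full-width embedding evaluates in well under a second per sample", {
  cfg <- vqcConfig(Q = 10, L = 6, seed = 37)
  th <- initVqcParams(cfg)
  x <- runif(10, 0, pi)
  quantumEmbed(x, th, cfg)  # warm the index caches
  t0 <- Sys.time()
  for (i in 1:3) z <- quantumEmbed(x, th, cfg)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs") / 3, 1)
})
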