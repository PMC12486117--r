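test_that("relevance and redundancy scores follow the correlation conventions", {
  set.seed(1)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  X <- cbind(
    exact = y,                       # perfect point-biserial correlation
    const = rep(2, n),               # constant: defined as 0
    noise = rnorm(n)
  )
  sc <- scoreFeatures(X, y)
  expect_equal(sc$r[1], 1)
  expect_equal(sc$r[2], 0)
  expect_equal(unname(sc$rho[2, ]), c(0, 0, 0))
  expect_equal(diag(sc$rho), c(0, 0, 0), ignore_attr = TRUE)
  expect_true(isSymmetric(unname(sc$rho)))
  expect_error(scoreFeatures(X, rep(1, n)), "single class")
  expect_error(scoreFeatures(cbind(c(NA, rnorm(n - 1))), y), "missing")
})

test_that("noisy duplicates score as redundant pairs", {
  co <- generateCohort(syntheticConfig(n_patients = 300, n_redundant = 3,
                                       missing_rate = 0, seed = 21))
  X <- pooledCohortTable(co)
  sc <- scoreFeatures(X, cohortLabels(co))
  red <- plantedTruth(co)$redundant
  nimg <- ncol(imgFeatures(co))
  for (i in seq_len(nrow(red))) {
    ci <- red$index[i] + if (red$modality[i] == "gen") nimg else 0
    pi <- red$parentIndex[i] + if (red$parentModality[i] == "gen") nimg else 0
    expect_gt(sc$rho[ci, pi], 0.8)
  }
})

test_that("the QUBO expansion reproduces the enumerated worked example", {
  q <- workedQubo()
  costs <- quboCosts(q)
  # bitstrings in basis order 00, 10, 01, 11 (qubit 0 = feature 1 = LSB)
  expect_equal(costs, c(2, -1, -0.5, 0.5))
  expect_equal(quboCost(q, c(1, 0)), -1)
  bf <- bruteForceSelect(q)
  expect_equal(bf$indices, 1L)
  expect_equal(bf$cost, -1)
})

test_that("a separable cost selects exactly the positive-relevance features", {
  r <- c(0.3, 0, 0.8, 0.1)
  q <- buildQubo(list(r = r, rho = matrix(0, 4, 4)), k = 2, alpha = 0,
                 beta = 0)
  bf <- bruteForceSelect(q)
  expect_equal(bf$indices, which(r > 0))
})

test_that("a dominant cardinality penalty forces subsets of size k", {
  set.seed(3)
  rho <- abs(cor(matrix(rnorm(50 * 6), 50, 6))); diag(rho) <- 0
  q <- buildQubo(list(r = runif(6), rho = rho), k = 3, alpha = 1, beta = 50)
  costs <- quboCosts(q)
  sizes <- rowSums(qrgfusion:::bitTable(6))
  near <- which(costs <= min(costs) + 1)
  expect_true(all(sizes[near] == 3))
})

test_that("adding a constant shifts the optimal cost but not the subset", {
  q <- workedQubo()
  q2 <- q; q2@const <- q@const + 5
  a <- bruteForceSelect(q); b <- bruteForceSelect(q2)
  expect_equal(b$indices, a$indices)
  expect_equal(b$cost, a$cost + 5)
})

test_that("zero angles leave the uniform superposition untouched", {
  q <- workedQubo()
  st <- qaoaState(q, c(0, 0), c(0, 0))
  expect_equal(st, rep(complex(real = 0.5), 4), tolerance = 1e-12)
})

test_that("the QAOA state matches a dense matrix-product oracle and stays normalised", {
  q <- workedQubo()
  costs <- quboCosts(q)
  gam <- c(0.37, 1.1); bet <- c(0.81, 0.25)
  U <- diag(4)
  for (j in 1:2) {
    phase <- diag(exp(complex(imaginary = -gam[j] * costs)))
    mixer <- denseGate1(2, 1, oracleRX(2 * bet[j])) %*%
      denseGate1(2, 0, oracleRX(2 * bet[j]))
    U <- mixer %*% phase %*% U
  }
  oracle <- as.vector(U %*% rep(0.5 + 0i, 4))
  mine <- qaoaState(q, gam, bet)
  expect_lt(max(Mod(oracle - mine)), 1e-8)
  set.seed(4)
  for (i in 1:5) {
    st <- qaoaState(q, runif(3, 0, 2 * pi), runif(3, 0, 2 * pi))
    expect_lt(abs(stateNorm2(st) - 1), 1e-9)
  }
})

test_that("cost expectations follow the measurement distribution", {
  q <- workedQubo()
  costs <- quboCosts(q)
  expect_equal(qaoaExpectation(q, qrgfusion::uniformState(2)), mean(costs))
  basis <- complex(real = c(0, 1, 0, 0))
  expect_equal(qaoaExpectation(q, basis), costs[2])
  set.seed(5)
  st <- qaoaState(q, runif(2), runif(2))
  expect_gte(qaoaExpectation(q, st), min(costs) - 1e-12)
})

test_that("angle optimisation beats the uniform start and improves with depth", {
  q <- workedQubo()
  costs <- quboCosts(q)
  opt1 <- optimizeQaoa(q, qaoaConfig(p = 1, restarts = 3, seed = 6))
  expect_lte(opt1$expectation, mean(costs))
  opt2 <- optimizeQaoa(q, qaoaConfig(p = 2, restarts = 3, seed = 6),
                       init = list(gammas = c(opt1$gammas, 0),
                                   betas = c(opt1$betas, 0)))
  expect_lte(opt2$expectation, opt1$expectation + 1e-9)
  # dense-grid scan oracle places the p=2 optimum within 0.05 of the global
  # minimum -1 for this instance
  expect_lt(abs(opt2$expectation - (-1)), 0.05)
  # determinism of the seeded search
  optA <- optimizeQaoa(q, qaoaConfig(p = 2, restarts = 2, seed = 9))
  optB <- optimizeQaoa(q, qaoaConfig(p = 2, restarts = 2, seed = 9))
  expect_identical(optA, optB)
})

test_that("subset extraction honours concentration, mode, and the oracle bound", {
  q <- workedQubo()
  conc <- complex(real = c(0, 1, 0, 0))     # all mass on bitstring 10
  for (mode in c("exact", "sampled")) {
    ss <- sampleSubset(q, conc, qaoaConfig(mode = mode, seed = 2))
    expect_equal(ss$indices, 1L)
  }
  set.seed(8)
  bf <- bruteForceSelect(q)
  for (i in 1:10) {
    st <- qaoaState(q, runif(2, 0, 2 * pi), runif(2, 0, 2 * pi))
    for (mode in c("exact", "sampled")) {
      ss <- sampleSubset(q, st, qaoaConfig(mode = mode, seed = i))
      expect_gte(ss$cost, bf$cost - 1e-12)
    }
  }
})

test_that("brute force refuses oversized problems and ties break lexicographically", {
  big <- new("QuboProblem", n = 21L, h = numeric(21), J = matrix(0, 21, 21),
             const = 0)
  expect_error(bruteForceSelect(big), "n > 20")
  # symmetric two-feature tie: 10 and 01 share the minimum; 01 (bitstring
  # "01" reading feature 1 first) is lexicographically smaller than "10"
  tie <- buildQubo(list(r = c(0.5, 0.5), rho = matrix(0, 2, 2)), k = 1,
                   alpha = 0, beta = 1)
  bf <- bruteForceSelect(tie)
  expect_equal(quboCost(tie, c(1, 0)), quboCost(tie, c(0, 1)))
  expect_equal(bf$bits, c(0, 1))
})

test_that("the QUBO coefficient export round-trips linear and pairwise terms", {
  q <- workedQubo()
  f <- withr::local_tempfile(fileext = ".csv")
  writeQubo(q, f)
  df <- read.csv(f)
  expect_equal(df$coefficient[df$i == 0 & df$j == 0], q@const)
  expect_equal(df$coefficient[df$i == 1 & df$j == 1], q@h[1])
  expect_equal(df$coefficient[df$i == 1 & df$j == 2], q@J[1, 2])
})
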