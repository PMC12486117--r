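# Dense-matrix oracles for the statevector simulator, built independently of
# the implementation: full 2^n x 2^n operators assembled with kronecker
# products (qubit 0 is the least-significant bit, so a gate on qubit q is
# kron(I_high, U, I_low) with I_low of dimension 2^q).

denseGate1 <- function(n, q, U) {
  lowDim <- 2^q
  highDim <- 2^(n - q - 1)
  kronecker(diag(highDim), kronecker(U, diag(lowDim)))
}

denseCnot <- function(n, control, target) {
  d <- 2^n
  M <- matrix(0, d, d)
  for (i in 0:(d - 1)) {
    j <- if (bitwAnd(i, bitwShiftL(1L, control)) > 0L)
      bitwXor(i, bitwShiftL(1L, target)) else i
    M[j + 1, i + 1] <- 1
  }
  M
}

oracleRX <- function(th) matrix(c(cos(th / 2), complex(imaginary = -sin(th / 2)),
                                  complex(imaginary = -sin(th / 2)), cos(th / 2)),
                                2, 2)
oracleRY <- function(th) matrix(c(cos(th / 2), sin(th / 2),
                                  -sin(th / 2), cos(th / 2)), 2, 2)
oracleRZ <- function(th) diag(c(exp(complex(imaginary = -th / 2)),
                                exp(complex(imaginary = th / 2))))

# the two-feature worked QUBO: r = (1, 0.5), no redundancy, k = 1, alpha = 1,
# beta = 2; enumerated costs are 00 -> 2, 10 -> -1, 01 -> -0.5, 11 -> 0.5
workedQubo <- function() {
  buildQubo(list(r = c(1, 0.5), rho = matrix(0, 2, 2)),
            k = 1, alpha = 1, beta = 2)
}

# small standardized cohort table with genomic missing values imputed, plus
# 1-based planted indices into the pooled (imaging then genomic) columns
pooledCohortTable <- function(cohort) {
  X <- cbind(imgFeatures(cohort), genFeatures(cohort))
  if (anyNA(X)) {
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  X
}

plantedPooled <- function(cohort) {
  tr <- plantedTruth(cohort)
  sort(c(tr$imgInformative, tr$genInformative + ncol(imgFeatures(cohort))))
}
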