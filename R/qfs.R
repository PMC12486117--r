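# QAOA feature selection: relevance/redundancy scoring, QUBO construction,
# exact QAOA simulation, derivative-free angle optimisation, measurement-based
# subset extraction, and the exhaustive brute-force oracle.

#' Relevance / redundancy scores for candidate features
#'
#' Computes the filter statistics the selection QUBO is built from:
#' per-feature relevance `r_i = |point-biserial correlation(X_i, y)|` (the
#' Pearson correlation of a feature with the binary label) and pairwise
#' redundancy `rho_ij = |Pearson correlation(X_i, X_j)|`. Any correlation that
#' is 0/0 because a feature is constant is defined as 0.
#'
#' @param X numeric matrix, samples x features, no missing values.
#' @param y binary 0/1 labels; both classes must be present.
#' @return list with `r` (length-p relevance vector in `[0,1]`) and `rho`
#'   (p x p symmetric redundancy matrix, zero diagonal).
#' @export
scoreFeatures <- function(X, y) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values")
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("y contains a single class; relevance is undefined")
  r <- suppressWarnings(abs(as.vector(cor(X, y))))
  r[!is.finite(r)] <- 0
  rho <- suppressWarnings(abs(cor(X)))
  rho[!is.finite(rho)] <- 0
  diag(rho) <- 0
  list(r = r, rho = rho)
}

#' Build the feature-selection QUBO
#'
#' The selection cost over bitstrings z (bit i = feature i selected) is
#' \deqn{cost(z) = -\sum_i r_i z_i + \alpha \sum_{i<j} \rho_{ij} z_i z_j +
#'   \beta (\sum_i z_i - k)^2}
#' i.e. reward relevance, penalise pairwise redundancy, and softly pin the
#' subset size to `k`. Using `z_i^2 = z_i`, the cardinality term expands into
#' the linear and pairwise coefficients exactly.
#'
#' @param scores output of [scoreFeatures()] (or any list with `r`, `rho`).
#' @param k target subset size, `1 <= k <= length(r)`.
#' @param alpha redundancy penalty weight (>= 0). The default 0.25 keeps the
#'   penalty below the relevance scale of a strongly informative feature:
#'   features that all carry the class signal are mutually correlated through
#'   the label itself (about `e^2/4 / (1 + e^2/4)` for a standardized mean
#'   shift `e`), and an `alpha` near 1 would make the optimum avoid selecting
#'   several of them at once.
#' @param beta cardinality penalty weight (>= 0); default `2 * max(r)` so the
#'   size constraint dominates any single relevance gain.
#' @return a [QuboProblem-class].
#' @export
buildQubo <- function(scores, k, alpha = 0.25, beta = NULL) {
  r <- scores$r
  rho <- scores$rho
  n <- length(r)
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= ", n)
  if (is.null(beta)) beta <- 2 * max(r)
  if (alpha < 0 || beta < 0) stop("alpha and beta must be nonnegative")
  h <- -r + beta * (1 - 2 * k)
  J <- alpha * rho + 2 * beta
  J[lower.tri(J, diag = TRUE)] <- 0
  new("QuboProblem", n = as.integer(n), h = as.numeric(h), J = J,
      const = beta * k^2)
}

#' Cost of every basis state of a QUBO
#'
#' @param qubo a [QuboProblem-class] with `n <= 20`.
#' @return numeric vector of length `2^n`; entry `j+1` is the cost of the
#'   bitstring equal to the binary expansion of `j` (bit i = feature i+1).
#' @export
quboCosts <- function(qubo) {
  if (qubo@n > 20L) stop("exact enumeration limited to n <= 20")
  Z <- bitTable(qubo@n)
  as.vector(qubo@const + Z %*% qubo@h + rowSums((Z %*% qubo@J) * Z))
}

#' Cost of one selection bitstring
#' @param qubo a [QuboProblem-class].
#' @param z 0/1 vector of length `n`.
#' @return numeric cost.
#' @export
quboCost <- function(qubo, z) {
  z <- as.numeric(z)
  qubo@const + sum(qubo@h * z) + as.numeric(t(z) %*% qubo@J %*% z)
}

#' QAOA configuration
#'
#' @param p number of alternation layers (default 3, the ablation optimum).
#' @param restarts random restarts of the angle search.
#' @param maxit maximum Nelder-Mead iterations per restart.
#' @param nSamples measurement shots in `"sampled"` mode.
#' @param seed RNG seed for restarts and sampling.
#' @param mode `"exact"` (threshold on exact probabilities) or `"sampled"`.
#' @return validated configuration list.
#' @export
qaoaConfig <- function(p = 3L, restarts = 5L, maxit = 300L,
                       nSamples = 1024L, seed = 1L, mode = c("exact", "sampled")) {
  mode <- match.arg(mode)
  if (p < 1L) stop("p must be >= 1")
  list(p = as.integer(p), restarts = as.integer(restarts),
       maxit = as.integer(maxit), nSamples = as.integer(nSamples),
       seed = as.integer(seed), mode = mode)
}

#' Simulate the QAOA state
#'
#' Starts from the uniform superposition and alternates, for layers
#' j = 1..p, the diagonal cost phase `exp(-i gamma_j cost(z))` applied per
#' basis state with the transverse-field mixer `RX(2 beta_j)` applied to every
#' qubit. Because the cost Hamiltonian is diagonal the phase step is exact; no
#' gate decomposition is needed.
#'
#' @param qubo a [QuboProblem-class] with `n <= 20`.
#' @param gammas,betas numeric angle vectors of equal length p.
#' @param costs optional precomputed [quboCosts()] vector (avoids
#'   recomputation inside optimisation loops).
#' @return complex statevector of length `2^n`.
#' @export
qaoaState <- function(qubo, gammas, betas, costs = NULL) {
  if (length(gammas) != length(betas))
    stop("gammas and betas must have equal length")
  if (is.null(costs)) costs <- quboCosts(qubo)
  n <- qubo@n
  amp <- uniformState(n)
  for (j in seq_along(gammas)) {
    amp <- amp * exp(complex(imaginary = -gammas[j] * costs))
    U <- gateRX(2 * betas[j])
    for (q in 0:(n - 1)) amp <- applyGate1(amp, q, U)
  }
  amp
}

#' Expectation of the QUBO cost in a state
#'
#' `sum_z |amp_z|^2 cost(z)`.
#'
#' @param qubo a [QuboProblem-class].
#' @param state complex statevector of length `2^n`.
#' @param costs optional precomputed cost vector.
#' @return numeric expectation value.
#' @export
qaoaExpectation <- function(qubo, state, costs = NULL) {
  if (is.null(costs)) costs <- quboCosts(qubo)
  if (length(state) != length(costs)) stop("state/cost dimension mismatch")
  sum(Mod(state)^2 * costs)
}

#' Optimise QAOA angles
#'
#' Derivative-free Nelder-Mead search over the 2p angles, with seeded random
#' restarts (gammas and betas initialised uniformly on `[0, 2*pi)`); an
#' optional explicit `init` (e.g. the padded optimum of a shallower circuit)
#' is used as one additional start. Angles are reported modulo `2*pi`.
#'
#' @param qubo a [QuboProblem-class].
#' @param config a [qaoaConfig()].
#' @param init optional list with `gammas`, `betas` used as an extra start.
#' @return list with `gammas`, `betas`, `expectation`, and `evaluations`.
#' @export
optimizeQaoa <- function(qubo, config = qaoaConfig(), init = NULL) {
  costs <- quboCosts(qubo)
  p <- config$p
  fn <- function(par) {
    st <- qaoaState(qubo, par[seq_len(p)], par[p + seq_len(p)], costs = costs)
    sum(Mod(st)^2 * costs)
  }
  starts <- list()
  rng <- localRNG(config$seed)
  for (s in seq_len(config$restarts))
    starts[[s]] <- rng(function() runif(2 * p, 0, 2 * pi))
  if (!is.null(init))
    starts[[length(starts) + 1L]] <- c(init$gammas, init$betas)
  best <- NULL
  nev <- 0L
  for (par0 in starts) {
    fit <- optim(par0, fn, method = "Nelder-Mead",
                 control = list(maxit = config$maxit, reltol = 1e-10))
    nev <- nev + fit$counts[["function"]]
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  ang <- best$par %% (2 * pi)
  list(gammas = ang[seq_len(p)], betas = ang[p + seq_len(p)],
       expectation = best$value, evaluations = nev)
}

# run `expr_fn` under a private RNG stream without disturbing the caller's
# .Random.seed; returns a closure usable repeatedly with the same stream.
localRNG <- function(seed) {
  state <- NULL
  function(expr_fn) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(state)) set.seed(seed) else
      assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (is.null(old)) rm(list = ".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv())
    })
    expr_fn()
  }
}

.bitstringKey <- function(bits) apply(bits, 1L, paste0, collapse = "")

#' Extract a feature subset from a QAOA state
#'
#' In `"sampled"` mode, draws `nSamples` basis outcomes from the measurement
#' distribution and returns the sampled bitstring of minimum cost. In
#' `"exact"` mode, returns the minimum-cost bitstring among all basis states
#' with probability at least `1 / 2^(n+2)`. Cost ties are broken by the
#' lexicographically smallest bitstring (feature 1 first).
#'
#' @param qubo a [QuboProblem-class].
#' @param state QAOA statevector.
#' @param config a [qaoaConfig()].
#' @return list with `indices` (sorted 1-based selected features), `cost`,
#'   `bits`, and `provenance = "qaoa"`.
#' @export
sampleSubset <- function(qubo, state, config = qaoaConfig()) {
  n <- qubo@n
  costs <- quboCosts(qubo)
  probs <- Mod(state)^2
  if (config$mode == "exact") {
    cand <- which(probs >= 1 / 2^(n + 2))
    if (!length(cand)) cand <- which.max(probs)
  } else {
    rng <- localRNG(config$seed)
    draw <- rng(function() sample.int(2^n, config$nSamples, replace = TRUE,
                                      prob = probs))
    cand <- unique(draw)
  }
  bits <- bitTable(n)[cand, , drop = FALSE]
  key <- .bitstringKey(bits)
  ord <- order(costs[cand], key)
  pick <- cand[ord[1L]]
  z <- bitTable(n)[pick, ]
  list(indices = which(z == 1), cost = costs[pick], bits = z,
       provenance = "qaoa")
}

#' Exhaustive QUBO minimisation (verification oracle)
#'
#' Enumerates all `2^n` bitstrings and returns the global minimum, with cost
#' ties broken by the lexicographically smallest bitstring.
#'
#' @param qubo a [QuboProblem-class] with `n <= 20`.
#' @return list with `indices`, `cost`, `bits`, `provenance = "brute_force"`.
#' @export
bruteForceSelect <- function(qubo) {
  if (qubo@n > 20L)
    stop("brute-force enumeration refused for n > 20 (got n = ", qubo@n, ")")
  costs <- quboCosts(qubo)
  best <- min(costs)
  cand <- which(costs <= best + 1e-12)
  bits <- bitTable(qubo@n)[cand, , drop = FALSE]
  pick <- cand[order(.bitstringKey(bits))[1L]]
  z <- bitTable(qubo@n)[pick, ]
  list(indices = which(z == 1), cost = costs[pick], bits = z,
       provenance = "brute_force")
}

#' QAOA feature selection, end to end
#'
#' Convenience wrapper: score features, build the QUBO, optimise the angles,
#' and extract the subset from the optimised state.
#'
#' @param X samples x features matrix (no missing values).
#' @param y binary labels.
#' @param k target subset size.
#' @param alpha,beta QUBO weights, see [buildQubo()].
#' @param config a [qaoaConfig()].
#' @return list with the subset (`indices`, `cost`, `bits`, `provenance`),
#'   the `qubo`, `scores`, and the optimised `angles`.
#' @export
selectFeatures <- function(X, y, k, alpha = 0.25, beta = NULL,
                           config = qaoaConfig()) {
  scores <- scoreFeatures(X, y)
  qubo <- buildQubo(scores, k = k, alpha = alpha, beta = beta)
  opt <- optimizeQaoa(qubo, config)
  state <- qaoaState(qubo, opt$gammas, opt$betas)
  subset <- sampleSubset(qubo, state, config)
  list(indices = subset$indices, cost = subset$cost, bits = subset$bits,
       provenance = subset$provenance, qubo = qubo, scores = scores,
       angles = opt)
}

#' Export a QUBO as a three-column coefficient table
#'
#' Rows with `i == j` carry the linear coefficients `h_i`; rows with `i < j`
#' carry the pairwise coefficients. The constant is attached as a comment-free
#' extra row with `i = j = 0`.
#'
#' @param qubo a [QuboProblem-class].
#' @param path CSV destination.
#' @return the data.frame, invisibly.
#' @export
writeQubo <- function(qubo, path) {
  up <- which(qubo@J != 0, arr.ind = TRUE)
  df <- rbind(
    data.frame(i = 0L, j = 0L, coefficient = qubo@const),
    data.frame(i = seq_len(qubo@n), j = seq_len(qubo@n),
               coefficient = qubo@h),
    if (nrow(up)) data.frame(i = up[, 1], j = up[, 2],
                             coefficient = qubo@J[up])
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
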