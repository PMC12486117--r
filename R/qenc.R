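# Angle encoding and the variational quantum circuit that turns selected
# features into Pauli-Z expectation features z_q. All circuit evaluation is
# exact statevector arithmetic; batched variants operate on a matrix whose
# columns are per-sample statevectors.

#' Variational circuit configuration
#'
#' The ansatz is fixed: per layer, an RY then an RZ rotation on every qubit,
#' followed by CNOT entanglement (ring: control q -> target (q+1) mod Q; line
#' omits the wrap; a single qubit skips entanglement).
#'
#' @param Q qubit count, `1 <= Q <= 14`.
#' @param L layer count, `L >= 0` (`L = 0` means encode-and-measure only).
#' @param entangler `"ring"` or `"line"`.
#' @param seed RNG seed used by [initVqcParams()].
#' @return validated configuration list.
#' @export
vqcConfig <- function(Q = 10L, L = 6L, entangler = c("ring", "line"),
                      seed = 1L) {
  entangler <- match.arg(entangler)
  if (Q < 1L || Q > 14L) stop("Q must satisfy 1 <= Q <= 14")
  if (L < 0L) stop("L must be >= 0")
  list(Q = as.integer(Q), L = as.integer(L), entangler = entangler,
       seed = as.integer(seed))
}

#' Initialise circuit angles
#'
#' Angles are drawn `N(0, sd^2)` from the seeded RNG; small-angle
#' initialisation keeps the circuit near identity, which avoids flat training
#' starts at this scale.
#'
#' @param config a [vqcConfig()].
#' @param sd initial angle scale (default 0.1 rad).
#' @return numeric array of shape `[L, Q, 2]` (RY angle then RZ angle);
#'   a zero-extent array when `L = 0`.
#' @export
initVqcParams <- function(config, sd = 0.1) {
  rng <- localRNG(config$seed)
  th <- rng(function() rnorm(config$L * config$Q * 2L, 0, sd))
  array(th, dim = c(config$L, config$Q, 2L))
}

#' Fit a per-feature angle scaler
#'
#' Records per-feature minimum and maximum on the training split; these are
#' the only statistics [scaleToAngles()] uses, so test data never leak into
#' the scaling.
#'
#' @param X training-split feature matrix (samples x features).
#' @return list with `min` and `max` vectors.
#' @export
fitAngleScaler <- function(X) {
  X <- as.matrix(X)
  list(min = apply(X, 2L, min), max = apply(X, 2L, max))
}

#' Map features to rotation angles
#'
#' `x -> pi * (x - min) / (max - min)`, clipped to `[0, pi]`. A degenerate
#' feature (`max == min` on the training split) maps to `pi/2`.
#'
#' @param X feature matrix (samples x features).
#' @param scaler a fitted [fitAngleScaler()].
#' @return matrix of angles in `[0, pi]`.
#' @export
scaleToAngles <- function(X, scaler) {
  X <- as.matrix(X)
  span <- scaler$max - scaler$min
  A <- sweep(sweep(X, 2L, scaler$min, "-"), 2L, pmax(span, .Machine$double.eps),
             "/") * pi
  A[, span == 0] <- pi / 2
  pmin(pmax(A, 0), pi)
}

#' Angle-encode a feature vector into a product state
#'
#' \deqn{|x\rangle = \bigotimes_i \cos(x_i/2)|0\rangle + \sin(x_i/2)|1\rangle}
#' All amplitudes are real and nonnegative for angles in `[0, pi]`.
#'
#' @param x numeric vector of angles in `[0, pi]` (length Q).
#' @return complex statevector of length `2^Q`.
#' @export
angleEncode <- function(x) {
  if (any(x < -1e-12 | x > pi + 1e-12))
    stop("angles must lie in [0, pi]")
  amp <- complex(real = 1)
  for (xi in x) amp <- c(amp * cos(xi / 2), amp * sin(xi / 2))
  amp
}

# batch variant: columns of the returned 2^Q x B matrix are product states
angleEncodeBatch <- function(A) {
  # A: B x Q matrix of angles
  B <- nrow(A); Q <- ncol(A)
  amp <- matrix(complex(real = 1), nrow = 1L, ncol = B)
  for (q in seq_len(Q)) {
    cq <- cos(A[, q] / 2); sq <- sin(A[, q] / 2)
    amp <- rbind(sweep(amp, 2L, cq, "*"), sweep(amp, 2L, sq, "*"))
  }
  amp
}

#' Apply the variational circuit
#'
#' For each layer, applies `RY(theta[l, q, 1])` then `RZ(theta[l, q, 2])` on
#' every qubit q, followed by the configured CNOT entangler.
#'
#' @param state complex statevector of length `2^Q` (or a `2^Q x B` batch).
#' @param params angle array from [initVqcParams()].
#' @param config a [vqcConfig()].
#' @return evolved state, same shape.
#' @export
applyVqc <- function(state, params, config) {
  Q <- config$Q; L <- config$L
  d <- if (is.matrix(state)) nrow(state) else length(state)
  if (d != 2^Q) stop("state dimension does not match Q")
  if (L > 0 && !all(dim(params) == c(L, Q, 2L)))
    stop("params shape must be [L, Q, 2]")
  if (L == 0L) return(state)
  for (l in seq_len(L)) {
    for (q in seq_len(Q)) {
      state <- applyGate1(state, q - 1L, gateRY(params[l, q, 1L]))
      state <- applyGate1(state, q - 1L, gateRZ(params[l, q, 2L]))
    }
    if (Q > 1L) {
      last <- if (config$entangler == "ring") Q else Q - 1L
      for (q in seq_len(last))
        state <- applyCnot(state, q - 1L, q %% Q)
    }
  }
  state
}

#' Pauli-Z expectations of every qubit
#'
#' `z_q[i] = sum_z |amp_z|^2 * (+1 if bit i of z is 0 else -1)`; every entry
#' lies in `[-1, 1]`.
#'
#' @param state normalised statevector (norm within 1e-6 of 1) or batch
#'   matrix of column statevectors.
#' @return numeric vector of length Q (or a `B x Q` matrix for a batch).
#' @export
measureExpectations <- function(state) {
  nrm <- stateNorm2(state)
  if (any(abs(nrm - 1) > 1e-6))
    stop("state is not normalised (|norm^2 - 1| > 1e-6)")
  n <- nQubits(state)
  S <- 1 - 2 * bitTable(n)           # 2^n x n matrix of +/-1 signs
  if (is.matrix(state)) {
    t(crossprod(S, Mod(state)^2))    # B x Q
  } else {
    as.vector(crossprod(S, Mod(state)^2))
  }
}

#' Quantum feature embedding of one sample
#'
#' Composition `measureExpectations(applyVqc(angleEncode(x)))`; with `L = 0`
#' this reduces to `cos(x)` elementwise.
#'
#' @param x angle vector of length Q (see [scaleToAngles()]).
#' @param params angle array from [initVqcParams()].
#' @param config a [vqcConfig()].
#' @return numeric vector `z_q` of length Q, entries in `[-1, 1]`.
#' @export
quantumEmbed <- function(x, params, config) {
  if (length(x) != config$Q) stop("length(x) must equal Q")
  measureExpectations(applyVqc(angleEncode(x), params, config))
}

#' Quantum embeddings for a batch of samples
#'
#' @param A `B x Q` matrix of angles.
#' @param params,config as in [quantumEmbed()].
#' @return `B x Q` matrix of Pauli-Z expectation features.
#' @export
quantumEmbedBatch <- function(A, params, config) {
  if (ncol(A) != config$Q) stop("ncol(A) must equal Q")
  measureExpectations(applyVqc(angleEncodeBatch(A), params, config))
}

#' Adjoint-mode gradient of the quantum features (fast path)
#'
#' Computes exactly the same gradient as [parameterShiftGrad()] by a reverse
#' sweep over the circuit (adjoint differentiation): the per-sample upstream
#' weights define a diagonal effective observable, and each rotation angle's
#' derivative is read off as `Im(<b| G |psi>)` with `G` the gate generator,
#' unapplying gates one by one. Cost is two gate applications per gate
#' instead of two full circuit evaluations per parameter, which is what makes
#' depth-6, 10-qubit training tractable; equality with the parameter-shift
#' rule is a tested invariant.
#'
#' @param A `B x Q` matrix of encoding angles.
#' @param params angle array `[L, Q, 2]`.
#' @param config a [vqcConfig()].
#' @param upstream `B x Q` loss gradient w.r.t. `z_q`.
#' @return array `[L, Q, 2]` of gradients summed over the batch.
#' @export
vqcGradAdjoint <- function(A, params, config, upstream) {
  L <- config$L; Q <- config$Q
  grad <- array(0, dim = c(L, Q, 2L))
  if (L == 0L) return(grad)
  if (!is.matrix(A)) A <- matrix(A, nrow = 1L)
  if (!is.matrix(upstream)) upstream <- matrix(upstream, nrow = 1L)
  psi <- applyVqc(angleEncodeBatch(A), params, config)
  S <- 1 - 2 * bitTable(Q)                  # 2^Q x Q signs
  D <- S %*% t(upstream)                    # diagonal observable per sample
  # z_q = psi^dagger Z_q psi, so dLoss/dpsi* = 2 * D * psi / ... handled via
  # b = D * psi and grad_k = 2 * Im(<b| G/2 |psi_k>) = Im(<b| G |psi_k>)
  b <- D * psi
  GY <- matrix(c(0, complex(imaginary = 1), complex(imaginary = -1), 0), 2, 2)
  lastE <- if (config$entangler == "ring") Q else Q - 1L
  for (l in rev(seq_len(L))) {
    if (Q > 1L) {
      for (q in rev(seq_len(lastE))) {
        psi <- applyCnot(psi, q - 1L, q %% Q)
        b <- applyCnot(b, q - 1L, q %% Q)
      }
    }
    for (q in rev(seq_len(Q))) {
      # RZ then RY in reverse; the RZ generator Z is diagonal +1/-1
      sgn <- 1 - 2 * bitTable(Q)[, q]
      Gpsi <- psi * sgn
      grad[l, q, 2L] <- sum(Im(Conj(b) * Gpsi))
      Uinv <- gateRZ(-params[l, q, 2L])
      psi <- applyGate1(psi, q - 1L, Uinv)
      b <- applyGate1(b, q - 1L, Uinv)
      GpsiY <- applyGate1(psi, q - 1L, GY)
      grad[l, q, 1L] <- sum(Im(Conj(b) * GpsiY))
      UinvY <- gateRY(-params[l, q, 1L])
      psi <- applyGate1(psi, q - 1L, UinvY)
      b <- applyGate1(b, q - 1L, UinvY)
    }
  }
  grad
}

#' Parameter-shift gradient of the quantum features
#'
#' For each circuit angle `theta_k`, `d z_q / d theta_k` is evaluated exactly
#' by the parameter-shift rule `(z_q(theta_k + pi/2) - z_q(theta_k - pi/2))/2`
#' (valid for the RY/RZ generators used here), then contracted with the
#' upstream loss gradient.
#'
#' @param x angle vector of length Q (one sample), or a `B x Q` matrix.
#' @param params angle array `[L, Q, 2]`.
#' @param config a [vqcConfig()].
#' @param upstream loss gradient w.r.t. `z_q`: length-Q vector (or `B x Q`).
#' @return array of shape `[L, Q, 2]` with the chained gradient (summed over
#'   the batch when inputs are matrices).
#' @export
parameterShiftGrad <- function(x, params, config, upstream) {
  L <- config$L; Q <- config$Q
  grad <- array(0, dim = c(L, Q, 2L))
  if (L == 0L) return(grad)
  A <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  U <- if (is.matrix(upstream)) upstream else matrix(upstream, nrow = 1L)
  enc <- angleEncodeBatch(A)
  for (l in seq_len(L)) for (q in seq_len(Q)) for (a in 1:2) {
    for (s in c(1, -1)) {
      shifted <- params
      shifted[l, q, a] <- shifted[l, q, a] + s * pi / 2
      z <- measureExpectations(applyVqc(enc, shifted, config))
      grad[l, q, a] <- grad[l, q, a] + s * sum(U * z) / 2
    }
  }
  grad
}
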