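# Exact statevector simulation primitives shared by the QAOA feature-selection
# and variational-circuit encoding code. A statevector is a plain complex
# vector of length 2^n (or a 2^n x B matrix for a batch of states); qubit 0 is
# the least-significant bit of the basis index, so amplitude j+1 belongs to the
# basis state whose bit q equals bit q of the integer j.

#' Number of qubits of a statevector
#' @param state complex vector of length `2^n` or a `2^n x B` matrix.
#' @return integer n.
#' @export
nQubits <- function(state) {
  d <- if (is.matrix(state)) nrow(state) else length(state)
  n <- as.integer(round(log2(d)))
  if (2^n != d) stop("state length is not a power of two")
  n
}

#' Uniform superposition state |+>^n
#' @param n qubit count.
#' @return complex vector of length `2^n` with all amplitudes `2^(-n/2)`.
#' @export
uniformState <- function(n) rep(complex(real = 2^(-n / 2)), 2^n)

# 0/1 bit matrix: row j+1 holds the bits of integer j, column q = bit q (LSB
# first). Cached per n because it is hit in every expectation evaluation.
.bitCache <- new.env(parent = emptyenv())
bitTable <- function(n) {
  key <- as.character(n)
  if (!is.null(.bitCache[[key]])) return(.bitCache[[key]])
  j <- 0:(2^n - 1)
  B <- vapply(0:(n - 1), function(q) bitwAnd(bitwShiftR(j, q), 1L),
              integer(2^n))
  B <- matrix(as.numeric(B), nrow = 2^n)
  .bitCache[[key]] <- B
  B
}

#' Apply a single-qubit gate to a statevector
#'
#' Applies the 2x2 unitary `U` to qubit `q` (0-based) of `state`, which may be
#' a single statevector or a matrix whose columns are statevectors (the gate is
#' applied to every column). Implemented by reshaping so the target qubit's two
#' subspaces are contiguous slabs; no 2^n x 2^n matrix is ever formed.
#'
#' @param state complex vector `2^n` or matrix `2^n x B`.
#' @param q target qubit, `0 <= q < n`.
#' @param U complex 2x2 matrix.
#' @return state of the same shape.
#' @export
applyGate1 <- function(state, q, U) {
  mat <- is.matrix(state)
  d <- if (mat) nrow(state) else length(state)
  n <- as.integer(round(log2(d)))
  if (q < 0 || q >= n) stop("qubit index out of range")
  ic <- .gateIdx(n, q)
  if (mat) {
    a0 <- state[ic$i0, , drop = FALSE]
    a1 <- state[ic$i1, , drop = FALSE]
    state[ic$i0, ] <- U[1, 1] * a0 + U[1, 2] * a1
    state[ic$i1, ] <- U[2, 1] * a0 + U[2, 2] * a1
  } else {
    a0 <- state[ic$i0]
    a1 <- state[ic$i1]
    state[ic$i0] <- U[1, 1] * a0 + U[1, 2] * a1
    state[ic$i1] <- U[2, 1] * a0 + U[2, 2] * a1
  }
  state
}

# cached index pairs splitting the basis by the value of bit q
.gateIdxCache <- new.env(parent = emptyenv())
.gateIdx <- function(n, q) {
  key <- paste(n, q, sep = ":")
  ic <- .gateIdxCache[[key]]
  if (!is.null(ic)) return(ic)
  j <- 0:(2^n - 1)
  hot <- bitwAnd(j, bitwShiftL(1L, q)) > 0L
  ic <- list(i0 = which(!hot), i1 = which(hot))
  .gateIdxCache[[key]] <- ic
  ic
}

#' Apply a CNOT gate
#'
#' @param state complex vector `2^n` or matrix of column statevectors.
#' @param control,target 0-based qubit indices, distinct.
#' @return state of the same shape.
#' @export
applyCnot <- function(state, control, target) {
  mat <- is.matrix(state)
  d <- if (mat) nrow(state) else length(state)
  n <- as.integer(round(log2(d)))
  if (control == target) stop("control and target must differ")
  if (max(control, target) >= n || min(control, target) < 0)
    stop("qubit index out of range")
  perm <- cnotPerm(n, control, target)
  if (mat) state[perm, , drop = FALSE] else state[perm]
}

.permCache <- new.env(parent = emptyenv())
cnotPerm <- function(n, control, target) {
  key <- paste(n, control, target, sep = ":")
  if (!is.null(.permCache[[key]])) return(.permCache[[key]])
  j <- 0:(2^n - 1)
  src <- ifelse(bitwAnd(j, bitwShiftL(1L, control)) > 0L,
                bitwXor(j, bitwShiftL(1L, target)), j)
  .permCache[[key]] <- src + 1L
  src + 1L
}

# Rotation gate matrices. RX(theta) = exp(-i theta X / 2), etc.
gateRX <- function(theta) {
  c <- cos(theta / 2); s <- sin(theta / 2)
  matrix(c(complex(real = c), complex(imaginary = -s),
           complex(imaginary = -s), complex(real = c)), 2, 2)
}
gateRY <- function(theta) {
  c <- cos(theta / 2); s <- sin(theta / 2)
  matrix(complex(real = c(c, s, -s, c)), 2, 2)
}
gateRZ <- function(theta) {
  matrix(c(exp(complex(imaginary = -theta / 2)), 0, 0,
           exp(complex(imaginary = theta / 2))), 2, 2)
}

#' Squared-magnitude norm of a statevector
#' @param state complex vector or matrix of column statevectors.
#' @return numeric scalar (or per-column vector) `sum(|amp|^2)`.
#' @export
stateNorm2 <- function(state) {
  if (is.matrix(state)) colSums(Mod(state)^2) else sum(Mod(state)^2)
}
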