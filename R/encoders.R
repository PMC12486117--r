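# Classical modality encoders. The genomic encoder is a compact transformer
# (token projection + sinusoidal positions + multi-head self-attention +
# feed-forward blocks with residual connections and layer normalisation,
# mean-pooled, linearly mapped to d_gen); forward and reverse passes are
# written out explicitly since no autodiff framework is involved. The image
# patch encoder is a small residual convolutional network used forward with
# seeded filters.

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V` with the softmax taken row-wise.
#'
#' @param Qm,Km,Vm numeric matrices; `Qm` is queries x d_k, `Km` keys x d_k,
#'   `Vm` keys x d_v.
#' @param d_k key dimension used in the scaling (defaults to `ncol(Km)`).
#' @return matrix of attended values (queries x d_v).
#' @export
attention <- function(Qm, Km, Vm, d_k = ncol(Km)) {
  if (ncol(Qm) != ncol(Km) || nrow(Km) != nrow(Vm))
    stop("attention dimension mismatch")
  S <- Qm %*% t(Km) / sqrt(d_k)
  A <- .softmaxRows(S)
  A %*% Vm
}

.softmaxRows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Genomic encoder configuration
#'
#' @param token_size features per token (the vector is chunked and the last
#'   token zero-padded).
#' @param d_model model width; must be divisible by `n_heads`.
#' @param n_heads attention heads.
#' @param n_layers transformer layers.
#' @param d_gen output embedding dimension.
#' @param d_ff feed-forward width (default `2 * d_model`).
#' @param seed RNG seed for parameter initialisation.
#' @return validated configuration list.
#' @export
genomicEncoderConfig <- function(token_size = 8L, d_model = 16L, n_heads = 2L,
                                 n_layers = 1L, d_gen = 8L,
                                 d_ff = 2L * d_model, seed = 1L) {
  if (d_model %% n_heads != 0) stop("d_model must be divisible by n_heads")
  list(token_size = as.integer(token_size), d_model = as.integer(d_model),
       n_heads = as.integer(n_heads), n_layers = as.integer(n_layers),
       d_gen = as.integer(d_gen), d_ff = as.integer(d_ff),
       seed = as.integer(seed))
}

# sinusoidal positional encodings, T x d
.posEncoding <- function(T, d) {
  P <- matrix(0, T, d)
  pos <- seq_len(T) - 1
  for (j in seq_len(d)) {
    i <- (j - 1) %/% 2
    w <- 1 / 10000^(2 * i / d)
    P[, j] <- if (j %% 2 == 1) sin(pos * w) else cos(pos * w)
  }
  P
}

.glorot <- function(rng, nin, nout) {
  rng(function() matrix(rnorm(nin * nout, 0, sqrt(2 / (nin + nout))),
                        nin, nout))
}

#' Initialise genomic encoder parameters
#'
#' Weights are Glorot-scaled normal draws from the seeded RNG; layer-norm
#' gains start at 1, all biases at 0.
#'
#' @param config a [genomicEncoderConfig()].
#' @return named list of parameter arrays (prefix `gen.`).
#' @export
initGenomicEncoder <- function(config) {
  rng <- localRNG(config$seed)
  d <- config$d_model
  p <- list()
  p[["gen.Wtok"]] <- .glorot(rng, config$token_size, d)
  p[["gen.btok"]] <- numeric(d)
  for (l in seq_len(config$n_layers)) {
    pre <- sprintf("gen.L%d.", l)
    for (nm in c("Wq", "Wk", "Wv", "Wo"))
      p[[paste0(pre, nm)]] <- .glorot(rng, d, d)
    for (nm in c("bq", "bk", "bv", "bo"))
      p[[paste0(pre, nm)]] <- numeric(d)
    p[[paste0(pre, "ln1.g")]] <- rep(1, d)
    p[[paste0(pre, "ln1.b")]] <- numeric(d)
    p[[paste0(pre, "ff.W1")]] <- .glorot(rng, d, config$d_ff)
    p[[paste0(pre, "ff.b1")]] <- numeric(config$d_ff)
    p[[paste0(pre, "ff.W2")]] <- .glorot(rng, config$d_ff, d)
    p[[paste0(pre, "ff.b2")]] <- numeric(d)
    p[[paste0(pre, "ln2.g")]] <- rep(1, d)
    p[[paste0(pre, "ln2.b")]] <- numeric(d)
  }
  p[["gen.Wout"]] <- .glorot(rng, d, config$d_gen)
  p[["gen.bout"]] <- numeric(config$d_gen)
  p
}

.lnForward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  v <- rowMeans((x - mu)^2)
  sigma <- sqrt(v + eps)
  xhat <- (x - mu) / sigma
  list(y = sweep(xhat, 2L, g, "*") + matrix(b, nrow(x), length(b),
                                            byrow = TRUE),
       xhat = xhat, sigma = sigma)
}

.lnBackward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) / cache$sigma
  list(dx = dx, dg = dg, db = db)
}

# chunk a genomic vector into zero-padded tokens (T x token_size)
.tokenize <- function(g, token_size) {
  G <- length(g)
  T <- ceiling(G / token_size)
  padded <- c(g, numeric(T * token_size - G))
  matrix(padded, T, token_size, byrow = TRUE)
}

.addBias <- function(X, b) X + matrix(b, nrow(X), length(b), byrow = TRUE)

# forward pass for one sample; returns embedding and (optionally) the cache
# needed for the reverse pass
.genForward <- function(g, params, config, keepCache = FALSE) {
  Tok <- .tokenize(g, config$token_size)
  T <- nrow(Tok)
  d <- config$d_model
  H <- config$n_heads
  dk <- d %/% H
  X <- .addBias(Tok %*% params[["gen.Wtok"]], params[["gen.btok"]]) +
    .posEncoding(T, d)
  cache <- list(Tok = Tok, layers = vector("list", config$n_layers))
  for (l in seq_len(config$n_layers)) {
    pre <- sprintf("gen.L%d.", l)
    Xin <- X
    Qm <- .addBias(Xin %*% params[[paste0(pre, "Wq")]],
                   params[[paste0(pre, "bq")]])
    Km <- .addBias(Xin %*% params[[paste0(pre, "Wk")]],
                   params[[paste0(pre, "bk")]])
    Vm <- .addBias(Xin %*% params[[paste0(pre, "Wv")]],
                   params[[paste0(pre, "bv")]])
    O <- matrix(0, T, d)
    As <- vector("list", H)
    for (h in seq_len(H)) {
      cols <- (h - 1L) * dk + seq_len(dk)
      A <- .softmaxRows(Qm[, cols, drop = FALSE] %*%
                          t(Km[, cols, drop = FALSE]) / sqrt(dk))
      As[[h]] <- A
      O[, cols] <- A %*% Vm[, cols, drop = FALSE]
    }
    Op <- .addBias(O %*% params[[paste0(pre, "Wo")]],
                   params[[paste0(pre, "bo")]])
    R1 <- Xin + Op
    ln1 <- .lnForward(R1, params[[paste0(pre, "ln1.g")]],
                      params[[paste0(pre, "ln1.b")]])
    X1 <- ln1$y
    Hpre <- .addBias(X1 %*% params[[paste0(pre, "ff.W1")]],
                     params[[paste0(pre, "ff.b1")]])
    Hrelu <- pmax(Hpre, 0)
    Fout <- .addBias(Hrelu %*% params[[paste0(pre, "ff.W2")]],
                     params[[paste0(pre, "ff.b2")]])
    R2 <- X1 + Fout
    ln2 <- .lnForward(R2, params[[paste0(pre, "ln2.g")]],
                      params[[paste0(pre, "ln2.b")]])
    if (keepCache)
      cache$layers[[l]] <- list(Xin = Xin, Qm = Qm, Km = Km, Vm = Vm,
                                As = As, O = O, ln1 = ln1, X1 = X1,
                                Hpre = Hpre, Hrelu = Hrelu, ln2 = ln2)
    X <- ln2$y
  }
  u <- colMeans(X)
  z <- as.vector(u %*% params[["gen.Wout"]]) + params[["gen.bout"]]
  cache$Xlast <- X
  cache$u <- u
  if (keepCache) list(z = z, cache = cache) else list(z = z)
}

# reverse pass for one sample: dz is the loss gradient w.r.t. the embedding;
# returns gradients for every gen.* parameter (named like params)
.genBackward <- function(dz, params, config, cache) {
  T <- nrow(cache$Xlast)
  d <- config$d_model
  H <- config$n_heads
  dk <- d %/% H
  grads <- list()
  grads[["gen.Wout"]] <- outer(cache$u, dz)
  grads[["gen.bout"]] <- dz
  dX <- matrix(as.vector(params[["gen.Wout"]] %*% dz), T, d,
               byrow = TRUE) / T
  for (l in rev(seq_len(config$n_layers))) {
    pre <- sprintf("gen.L%d.", l)
    cc <- cache$layers[[l]]
    bk2 <- .lnBackward(dX, cc$ln2, params[[paste0(pre, "ln2.g")]])
    grads[[paste0(pre, "ln2.g")]] <- bk2$dg
    grads[[paste0(pre, "ln2.b")]] <- bk2$db
    dR2 <- bk2$dx
    dX1 <- dR2
    dF <- dR2
    grads[[paste0(pre, "ff.W2")]] <- t(cc$Hrelu) %*% dF
    grads[[paste0(pre, "ff.b2")]] <- colSums(dF)
    dHrelu <- dF %*% t(params[[paste0(pre, "ff.W2")]])
    dHpre <- dHrelu * (cc$Hpre > 0)
    grads[[paste0(pre, "ff.W1")]] <- t(cc$X1) %*% dHpre
    grads[[paste0(pre, "ff.b1")]] <- colSums(dHpre)
    dX1 <- dX1 + dHpre %*% t(params[[paste0(pre, "ff.W1")]])
    bk1 <- .lnBackward(dX1, cc$ln1, params[[paste0(pre, "ln1.g")]])
    grads[[paste0(pre, "ln1.g")]] <- bk1$dg
    grads[[paste0(pre, "ln1.b")]] <- bk1$db
    dR1 <- bk1$dx
    dXin <- dR1
    dOp <- dR1
    grads[[paste0(pre, "Wo")]] <- t(cc$O) %*% dOp
    grads[[paste0(pre, "bo")]] <- colSums(dOp)
    dO <- dOp %*% t(params[[paste0(pre, "Wo")]])
    dQm <- matrix(0, T, d); dKm <- matrix(0, T, d); dVm <- matrix(0, T, d)
    for (h in seq_len(H)) {
      cols <- (h - 1L) * dk + seq_len(dk)
      A <- cc$As[[h]]
      dOh <- dO[, cols, drop = FALSE]
      Vh <- cc$Vm[, cols, drop = FALSE]
      dA <- dOh %*% t(Vh)
      dVm[, cols] <- t(A) %*% dOh
      dS <- A * (dA - rowSums(dA * A))
      dQm[, cols] <- dS %*% cc$Km[, cols, drop = FALSE] / sqrt(dk)
      dKm[, cols] <- t(dS) %*% cc$Qm[, cols, drop = FALSE] / sqrt(dk)
    }
    grads[[paste0(pre, "Wq")]] <- t(cc$Xin) %*% dQm
    grads[[paste0(pre, "bq")]] <- colSums(dQm)
    grads[[paste0(pre, "Wk")]] <- t(cc$Xin) %*% dKm
    grads[[paste0(pre, "bk")]] <- colSums(dKm)
    grads[[paste0(pre, "Wv")]] <- t(cc$Xin) %*% dVm
    grads[[paste0(pre, "bv")]] <- colSums(dVm)
    dXin <- dXin + dQm %*% t(params[[paste0(pre, "Wq")]]) +
      dKm %*% t(params[[paste0(pre, "Wk")]]) +
      dVm %*% t(params[[paste0(pre, "Wv")]])
    dX <- dXin
  }
  grads[["gen.Wtok"]] <- t(cache$Tok) %*% dX
  grads[["gen.btok"]] <- colSums(dX)
  grads
}

#' Encode a genomic feature vector
#'
#' Chunks the standardized vector into tokens, projects them to the model
#' width, adds sinusoidal positional encodings, applies the configured
#' number of multi-head self-attention + feed-forward layers (residual
#' connections and layer normalisation), mean-pools over tokens and maps
#' linearly to the `d_gen`-dimensional embedding.
#'
#' @param g numeric genomic feature vector (nonempty).
#' @param params parameter list from [initGenomicEncoder()].
#' @param config the matching [genomicEncoderConfig()].
#' @return numeric embedding of length `d_gen`.
#' @export
encodeGenomics <- function(g, params, config) {
  if (length(g) == 0) stop("empty genomic vector")
  .genForward(g, params, config)$z
}

# ---- residual convolutional patch encoder --------------------------------

#' Image patch encoder configuration
#'
#' @param n_res_blocks residual blocks (two 3x3 convolutions + identity skip
#'   each; a 2x2 stride-2 average-pool downsample sits between blocks).
#' @param base_channels channel width used throughout.
#' @param d_img output embedding dimension.
#' @param seed RNG seed for the filter initialisation.
#' @return configuration list.
#' @export
imageEncoderConfig <- function(n_res_blocks = 3L, base_channels = 8L,
                               d_img = 8L, seed = 1L) {
  if (n_res_blocks < 1 || base_channels < 1 || d_img < 1)
    stop("all sizes must be >= 1")
  list(n_res_blocks = as.integer(n_res_blocks),
       base_channels = as.integer(base_channels),
       d_img = as.integer(d_img), seed = as.integer(seed))
}

#' Initialise image encoder parameters
#' @param config an [imageEncoderConfig()].
#' @return named list of filter arrays and the final linear map.
#' @export
initImageEncoder <- function(config) {
  rng <- localRNG(config$seed)
  C <- config$base_channels
  conv <- function(cin, cout)
    rng(function() array(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                         dim = c(3, 3, cin, cout)))
  p <- list(stem = conv(1L, C), stem.b = numeric(C))
  for (k in seq_len(config$n_res_blocks)) {
    p[[sprintf("blk%d.W1", k)]] <- conv(C, C)
    p[[sprintf("blk%d.b1", k)]] <- numeric(C)
    p[[sprintf("blk%d.W2", k)]] <- conv(C, C)
    p[[sprintf("blk%d.b2", k)]] <- numeric(C)
  }
  p$proj <- .glorot(rng, C, config$d_img)
  p$proj.b <- numeric(config$d_img)
  p
}

# 'same' zero-padded 3x3 convolution via shifted sums; X is H x W x Cin
.conv3 <- function(X, W, b) {
  if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
  Hh <- dim(X)[1]; Ww <- dim(X)[2]; Cin <- dim(X)[3]; Cout <- dim(W)[4]
  out <- array(0, dim = c(Hh, Ww, Cout))
  for (co in seq_len(Cout)) {
    acc <- matrix(b[co], Hh, Ww)
    for (ci in seq_len(Cin)) for (di in -1:1) for (dj in -1:1) {
      w <- W[di + 2, dj + 2, ci, co]
      if (w == 0) next
      rs <- max(1, 1 + di):min(Hh, Hh + di)
      cs <- max(1, 1 + dj):min(Ww, Ww + dj)
      acc[rs - di, cs - dj] <- acc[rs - di, cs - dj] + w * X[rs, cs, ci]
    }
    out[, , co] <- acc
  }
  out
}

.avgPool2 <- function(X) {
  Hh <- dim(X)[1] %/% 2L; Ww <- dim(X)[2] %/% 2L
  out <- array(0, dim = c(Hh, Ww, dim(X)[3]))
  for (c in seq_len(dim(X)[3])) {
    M <- X[seq_len(2L * Hh), seq_len(2L * Ww), c]
    out[, , c] <- (M[seq(1, 2 * Hh, 2), seq(1, 2 * Ww, 2)] +
                   M[seq(2, 2 * Hh, 2), seq(1, 2 * Ww, 2)] +
                   M[seq(1, 2 * Hh, 2), seq(2, 2 * Ww, 2)] +
                   M[seq(2, 2 * Hh, 2), seq(2, 2 * Ww, 2)]) / 4
  }
  out
}

#' Encode a harmonized image patch
#'
#' Convolutional stem, `n_res_blocks` residual blocks (two 3x3 convolutions
#' with an identity skip), stride-2 average-pool downsampling between blocks,
#' global average pooling and a linear map to `d_img`. Deterministic given
#' the parameters.
#'
#' @param patch an `ImagePatch` (or matrix), at least 16 x 16.
#' @param params parameter list from [initImageEncoder()].
#' @param config the matching [imageEncoderConfig()].
#' @return numeric embedding of length `d_img`.
#' @export
encodeImage <- function(patch, params, config) {
  patch <- .asPatch(patch)
  px <- patch$pixels
  if (nrow(px) < 16 || ncol(px) < 16)
    stop("patch smaller than the 16x16 receptive minimum")
  X <- .conv3(px, params$stem, params$stem.b)
  X <- pmax(X, 0)
  for (k in seq_len(config$n_res_blocks)) {
    Y <- pmax(.conv3(X, params[[sprintf("blk%d.W1", k)]],
                     params[[sprintf("blk%d.b1", k)]]), 0)
    Y <- .conv3(Y, params[[sprintf("blk%d.W2", k)]],
                params[[sprintf("blk%d.b2", k)]])
    X <- pmax(X + Y, 0)
    if (k < config$n_res_blocks && dim(X)[1] >= 4 && dim(X)[2] >= 4)
      X <- .avgPool2(X)
  }
  gap <- apply(X, 3L, mean)
  as.vector(gap %*% params$proj) + params$proj.b
}
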