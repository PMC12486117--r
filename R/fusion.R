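# Multimodal fusion: dense image-branch encoder, transformer genomic encoder,
# VQC quantum features, fully connected head, the calibration-penalised hybrid
# loss, and training. Classical parameters are updated with gradients from the
# explicit reverse passes; circuit angles get the parameter-shift gradient,
# evaluated through an equivalent adjoint sweep for speed.

#' Fusion architecture configuration
#'
#' @param d_in_img width of the image-branch input table.
#' @param n_gen width of the genomic feature vector.
#' @param h_img hidden width of the dense image-branch encoder.
#' @param d_img image embedding dimension.
#' @param gen a [genomicEncoderConfig()].
#' @param vqc a [vqcConfig()]; `Q` also fixes the selected-feature count.
#' @param h_head hidden width of the fusion head.
#' @param seed RNG seed for initialisation.
#' @return architecture list.
#' @export
fusionArch <- function(d_in_img, n_gen,
                       h_img = 16L, d_img = 8L,
                       gen = genomicEncoderConfig(),
                       vqc = vqcConfig(Q = 6L, L = 2L),
                       h_head = 16L, seed = 1L) {
  list(d_in_img = as.integer(d_in_img), n_gen = as.integer(n_gen),
       h_img = as.integer(h_img), d_img = as.integer(d_img),
       gen = gen, vqc = vqc, h_head = as.integer(h_head),
       seed = as.integer(seed))
}

#' Training configuration
#'
#' @param lambda weight of the calibration (soft-ECE) penalty, `>= 0`.
#' @param ece_bins bin count M for both the soft surrogate and reported ECE.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs training epochs cap.
#' @param patience epochs without composite-score improvement before stopping.
#' @param early_stop_w weight w in the early-stopping score `AUC - w * ECE`.
#' @param seed RNG seed for batch shuffling.
#' @return configuration list.
#' @export
trainConfig <- function(lambda = 0.1, ece_bins = 10L, lr = 0.01,
                        batch_size = 32L, max_epochs = 30L, patience = 10L,
                        early_stop_w = 1, seed = 1L) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (ece_bins < 2) stop("ece_bins must be >= 2")
  list(lambda = lambda, ece_bins = as.integer(ece_bins), lr = lr,
       batch_size = as.integer(batch_size),
       max_epochs = as.integer(max_epochs), patience = as.integer(patience),
       early_stop_w = early_stop_w, seed = as.integer(seed))
}

#' Initialise a fusion model
#'
#' @param arch a [fusionArch()].
#' @return a [FusionModel-class] with seeded parameters and empty fitted
#'   state.
#' @export
initFusionModel <- function(arch) {
  rng <- localRNG(arch$seed)
  p <- list()
  p[["img.W1"]] <- .glorot(rng, arch$d_in_img, arch$h_img)
  p[["img.b1"]] <- numeric(arch$h_img)
  p[["img.W2"]] <- .glorot(rng, arch$h_img, arch$d_img)
  p[["img.b2"]] <- numeric(arch$d_img)
  p <- c(p, initGenomicEncoder(arch$gen))
  p[["vqc.theta"]] <- initVqcParams(arch$vqc)
  dcat <- arch$d_img + arch$gen$d_gen + arch$vqc$Q
  p[["head.W1"]] <- .glorot(rng, dcat, arch$h_head)
  p[["head.b1"]] <- numeric(arch$h_head)
  p[["head.W2"]] <- .glorot(rng, arch$h_head, 1L)
  p[["head.b2"]] <- 0
  new("FusionModel", params = p, arch = arch, fitted = list())
}

#' Fusion head prediction from the three embeddings
#'
#' Concatenates in the fixed order (image, genomic, quantum), applies one
#' ReLU hidden layer and the logistic link.
#'
#' @param z_img,z_gen,z_q embedding vectors (or matrices with samples in
#'   rows).
#' @param head list with `W1`, `b1`, `W2`, `b2`.
#' @return predicted probability (vector for matrix input), in (0, 1).
#' @export
fusePredict <- function(z_img, z_gen, z_q, head) {
  Z <- cbind(rbind(z_img), rbind(z_gen), rbind(z_q))
  if (ncol(Z) != nrow(head$W1)) stop("fusion head dimension mismatch")
  H <- pmax(.addBias(Z %*% head$W1, head$b1), 0)
  as.vector(plogis(as.vector(H %*% head$W2) + head$b2))
}

# ---- hybrid loss ---------------------------------------------------------

# soft-binned differentiable ECE surrogate: triangular (hat-function) bin
# memberships over M equal-width bins on [0.5, 1]; returns value and d/dp
.softEce <- function(p, y, M) {
  n <- length(p)
  w <- 0.5 / M
  centers <- 0.5 + (seq_len(M) - 0.5) * w
  conf <- pmax(p, 1 - p)
  dconf <- ifelse(p >= 0.5, 1, -1)
  cc <- pmin(pmax(conf, centers[1]), centers[M])
  inside <- conf > centers[1] & conf < centers[M]
  correct <- as.numeric((p >= 0.5) == (y == 1))
  U <- pmax(1 - abs(outer(cc, centers, "-")) / w, 0)   # n x M memberships
  s <- colSums(U)
  ok <- s > 0
  sSafe <- ifelse(ok, s, 1)
  accB <- colSums(U * correct) / sSafe
  confB <- colSums(U * conf) / sSafe
  D <- accB - confB
  val <- sum(s[ok] * abs(D[ok])) / n
  # gradient w.r.t. p
  sgn <- sign(D)
  dU <- matrix(0, n, M)
  for (b in seq_len(M)) {
    if (!ok[b]) next
    dU[, b] <- (abs(D[b]) + sgn[b] * ((correct - accB[b]) - (conf - confB[b])))
  }
  dUdcc <- -sign(outer(cc, centers, "-")) / w * (U > 0 & U < 1)
  dval_dcc <- rowSums(dU * dUdcc) / n
  dval_dconf_direct <- -(U %*% sgn) / n
  dconf_total <- dval_dcc * inside + as.vector(dval_dconf_direct)
  list(value = val, grad = dconf_total * dconf)
}

#' Hybrid calibrated training loss
#'
#' Natural-log binary cross-entropy plus `lambda` times a soft-binned
#' differentiable surrogate of the expected calibration error (triangular
#' kernel memberships over `M` equal-width confidence bins on `[0.5, 1]`,
#' weighted absolute gap between soft accuracy and soft confidence). The
#' hard-binned ECE reported by [computeMetrics()] is a different, piecewise
#' constant quantity; the surrogate exists only to carry gradients.
#' Probabilities at exactly 0 or 1 are clamped to `[1e-7, 1 - 1e-7]` with a
#' warning.
#'
#' @param p predicted probabilities.
#' @param y binary 0/1 labels.
#' @param lambda calibration penalty weight.
#' @param M surrogate bin count.
#' @return loss value with attributes `ce` (cross-entropy term) and
#'   `softEce` (surrogate value).
#' @export
hybridLoss <- function(p, y, lambda = 0.1, M = 10L) {
  if (length(p) != length(y)) stop("length mismatch")
  if (any(p <= 0 | p >= 1)) {
    warning("probabilities clamped to [1e-7, 1 - 1e-7]")
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  }
  y <- as.numeric(y)
  ce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  se <- if (lambda > 0) .softEce(p, y, M)$value else 0
  structure(ce + lambda * se, ce = ce, softEce = se)
}

# loss gradient w.r.t. the logit (p = plogis(logit))
.hybridLossGradLogit <- function(p, y, lambda, M) {
  n <- length(p)
  dce_dp <- (p - y) / (p * (1 - p)) / n
  dse_dp <- if (lambda > 0) .softEce(p, y, M)$grad else 0
  (dce_dp + lambda * dse_dp) * p * (1 - p)
}

# ---- forward/backward over a batch ---------------------------------------

# batch forward; Ximg: B x d_in_img (standardized), Glist: list of genomic
# vectors, A: B x Q angle matrix
.fusionForward <- function(params, arch, Ximg, Glist, A, keepCache = FALSE) {
  B <- nrow(Ximg)
  H1 <- .addBias(Ximg %*% params[["img.W1"]], params[["img.b1"]])
  H1r <- pmax(H1, 0)
  Zimg <- .addBias(H1r %*% params[["img.W2"]], params[["img.b2"]])
  genOut <- lapply(Glist, .genForward, params = params, config = arch$gen,
                   keepCache = keepCache)
  Zgen <- do.call(rbind, lapply(genOut, `[[`, "z"))
  Zq <- quantumEmbedBatch(A, params[["vqc.theta"]], arch$vqc)
  Z <- cbind(Zimg, Zgen, Zq)
  Hh <- .addBias(Z %*% params[["head.W1"]], params[["head.b1"]])
  Hr <- pmax(Hh, 0)
  logit <- as.vector(Hr %*% params[["head.W2"]]) + params[["head.b2"]]
  p <- plogis(logit)
  out <- list(p = p, logit = logit)
  if (keepCache)
    out$cache <- list(H1 = H1, H1r = H1r, Zimg = Zimg, Zgen = Zgen, Zq = Zq,
                      Z = Z, Hh = Hh, Hr = Hr, genOut = genOut, Ximg = Ximg,
                      A = A)
  out
}

.fusionBackward <- function(params, arch, fw, dlogit) {
  cc <- fw$cache
  g <- list()
  dHr <- outer(dlogit, as.vector(params[["head.W2"]]))
  dHh <- dHr * (cc$Hh > 0)
  g[["head.W2"]] <- t(cc$Hr) %*% matrix(dlogit, ncol = 1)
  g[["head.b2"]] <- sum(dlogit)
  g[["head.W1"]] <- t(cc$Z) %*% dHh
  g[["head.b1"]] <- colSums(dHh)
  dZ <- dHh %*% t(params[["head.W1"]])
  d1 <- arch$d_img; d2 <- arch$gen$d_gen; Q <- arch$vqc$Q
  dZimg <- dZ[, seq_len(d1), drop = FALSE]
  dZgen <- dZ[, d1 + seq_len(d2), drop = FALSE]
  dZq <- dZ[, d1 + d2 + seq_len(Q), drop = FALSE]
  # image branch
  g[["img.W2"]] <- t(cc$H1r) %*% dZimg
  g[["img.b2"]] <- colSums(dZimg)
  dH1 <- (dZimg %*% t(params[["img.W2"]])) * (cc$H1 > 0)
  g[["img.W1"]] <- t(cc$Ximg) %*% dH1
  g[["img.b1"]] <- colSums(dH1)
  # genomic branch, per sample
  for (i in seq_along(cc$genOut)) {
    gi <- .genBackward(dZgen[i, ], params, arch$gen, cc$genOut[[i]]$cache)
    for (nm in names(gi))
      g[[nm]] <- if (is.null(g[[nm]])) gi[[nm]] else g[[nm]] + gi[[nm]]
  }
  # quantum branch: adjoint sweep, numerically identical to the
  # parameter-shift rule (tested invariant) at a fraction of the cost
  g[["vqc.theta"]] <- vqcGradAdjoint(cc$A, params[["vqc.theta"]],
                                     arch$vqc, dZq)
  g
}

# ---- training ------------------------------------------------------------

.adamInit <- function(params)
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)

.adamStep <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gr
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gr^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# impute a patients x features table: each missing cell takes the mean of the
# feature in the k nearest pool patients (Euclidean over co-observed
# features); the pool is the training split so held-out rows never inform
# each other
.imputeWithPool <- function(X, poolIdx, k = 5L) {
  if (!anyNA(X)) return(X)
  obs <- !is.na(X)
  out <- X
  for (i in which(rowSums(!obs) > 0)) {
    for (j in which(!obs[i, ])) {
      cand <- poolIdx[obs[poolIdx, j] & poolIdx != i]
      if (!length(cand)) { out[i, j] <- 0; next }
      d <- vapply(cand, function(t) {
        co <- obs[i, ] & obs[t, ]
        if (!any(co)) return(Inf)
        sqrt(sum((X[i, co] - X[t, co])^2))
      }, numeric(1))
      use <- cand[order(d, cand)][seq_len(min(k, length(cand)))]
      out[i, j] <- mean(X[use, j])
    }
  }
  out
}

#' Train the multimodal fusion model on a cohort split
#'
#' Full hybrid training protocol: genomic missing values are imputed with
#' training-pool neighbours, both feature tables are z-scored with statistics
#' fitted on the training split, QAOA selects `Q` features from the pooled
#' candidate set (training split only), the angle scaler is fitted on the
#' training split, and the model is optimised by minibatch Adam on the hybrid
#' loss -- classical parameters by the explicit reverse passes, circuit
#' angles by the parameter-shift rule. After each epoch the validation AUC
#' and hard ECE are computed; training early-stops on the composite score
#' `AUC - w * ECE` with the configured patience and the best checkpoint is
#' kept.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param split output of [patientSplit()] or [siteHoldoutSplit()].
#' @param arch a [fusionArch()]; defaults are derived from the cohort.
#' @param train a [trainConfig()].
#' @param qaoa a [qaoaConfig()] for the feature-selection stage.
#' @param alpha,beta QUBO weights passed to [buildQubo()].
#' @param n_candidates candidate-pool size for the QAOA stage: features are
#'   pre-screened to the `n_candidates` most label-correlated ones (training
#'   split only) so the selection QUBO stays within the exact-simulation
#'   qubit budget (`<= 20`, default 12).
#' @return list with `model` (a [FusionModel-class]), `history` (per-epoch
#'   data.frame: epoch, train loss, val AUC, val ECE, composite), and
#'   `selection` (the QAOA feature-selection record).
#' @export
trainFusion <- function(cohort, split, arch = NULL, train = trainConfig(),
                        qaoa = qaoaConfig(), alpha = 0.25, beta = NULL,
                        n_candidates = 12L) {
  ids <- patientIds(cohort)
  idx <- list(train = match(split$train, ids), val = match(split$val, ids),
              test = match(split$test, ids))
  if (any(vapply(idx[c("train", "val")], length, integer(1)) == 0))
    stop("empty split")
  y <- cohortLabels(cohort)
  Ximg <- imgFeatures(cohort)
  Xgen <- genFeatures(cohort)

  # genomic imputation with training-pool neighbours
  Xgen <- .imputeWithPool(Xgen, idx$train, k = 5L)

  # standardization statistics from the training split only
  std <- function(X) {
    mu <- colMeans(X[idx$train, , drop = FALSE])
    sdv <- apply(X[idx$train, , drop = FALSE], 2L, sd)
    sdv[sdv == 0] <- 1
    list(X = sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/"), mean = mu, sd = sdv)
  }
  simg <- std(Ximg); sgen <- std(Xgen)
  Ximg <- simg$X; Xgen <- sgen$X

  if (is.null(arch))
    arch <- fusionArch(d_in_img = ncol(Ximg), n_gen = ncol(Xgen))

  # QAOA feature selection over the pooled candidate table (training rows),
  # pre-screened by relevance so the QUBO fits the exact simulator
  pool <- cbind(Ximg, Xgen)
  n_candidates <- min(n_candidates, ncol(pool), 20L)
  rAll <- suppressWarnings(abs(as.vector(
    cor(pool[idx$train, , drop = FALSE], y[idx$train]))))
  rAll[!is.finite(rAll)] <- 0
  cand <- sort(order(rAll, decreasing = TRUE)[seq_len(n_candidates)])
  sel <- selectFeatures(pool[idx$train, cand, drop = FALSE], y[idx$train],
                        k = arch$vqc$Q, alpha = alpha, beta = beta,
                        config = qaoa)
  selIdx <- cand[sel$indices]
  if (length(selIdx) != arch$vqc$Q) {
    # soft cardinality: pad with next-most-relevant candidates or truncate
    # so the subset fills the Q qubits
    ord <- cand[order(sel$scores$r, decreasing = TRUE)]
    selIdx <- utils::head(unique(c(selIdx, ord)), arch$vqc$Q)
  }
  sel$candidates <- cand
  sel$poolIndices <- selIdx
  scaler <- fitAngleScaler(pool[idx$train, selIdx, drop = FALSE])
  A <- scaleToAngles(pool[, selIdx, drop = FALSE], scaler)

  Glist <- lapply(seq_len(nrow(Xgen)), function(i) Xgen[i, ])

  model <- initFusionModel(arch)
  params <- model@params
  adam <- .adamInit(params)
  rng <- localRNG(train$seed)
  history <- data.frame()
  best <- list(score = -Inf, params = params, epoch = 0L)

  evalSplit <- function(params, which) {
    ii <- idx[[which]]
    fw <- .fusionForward(params, arch, Ximg[ii, , drop = FALSE],
                         Glist[ii], A[ii, , drop = FALSE])
    fw$p
  }

  for (epoch in seq_len(train$max_epochs)) {
    ord <- rng(function() sample(idx$train))
    batches <- split(ord, ceiling(seq_along(ord) / train$batch_size))
    epochLoss <- 0
    for (bt in batches) {
      fw <- .fusionForward(params, arch, Ximg[bt, , drop = FALSE],
                           Glist[bt], A[bt, , drop = FALSE],
                           keepCache = TRUE)
      p <- pmin(pmax(fw$p, 1e-7), 1 - 1e-7)
      loss <- hybridLoss(p, y[bt], train$lambda, train$ece_bins)
      dlogit <- .hybridLossGradLogit(p, y[bt], train$lambda, train$ece_bins)
      grads <- .fusionBackward(params, arch, fw, dlogit)
      upd <- .adamStep(params, grads, adam, train$lr)
      params <- upd$params; adam <- upd$state
      epochLoss <- epochLoss + as.numeric(loss) * length(bt)
    }
    epochLoss <- epochLoss / length(idx$train)
    pv <- evalSplit(params, "val")
    vAuc <- if (length(unique(y[idx$val])) == 2)
      aucScore(pv, y[idx$val]) else NA_real_
    vEce <- eceScore(pv, y[idx$val], M = train$ece_bins)
    score <- (if (is.na(vAuc)) 0 else vAuc) - train$early_stop_w * vEce
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epochLoss, val_auc = vAuc, val_ece = vEce,
      composite = score))
    if (score > best$score + 1e-12) {
      best <- list(score = score, params = params, epoch = epoch)
    } else if (epoch - best$epoch >= train$patience) {
      break
    }
  }

  fitted <- list(selIdx = selIdx, scaler = scaler,
                 imgStats = list(mean = simg$mean, sd = simg$sd),
                 genStats = list(mean = sgen$mean, sd = sgen$sd),
                 trainIds = split$train, trainConfig = train)
  out <- new("FusionModel", params = best$params, arch = arch,
             fitted = fitted)
  list(model = out, history = history, selection = sel, bestEpoch = best$epoch)
}

#' Predict probabilities with a trained fusion model
#'
#' Applies the fitted preprocessing state (training-split imputation pool is
#' not re-used; missing genomic entries are filled with the training means,
#' i.e. zeros on the standardized scale) and the stored parameters.
#'
#' @param fit result of [trainFusion()] (or its `model` element).
#' @param cohort the cohort to score.
#' @param ids patient ids to score (default: all).
#' @return named vector of predicted probabilities.
#' @export
predictFusion <- function(fit, cohort, ids = patientIds(cohort)) {
  model <- if (inherits(fit, "FusionModel")) fit else fit$model
  ft <- model@fitted
  arch <- model@arch
  ii <- match(ids, patientIds(cohort))
  Ximg <- imgFeatures(cohort)[ii, , drop = FALSE]
  Xgen <- genFeatures(cohort)[ii, , drop = FALSE]
  Ximg <- sweep(sweep(Ximg, 2L, ft$imgStats$mean, "-"), 2L, ft$imgStats$sd, "/")
  Xgen <- sweep(sweep(Xgen, 2L, ft$genStats$mean, "-"), 2L, ft$genStats$sd, "/")
  Xgen[is.na(Xgen)] <- 0
  pool <- cbind(Ximg, Xgen)
  A <- scaleToAngles(pool[, ft$selIdx, drop = FALSE], ft$scaler)
  Glist <- lapply(seq_len(nrow(Xgen)), function(i) Xgen[i, ])
  fw <- .fusionForward(model@params, arch, Ximg, Glist, A)
  stats::setNames(fw$p, ids)
}

#' Save a fusion model checkpoint as JSON
#'
#' All parameter arrays, the architecture, and the fitted preprocessing state
#' in one plain-text archive; [loadCheckpoint()] restores a model producing
#' identical predictions.
#'
#' @param model a [FusionModel-class].
#' @param path destination file.
#' @return the path, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  obj <- list(
    params = lapply(model@params, function(x)
      list(dim = dim(x), values = as.numeric(x))),
    arch = model@arch,
    fitted = model@fitted
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Restore a fusion model from a JSON checkpoint
#' @param path file written by [saveCheckpoint()].
#' @return a [FusionModel-class].
#' @export
loadCheckpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    x <- as.numeric(p$values)
    if (!is.null(p$dim) && length(p$dim)) dim(x) <- as.integer(p$dim)
    x
  })
  arch <- obj$arch
  arch$gen[] <- lapply(arch$gen, function(v)
    if (is.numeric(v)) as.integer(v) else v)
  for (nm in c("d_in_img", "n_gen", "h_img", "d_img", "h_head", "seed"))
    arch[[nm]] <- as.integer(arch[[nm]])
  arch$vqc$Q <- as.integer(arch$vqc$Q)
  arch$vqc$L <- as.integer(arch$vqc$L)
  arch$vqc$seed <- as.integer(arch$vqc$seed)
  fitted <- obj$fitted
  if (!is.null(fitted$scaler)) {
    fitted$scaler$min <- as.numeric(fitted$scaler$min)
    fitted$scaler$max <- as.numeric(fitted$scaler$max)
  }
  new("FusionModel", params = params, arch = arch,
      fitted = if (is.null(fitted)) list() else fitted)
}
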