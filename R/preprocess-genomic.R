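# Genomic preprocessing on a GenomicMatrix (genes x samples): TPM/FPKM
# normalization with log2(1+x), k-nearest-neighbour imputation, low-variance
# filtering and z-score standardization with train-split statistics reusable
# on held-out samples.

#' Normalize raw expression counts to TPM or FPKM
#'
#' TPM: counts are length-normalized to per-kilobase rates, each sample is
#' rescaled so rates sum to `10^6`, then `log2(1 + x)` is applied. FPKM:
#' `counts * 10^9 / (length_bp * library_size)`, then `log2(1 + x)`.
#'
#' @param m a [GenomicMatrix-class] at stage `"raw"` with nonnegative counts.
#' @param method `"TPM"` or `"FPKM"`.
#' @return a [GenomicMatrix-class] at stage `"normalized"`.
#' @export
normalizeExpression <- function(m, method = c("TPM", "FPKM")) {
  method <- match.arg(method)
  counts <- gmValues(m)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  lensKb <- geneLengthsKb(m)
  lib <- colSums(counts, na.rm = TRUE)
  if (any(lib == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  out <- if (method == "TPM") {
    rate <- counts / lensKb
    rateSum <- colSums(rate, na.rm = TRUE)
    sweep(rate, 2L, rateSum, "/") * 1e6
  } else {
    sweep(counts / (lensKb * 1000), 2L, lib, "/") * 1e9
  }
  res <- m
  SummarizedExperiment::assay(res, "values") <- log2(1 + out)
  .advanceStage(res, "raw", "normalized")
}

#' k-nearest-neighbour imputation of missing expression values
#'
#' Each missing cell (gene g, sample s) is filled with the mean of gene g in
#' the k nearest samples, by Euclidean distance computed over the genes
#' co-observed between the two samples, restricted to samples where g is
#' observed. Distance ties are broken by sample order. When fewer than k
#' eligible samples exist, all of them are used.
#'
#' @param m a [GenomicMatrix-class] at stage `"normalized"`.
#' @param k neighbour count, `>= 1` (default 5).
#' @return a [GenomicMatrix-class] at stage `"imputed"`.
#' @export
imputeKnn <- function(m, k = 5L) {
  if (k < 1) stop("k must be >= 1")
  V <- gmValues(m)
  obs <- !is.na(V)
  allMissing <- rowSums(obs) == 0
  if (any(allMissing))
    stop("gene(s) missing in every sample: ",
         paste(rownames(V)[allMissing], collapse = ", "))
  res <- m
  if (!anyNA(V)) return(.advanceStage(res, "normalized", "imputed"))
  ns <- ncol(V)
  # pairwise distances over co-observed genes
  D <- matrix(Inf, ns, ns)
  for (s in seq_len(ns)) for (t in seq_len(ns)) {
    if (s == t) next
    co <- obs[, s] & obs[, t]
    D[s, t] <- if (any(co)) sqrt(sum((V[co, s] - V[co, t])^2)) else Inf
  }
  filled <- V
  for (s in seq_len(ns)) {
    mg <- which(!obs[, s])
    for (g in mg) {
      cand <- which(obs[g, ] & seq_len(ns) != s)
      ord <- cand[order(D[s, cand], cand)]
      use <- ord[seq_len(min(k, length(ord)))]
      filled[g, s] <- mean(V[g, use])
    }
  }
  SummarizedExperiment::assay(res, "values") <- filled
  .advanceStage(res, "normalized", "imputed")
}

#' Remove low-variance genes and z-score standardize
#'
#' Drops genes whose variance is below the `var_quantile` quantile of gene
#' variances (and all exactly-zero-variance genes), then z-scores each
#' remaining gene. When `stats` is supplied (as returned in the metadata of a
#' previous call on the training split), the stored gene set, means and
#' standard deviations are reused instead of being refit, so held-out samples
#' never influence the statistics.
#'
#' @param m a [GenomicMatrix-class] at stage `"imputed"`.
#' @param var_quantile quantile cutoff in `[0, 1)` (default 0.05).
#' @param stats optional statistics list from a previous (training) call.
#' @return a [GenomicMatrix-class] at stage `"standardized"`; the fitted
#'   statistics are stored in `metadata(x)$standardization`.
#' @export
filterAndStandardize <- function(m, var_quantile = 0.05, stats = NULL) {
  if (m@stage != "imputed")
    stop("operation requires stage 'imputed' but object is at stage '",
         m@stage, "'")
  V <- gmValues(m)
  if (is.null(stats)) {
    vars <- apply(V, 1L, var)
    thr <- as.numeric(quantile(vars, var_quantile))
    keep <- vars >= thr & vars > 0
    if (!any(keep)) stop("all genes removed by variance filtering")
    mu <- rowMeans(V[keep, , drop = FALSE])
    sdv <- apply(V[keep, , drop = FALSE], 1L, sd)
    stats <- list(keep = rownames(V)[keep], mean = mu, sd = sdv,
                  threshold = thr)
  }
  idx <- match(stats$keep, rownames(V))
  if (anyNA(idx)) stop("stats refer to genes absent from the matrix")
  Z <- (V[idx, , drop = FALSE] - stats$mean) / stats$sd
  res <- GenomicMatrix(Z, geneLengthsKb(m)[idx], stage = "imputed")
  colnames(res) <- colnames(m)
  S4Vectors::metadata(res)$standardization <- stats
  .advanceStage(res, "imputed", "standardized")
}
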