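# Splitting protocols (patient-level stratified and site-held-out) and the
# binary-classification metric suite: accuracy, precision, recall, F1,
# Mann-Whitney AUC, hard-binned expected calibration error, ROC and
# reliability curves.

# largest-remainder apportionment of n into parts proportional to fractions
.apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Stratified patient-level train/validation/test split
#'
#' Patients are shuffled per seed within each label stratum and assigned to
#' the three sets by largest-remainder rounding of the fractions, so sizes
#' are exact up to rounding and class prevalence is preserved per split.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param fractions length-3 vector (train, val, test) summing to 1.
#' @param stratified stratify by label (default TRUE).
#' @param seed RNG seed for the shuffles.
#' @return list with `train`, `val`, `test` (patient-id character vectors),
#'   `kind = "patient_level"`, `seed`, and `heldSite = NA`.
#' @export
patientSplit <- function(cohort, fractions = c(0.7, 0.15, 0.15),
                         stratified = TRUE, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- nPatients(cohort)
  if (n < 10) stop("cohort too small to split (n < 10)")
  ids <- patientIds(cohort)
  strata <- if (stratified) split(ids, cohortLabels(cohort)) else list(ids)
  small <- vapply(strata, length, integer(1)) < 3
  if (any(small))
    stop("stratum too small (< 3 patients): label ",
         paste(names(strata)[small], collapse = ", "))
  rng <- localRNG(seed)
  # two-way largest-remainder apportionment: global set sizes are exact,
  # per-stratum allocations deviate from proportionality by at most one
  global <- .apportion(n, fractions)
  K <- length(strata)
  raw <- vapply(strata, length, integer(1)) %o% fractions
  alloc <- t(vapply(seq_len(K),
                    function(k) .apportion(length(strata[[k]]), fractions),
                    integer(3)))
  # per-stratum totals are exact; shift single patients between sets until
  # the global set sizes are exact too, moving where it least hurts
  # proportionality
  repeat {
    excess <- colSums(alloc) - global
    if (all(excess == 0)) break
    s <- which.max(excess)
    t <- which.min(excess)
    cand <- which(alloc[, s] > 0)
    k <- cand[which.max(raw[cand, t] - alloc[cand, t])]
    alloc[k, s] <- alloc[k, s] - 1L
    alloc[k, t] <- alloc[k, t] + 1L
  }
  sets <- list(train = character(0), val = character(0), test = character(0))
  for (k in seq_len(K)) {
    st <- rng(function() sample(strata[[k]]))
    sizes <- alloc[k, ]
    cuts <- cumsum(sizes)
    sets$train <- c(sets$train, st[seq_len(sizes[1])])
    sets$val <- c(sets$val, st[seq_len(sizes[2]) + cuts[1]])
    sets$test <- c(sets$test, st[seq_len(sizes[3]) + cuts[2]])
  }
  list(train = sets$train, val = sets$val, test = sets$test,
       kind = "patient_level", seed = as.integer(seed), heldSite = NA)
}

#' Site-held-out split
#'
#' The held site's patients form the test set in full; the remaining patients
#' are split into train/validation, stratified by label.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param heldSite site identifier to exclude from training entirely.
#' @param val_fraction fraction of the remaining patients used for validation.
#' @param seed RNG seed.
#' @return list as in [patientSplit()] with `kind = "site_held_out"`.
#' @export
siteHoldoutSplit <- function(cohort, heldSite, val_fraction = 0.2, seed = 1L) {
  sites <- siteIds(cohort)
  if (!heldSite %in% sites) stop("held site '", heldSite, "' not present")
  if (length(unique(sites)) < 2) stop("need at least 2 sites")
  ids <- patientIds(cohort)
  testIds <- ids[sites == heldSite]
  rest <- ids[sites != heldSite]
  restLab <- cohortLabels(cohort)[sites != heldSite]
  rng <- localRNG(seed)
  tr <- va <- character(0)
  for (lv in unique(restLab)) {
    st <- rng(function() sample(rest[restLab == lv]))
    nv <- .apportion(length(st), c(1 - val_fraction, val_fraction))[2]
    va <- c(va, st[seq_len(nv)])
    tr <- c(tr, if (nv > 0) st[-seq_len(nv)] else st)
  }
  list(train = tr, val = va, test = testIds, kind = "site_held_out",
       seed = as.integer(seed), heldSite = heldSite)
}

#' Mann-Whitney AUC
#'
#' Over all positive/negative pairs, a pair is credited 1 when the positive
#' scores higher and 0.5 on a tie; equals trapezoidal integration of the ROC
#' curve.
#'
#' @param scores predicted probabilities (or any monotone scores).
#' @param y binary 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(scores, y) {
  y <- as.numeric(y)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0)
    stop("AUC undefined: only one class present")
  r <- rank(scores)
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# hard equal-width ECE bins on confidence = max(p, 1-p) over [0.5, 1]
.eceBins <- function(scores, y, threshold = 0.5, M = 10L) {
  conf <- pmax(scores, 1 - scores)
  pred <- as.integer(scores >= threshold)
  correct <- as.integer(pred == y)
  w <- 0.5 / M
  idx <- ceiling((conf - 0.5) / w)
  idx[idx < 1L] <- 1L
  idx[idx > M] <- M
  lower <- 0.5 + (seq_len(M) - 1) * w
  upper <- 0.5 + seq_len(M) * w
  count <- tabulate(idx, nbins = M)
  acc <- vapply(seq_len(M), function(b)
    if (count[b] > 0) mean(correct[idx == b]) else NA_real_, numeric(1))
  cf <- vapply(seq_len(M), function(b)
    if (count[b] > 0) mean(conf[idx == b]) else NA_real_, numeric(1))
  data.frame(lower = lower, upper = upper, count = count,
             accuracy = acc, confidence = cf)
}

#' Hard-binned expected calibration error
#'
#' Confidence is `max(p, 1-p)`, binned into `M` equal-width bins over
#' `[0.5, 1]`; `ECE = sum_m (|B_m|/n) |acc(B_m) - conf(B_m)|` with empty bins
#' skipped.
#'
#' @param scores predicted probabilities.
#' @param y binary 0/1 labels.
#' @param M bin count (default 10).
#' @param threshold decision threshold defining correctness (default 0.5).
#' @return ECE in `[0, 1]`.
#' @export
eceScore <- function(scores, y, M = 10L, threshold = 0.5) {
  bt <- .eceBins(scores, y, threshold, M)
  ok <- bt$count > 0
  sum(bt$count[ok] / length(scores) * abs(bt$accuracy[ok] - bt$confidence[ok]))
}

#' Full metric suite for one evaluation split
#'
#' Confusion counts at `score >= threshold`, then accuracy, precision,
#' recall, F1 by the standard formulas (a zero-denominator precision or
#' recall is defined as 0 and flagged), Mann-Whitney AUC (`NA` when only one
#' class is present), and hard-binned ECE.
#'
#' @param scores predicted probabilities.
#' @param y binary 0/1 labels of equal length.
#' @param threshold decision threshold (default 0.5).
#' @param M ECE bin count (default 10).
#' @return a [MetricsReport-class].
#' @export
computeMetrics <- function(scores, y, threshold = 0.5, M = 10L) {
  if (length(scores) != length(y)) stop("scores and y length mismatch")
  y <- as.integer(y)
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1L & y == 1L); TN <- sum(pred == 0L & y == 0L)
  FP <- sum(pred == 1L & y == 0L); FN <- sum(pred == 0L & y == 1L)
  degenerate <- FALSE
  P <- if (TP + FP > 0) TP / (TP + FP) else { degenerate <- TRUE; 0 }
  R <- if (TP + FN > 0) TP / (TP + FN) else { degenerate <- TRUE; 0 }
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  ACC <- (TP + TN) / length(y)
  AUC <- if (length(unique(y)) == 2) aucScore(scores, y) else NA_real_
  bt <- .eceBins(scores, y, threshold, M)
  ok <- bt$count > 0
  ECE <- sum(bt$count[ok] / length(y) * abs(bt$accuracy[ok] - bt$confidence[ok]))
  new("MetricsReport",
      metrics = c(ACC = ACC, precision = P, recall = R, F1 = F1, AUC = AUC,
                  ECE = ECE),
      threshold = threshold,
      confusion = c(TP = TP, TN = TN, FP = FP, FN = FN),
      binTable = bt,
      degenerate = degenerate)
}

#' ROC curve by descending threshold sweep
#'
#' Sweeps the unique scores as thresholds in descending order; the curve is
#' anchored at (0,0) and (1,1) and its trapezoidal area equals [aucScore()].
#'
#' @param scores predicted probabilities.
#' @param y binary 0/1 labels, both classes present.
#' @return data.frame with `threshold`, `FPR`, `TPR`.
#' @export
rocCurve <- function(scores, y) {
  y <- as.integer(y)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) stop("ROC undefined: only one class present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / npos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / nneg, numeric(1))
  data.frame(threshold = c(Inf, thr, -Inf),
             FPR = c(0, fpr, 1), TPR = c(0, tpr, 1))
}

#' Reliability curve (ECE bin table)
#'
#' @param scores predicted probabilities.
#' @param y binary 0/1 labels.
#' @param M bin count.
#' @param threshold decision threshold.
#' @return the calibration bin table (see [computeMetrics()]).
#' @export
reliabilityCurve <- function(scores, y, M = 10L, threshold = 0.5) {
  .eceBins(scores, y, threshold, M)
}

#' Trapezoidal area under an ROC curve table
#' @param roc data.frame from [rocCurve()].
#' @return numeric area.
#' @export
rocArea <- function(roc) {
  sum(diff(roc$FPR) * (utils::head(roc$TPR, -1) + utils::tail(roc$TPR, -1)) / 2)
}
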