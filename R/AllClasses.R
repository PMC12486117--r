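#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor rnorm runif rbinom rnbinom quantile sd var optim
#'   binomial glm predict plogis qlogis
NULL

#' Synthetic paired radiogenomic cohort
#'
#' Container for a simulated cohort of patients with paired imaging-derived and
#' genomic feature tables, site assignments, binary diagnostic labels, and the
#' planted ground truth (which features carry signal, which are redundant
#' copies). Produced by [generateCohort()].
#'
#' @slot patientIds character vector of unique patient identifiers.
#' @slot siteIds character vector, acquisition site per patient.
#' @slot labels integer vector of 0/1 diagnostic labels.
#' @slot imgFeatures numeric matrix, patients x imaging features.
#' @slot genFeatures numeric matrix, patients x genomic features; may contain
#'   `NA` for values masked missing-completely-at-random.
#' @slot truth list with elements `imgInformative`, `genInformative`
#'   (integer column indices into the respective tables) and `redundant`
#'   (data.frame with columns `modality`, `index`, `parentModality`,
#'   `parentIndex`).
#' @slot config the [syntheticConfig()] list the cohort was generated from.
#' @export
setClass("SyntheticCohort",
  representation(
    patientIds = "character",
    siteIds = "character",
    labels = "integer",
    imgFeatures = "matrix",
    genFeatures = "matrix",
    truth = "list",
    config = "list"
  )
)

setValidity("SyntheticCohort", function(object) {
  n <- length(object@patientIds)
  msg <- character()
  if (length(object@siteIds) != n) msg <- c(msg, "siteIds length != n_patients")
  if (length(object@labels) != n) msg <- c(msg, "labels length != n_patients")
  if (nrow(object@imgFeatures) != n) msg <- c(msg, "imgFeatures rows != n_patients")
  if (nrow(object@genFeatures) != n) msg <- c(msg, "genFeatures rows != n_patients")
  if (!all(object@labels %in% c(0L, 1L))) msg <- c(msg, "labels must be 0/1")
  ti <- object@truth$imgInformative
  tg <- object@truth$genInformative
  if (any(ti < 1L) || any(ti > ncol(object@imgFeatures)))
    msg <- c(msg, "imgInformative indices out of range")
  if (any(tg < 1L) || any(tg > ncol(object@genFeatures)))
    msg <- c(msg, "genInformative indices out of range")
  red <- object@truth$redundant
  if (nrow(red) > 0) {
    ri <- red$index[red$modality == "img"]
    rg <- red$index[red$modality == "gen"]
    if (length(intersect(ri, ti)) || length(intersect(rg, tg)))
      msg <- c(msg, "redundant and informative indices must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticCohort number of patients.
#' @param x,object a `SyntheticCohort`.
#' @export
nPatients <- function(x) length(x@patientIds)

#' @describeIn SyntheticCohort patient identifiers.
#' @export
patientIds <- function(x) x@patientIds

#' @describeIn SyntheticCohort site identifiers.
#' @export
siteIds <- function(x) x@siteIds

#' @describeIn SyntheticCohort 0/1 diagnostic labels.
#' @export
cohortLabels <- function(x) x@labels

#' @describeIn SyntheticCohort imaging feature matrix (patients x features).
#' @export
imgFeatures <- function(x) x@imgFeatures

#' @describeIn SyntheticCohort genomic feature matrix (patients x features).
#' @export
genFeatures <- function(x) x@genFeatures

#' @describeIn SyntheticCohort planted ground-truth indices.
#' @export
plantedTruth <- function(x) x@truth

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nPatients(object), "patients,",
      ncol(object@imgFeatures), "imaging +", ncol(object@genFeatures),
      "genomic features\n")
  cat("  sites:", paste(unique(object@siteIds), collapse = ", "),
      " positives:", sum(object@labels), "\n")
  cat("  planted informative: img {",
      paste(object@truth$imgInformative, collapse = ","), "} gen {",
      paste(object@truth$genInformative, collapse = ","), "}\n")
  nmiss <- sum(is.na(object@genFeatures))
  cat("  missing genomic entries:", nmiss, "\n")
})

#' Quadratic unconstrained binary optimisation (QUBO) problem
#'
#' Encodes the diagonal feature-selection cost Hamiltonian: the cost of a
#' selection bitstring z is `const + sum(h * z) + sum_{i<j} J[i,j] z_i z_j`.
#' Qubit/feature `i` corresponds to bit `i-1` (qubit 0 is the least-significant
#' bit of a basis-state index).
#'
#' @slot n number of binary variables (features).
#' @slot h numeric vector of linear coefficients.
#' @slot J strictly upper-triangular numeric matrix of pairwise coefficients.
#' @slot const additive constant.
#' @export
setClass("QuboProblem",
  representation(n = "integer", h = "numeric", J = "matrix", const = "numeric")
)

setValidity("QuboProblem", function(object) {
  msg <- character()
  if (length(object@h) != object@n) msg <- c(msg, "h length != n")
  if (!all(dim(object@J) == c(object@n, object@n))) msg <- c(msg, "J must be n x n")
  if (any(object@J[lower.tri(object@J, diag = TRUE)] != 0))
    msg <- c(msg, "J must be strictly upper-triangular")
  if (!all(is.finite(object@h)) || !all(is.finite(object@J)))
    msg <- c(msg, "coefficients must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "QuboProblem", function(object) {
  cat("QuboProblem on", object@n, "binary variables\n")
  cat("  constant:", format(object@const), "\n")
  cat("  |h| range: [", format(min(abs(object@h))), ",",
      format(max(abs(object@h))), "]  nonzero J:",
      sum(object@J != 0), "\n")
})

#' Genomic expression matrix with preprocessing stage tracking
#'
#' A [SummarizedExperiment::SummarizedExperiment] (genes x samples, single
#' assay named `"values"`) carrying per-gene lengths in `rowData()$length_kb`
#' and a forward-only preprocessing stage tag. Stage transitions are enforced:
#' `raw -> normalized -> imputed -> standardized`.
#'
#' @slot stage one of `"raw"`, `"normalized"`, `"imputed"`, `"standardized"`.
#' @export
setClass("GenomicMatrix",
  contains = "SummarizedExperiment",
  representation(stage = "character")
)

setValidity("GenomicMatrix", function(object) {
  msg <- character()
  if (!object@stage %in% c("raw", "normalized", "imputed", "standardized"))
    msg <- c(msg, "stage must be raw/normalized/imputed/standardized")
  if (!"length_kb" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain length_kb")
  lk <- SummarizedExperiment::rowData(object)$length_kb
  if (any(!is.finite(lk)) || any(lk <= 0))
    msg <- c(msg, "gene lengths must be positive and finite")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomicMatrix
#'
#' @param values numeric matrix, genes x samples (may contain `NA`).
#' @param lengthsKb positive per-gene lengths in kilobases.
#' @param stage preprocessing stage of `values` (default `"raw"`).
#' @return a [GenomicMatrix-class] object.
#' @export
GenomicMatrix <- function(values, lengthsKb, stage = "raw") {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%04d", seq_len(ncol(values)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values),
    rowData = S4Vectors::DataFrame(length_kb = as.numeric(lengthsKb))
  )
  new("GenomicMatrix", se, stage = stage)
}

#' @describeIn GenomicMatrix the current preprocessing stage tag.
#' @param x a `GenomicMatrix`.
#' @export
prepStage <- function(x) x@stage

#' @describeIn GenomicMatrix per-gene lengths in kilobases.
#' @export
geneLengthsKb <- function(x) SummarizedExperiment::rowData(x)$length_kb

#' @describeIn GenomicMatrix the genes x samples value matrix.
#' @export
gmValues <- function(x) SummarizedExperiment::assay(x, "values")

setMethod("show", "GenomicMatrix", function(object) {
  cat("GenomicMatrix [", object@stage, "]: ", nrow(object), " genes x ",
      ncol(object), " samples, ", sum(is.na(gmValues(object))),
      " missing\n", sep = "")
})

# stage machine: raw -> normalized -> imputed -> standardized
.advanceStage <- function(x, from, to) {
  if (x@stage != from)
    stop("operation requires stage '", from, "' but object is at stage '",
         x@stage, "'")
  x@stage <- to
  x
}

#' Evaluation metrics for one split
#'
#' Holds the full binary-classification metric suite for one evaluation split:
#' accuracy, precision, recall, F1, AUC, expected calibration error, the
#' confusion counts at the decision threshold, and the calibration bin table.
#'
#' @slot metrics named numeric vector with elements `ACC`, `precision`,
#'   `recall`, `F1`, `AUC`, `ECE`.
#' @slot threshold decision threshold applied to predicted probabilities.
#' @slot confusion named integer vector `TP`, `TN`, `FP`, `FN`.
#' @slot binTable data.frame with per-bin `lower`, `upper`, `count`,
#'   `accuracy`, `confidence`.
#' @slot degenerate logical; `TRUE` when a zero-denominator precision/recall
#'   was defined as 0 by convention.
#' @export
setClass("MetricsReport",
  representation(metrics = "numeric", threshold = "numeric",
                 confusion = "integer", binTable = "data.frame",
                 degenerate = "logical")
)

setValidity("MetricsReport", function(object) {
  need <- c("ACC", "precision", "recall", "F1", "AUC", "ECE")
  if (!all(need %in% names(object@metrics)))
    return("metrics must contain ACC, precision, recall, F1, AUC, ECE")
  ok <- object@metrics[!is.na(object@metrics)]
  if (any(ok < -1e-12 | ok > 1 + 1e-12))
    return("all metrics must lie in [0, 1]")
  TRUE
})

setMethod("show", "MetricsReport", function(object) {
  m <- object@metrics
  cat("MetricsReport (threshold ", format(object@threshold), ")\n", sep = "")
  cat(sprintf("  ACC %.4f  P %.4f  R %.4f  F1 %.4f  AUC %s  ECE %.4f\n",
              m["ACC"], m["precision"], m["recall"], m["F1"],
              ifelse(is.na(m["AUC"]), "NA", sprintf("%.4f", m["AUC"])),
              m["ECE"]))
  cat("  confusion: ", paste(names(object@confusion), object@confusion,
                             sep = "=", collapse = " "), "\n", sep = "")
})

#' @describeIn MetricsReport named metric vector.
#' @param x a `MetricsReport`.
#' @export
metricValues <- function(x) x@metrics

#' @describeIn MetricsReport confusion counts at the threshold.
#' @export
confusionCounts <- function(x) x@confusion

#' @describeIn MetricsReport calibration bin table (reliability diagram data).
#' @export
calibrationBins <- function(x) x@binTable

#' Trained multimodal fusion model
#'
#' Bundles every trainable parameter of the hybrid model: the image-branch
#' encoder, the self-attention genomic encoder, the variational-quantum-circuit
#' angles theta, and the fully connected fusion head, together with the
#' architecture configuration and fitted input scalers needed for prediction.
#'
#' @slot params named list of numeric arrays (flat parameter store).
#' @slot arch architecture configuration list.
#' @slot fitted list of fitted preprocessing state (feature subset, angle
#'   scaler, standardization statistics) captured on the training split.
#' @export
setClass("FusionModel",
  representation(params = "list", arch = "list", fitted = "list")
)

setMethod("show", "FusionModel", function(object) {
  npar <- sum(vapply(object@params, length, integer(1)))
  cat("FusionModel:", npar, "trainable parameters\n")
  cat("  image branch d_img =", object@arch$d_img,
      "| genomic d_gen =", object@arch$d_gen,
      "| quantum Q =", object@arch$vqc$Q, "L =", object@arch$vqc$L, "\n")
})

#' @describeIn FusionModel flat named list of parameter arrays.
#' @param x a `FusionModel`.
#' @export
modelParams <- function(x) x@params

#' @describeIn FusionModel architecture configuration.
#' @export
modelArch <- function(x) x@arch
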