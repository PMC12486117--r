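# Synthetic paired radiogenomic cohorts with planted ground truth, plus the
# image-patch and count-matrix fixtures used to exercise the preprocessing
# stages. Everything is reproducible bit-for-bit from the configured seed.

#' Synthetic cohort configuration
#'
#' Defines the simulated study conditions: cohort size, how many features per
#' modality, how many of them carry the planted class signal, how many are
#' redundant noisy copies, the standardized effect size, site batch structure,
#' genomic missingness, and class balance.
#'
#' @param n_patients number of patients.
#' @param n_img_features,n_gen_features feature-table widths per modality.
#' @param n_informative_img,n_informative_gen planted informative features per
#'   modality (must not exceed the table width).
#' @param n_redundant noisy copies of informative features (parents cycle over
#'   the informative sets, copies live in the parent's modality).
#' @param effect_size standardized mean shift between classes on informative
#'   features (informative values are `N(0,1)` for class 0, `N(effect_size,1)`
#'   for class 1).
#' @param site_count number of acquisition sites.
#' @param site_shift_sd scale of the additive per-site offset (`N(0, sd^2)`,
#'   one scalar per site added to every feature of that site's patients).
#' @param missing_rate genomic missing-completely-at-random rate in `[0, 1)`.
#' @param class_balance positive-class probability in `(0, 1)`.
#' @param seed integer RNG seed.
#' @return validated configuration list.
#' @export
syntheticConfig <- function(n_patients = 400L,
                            n_img_features = 16L, n_gen_features = 24L,
                            n_informative_img = 3L, n_informative_gen = 3L,
                            n_redundant = 4L,
                            effect_size = 1.0,
                            site_count = 3L, site_shift_sd = 0.3,
                            missing_rate = 0.05,
                            class_balance = 0.5,
                            seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_img_features = as.integer(n_img_features),
              n_gen_features = as.integer(n_gen_features),
              n_informative_img = as.integer(n_informative_img),
              n_informative_gen = as.integer(n_informative_gen),
              n_redundant = as.integer(n_redundant),
              effect_size = effect_size,
              site_count = as.integer(site_count),
              site_shift_sd = site_shift_sd,
              missing_rate = missing_rate,
              class_balance = class_balance,
              seed = as.integer(seed))
  if (cfg$n_informative_img > cfg$n_img_features)
    stop("n_informative_img exceeds n_img_features")
  if (cfg$n_informative_gen > cfg$n_gen_features)
    stop("n_informative_gen exceeds n_gen_features")
  if (cfg$n_redundant > cfg$n_informative_img + cfg$n_informative_gen)
    stop("n_redundant exceeds n_informative_img + n_informative_gen")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (cfg$class_balance <= 0 || cfg$class_balance >= 1)
    stop("class_balance must lie in (0, 1)")
  nfree_img <- cfg$n_img_features - cfg$n_informative_img
  nfree_gen <- cfg$n_gen_features - cfg$n_informative_gen
  if (cfg$n_redundant > nfree_img + nfree_gen)
    stop("n_redundant exceeds the number of non-informative feature slots")
  cfg
}

#' Generate a paired radiogenomic cohort
#'
#' Labels are Bernoulli(`class_balance`). Informative features are `N(0,1)`
#' in class 0 and shifted by `effect_size` in class 1; each redundant feature
#' is its parent plus `N(0, 0.25^2)` noise; all remaining features are pure
#' `N(0,1)` noise. A per-site scalar offset `N(0, site_shift_sd^2)` is added
#' to every feature of that site's patients, and genomic entries are masked
#' missing completely at random at `missing_rate`.
#'
#' @param config a [syntheticConfig()].
#' @return a [SyntheticCohort-class].
#' @export
generateCohort <- function(config = syntheticConfig()) {
  rng <- localRNG(config$seed)
  n <- config$n_patients
  y <- rng(function() rbinom(n, 1L, config$class_balance))
  sites <- rng(function() sample(sprintf("site%d", seq_len(config$site_count)),
                                 n, replace = TRUE))
  imgInf <- rng(function() sort(sample.int(config$n_img_features,
                                           config$n_informative_img)))
  genInf <- rng(function() sort(sample.int(config$n_gen_features,
                                           config$n_informative_gen)))

  drawBlock <- function(nfeat, inf) {
    M <- rng(function() matrix(rnorm(n * nfeat), n, nfeat))
    if (length(inf))
      M[, inf] <- M[, inf] + config$effect_size * y
    M
  }
  Ximg <- drawBlock(config$n_img_features, imgInf)
  Xgen <- drawBlock(config$n_gen_features, genInf)

  # redundant copies: parents cycle img-informative first, then gen
  parents <- data.frame(
    modality = c(rep("img", length(imgInf)), rep("gen", length(genInf))),
    index = c(imgInf, genInf), stringsAsFactors = FALSE)
  freeImg <- setdiff(seq_len(config$n_img_features), imgInf)
  freeGen <- setdiff(seq_len(config$n_gen_features), genInf)
  red <- data.frame(modality = character(0), index = integer(0),
                    parentModality = character(0), parentIndex = integer(0),
                    stringsAsFactors = FALSE)
  if (config$n_redundant > 0) {
    for (i in seq_len(config$n_redundant)) {
      par <- parents[((i - 1L) %% nrow(parents)) + 1L, ]
      slotImg <- par$modality == "img" && length(freeImg) > 0
      if (!slotImg && par$modality == "img" && length(freeGen) == 0)
        stop("no free feature slot for redundant copy")
      mod <- if (par$modality == "img") {
        if (length(freeImg)) "img" else "gen"
      } else {
        if (length(freeGen)) "gen" else "img"
      }
      noise <- rng(function() rnorm(n, 0, 0.25))
      src <- if (par$modality == "img") Ximg[, par$index] else Xgen[, par$index]
      if (mod == "img") {
        j <- freeImg[1L]; freeImg <- freeImg[-1L]
        Ximg[, j] <- src + noise
      } else {
        j <- freeGen[1L]; freeGen <- freeGen[-1L]
        Xgen[, j] <- src + noise
      }
      red <- rbind(red, data.frame(modality = mod, index = j,
                                   parentModality = par$modality,
                                   parentIndex = par$index,
                                   stringsAsFactors = FALSE))
    }
  }

  siteOffsets <- rng(function() rnorm(config$site_count, 0,
                                      config$site_shift_sd))
  names(siteOffsets) <- sprintf("site%d", seq_len(config$site_count))
  off <- siteOffsets[sites]
  Ximg <- Ximg + off
  Xgen <- Xgen + off

  if (config$missing_rate > 0) {
    mask <- rng(function() matrix(runif(length(Xgen)) < config$missing_rate,
                                  nrow(Xgen), ncol(Xgen)))
    Xgen[mask] <- NA_real_
  }

  colnames(Ximg) <- sprintf("f%04d", seq_len(ncol(Ximg)))
  colnames(Xgen) <- sprintf("f%04d", seq_len(ncol(Xgen)))
  new("SyntheticCohort",
      patientIds = sprintf("P%04d", seq_len(n)),
      siteIds = unname(sites),
      labels = as.integer(y),
      imgFeatures = Ximg,
      genFeatures = Xgen,
      truth = list(imgInformative = imgInf, genInformative = genInf,
                   redundant = red),
      config = config)
}

#' Generate a lesion image patch with mask (and optional bias field)
#'
#' The patch is positive Gaussian background noise with one elliptical blob
#' whose mean intensity and radius depend on the label (label 1 lesions are
#' larger and brighter). When `bias = TRUE` the patch is multiplied by a
#' smooth positive quadratic field affinely rescaled to the range
#' `[0.7, 1.3]`; the planted field is returned for verification.
#'
#' @param label 0 or 1.
#' @param size patch side length in pixels, `>= 16`.
#' @param bias logical; multiply by a planted quadratic bias field.
#' @param seed integer RNG seed.
#' @return list with `patch` (positive numeric matrix), `mask` (0/1 matrix of
#'   blob pixels), and `field` (the planted multiplicative field; all ones
#'   when `bias = FALSE`).
#' @export
generateImagePatch <- function(label, size = 32L, bias = FALSE, seed = 1L) {
  if (size < 16L) stop("size must be >= 16")
  rng <- localRNG(seed)
  bg <- rng(function() matrix(0.25 + rnorm(size * size, 0, 0.03), size, size))
  cx <- rng(function() size / 2 + runif(1, -size / 10, size / 10))
  cy <- rng(function() size / 2 + runif(1, -size / 10, size / 10))
  rx <- (if (label == 1) 0.22 else 0.14) * size
  ry <- rx * rng(function() runif(1, 0.7, 1.0))
  ang <- rng(function() runif(1, 0, pi))
  ix <- matrix(seq_len(size), size, size)
  iy <- matrix(seq_len(size), size, size, byrow = TRUE)
  u <- (ix - cx) * cos(ang) + (iy - cy) * sin(ang)
  v <- -(ix - cx) * sin(ang) + (iy - cy) * cos(ang)
  mask <- ((u / rx)^2 + (v / ry)^2) <= 1
  blobMean <- if (label == 1) 0.75 else 0.55
  blobNoise <- rng(function() rnorm(sum(mask), 0, 0.02))
  patch <- bg
  patch[mask] <- blobMean + blobNoise
  patch <- pmax(patch, 0.05)
  field <- matrix(1, size, size)
  if (bias) {
    cf <- rng(function() runif(6, -1, 1))
    xs <- (ix - (size + 1) / 2) / (size / 2)
    ys <- (iy - (size + 1) / 2) / (size / 2)
    raw <- cf[1] + cf[2] * xs + cf[3] * ys +
      cf[4] * xs^2 + cf[5] * xs * ys + cf[6] * ys^2
    rngF <- range(raw)
    field <- if (diff(rngF) < 1e-12) matrix(1, size, size) else
      0.7 + 0.6 * (raw - rngF[1]) / diff(rngF)
    patch <- patch * field
  }
  list(patch = patch, mask = mask * 1, field = field)
}

#' Generate a nonnegative count matrix with gene lengths
#'
#' Negative-binomial counts with log-normal per-gene means and per-sample
#' library-size factors laid out geometrically from 0.4x to 2.0x (a 5-fold
#' span) with mild jitter, so column sums differ by at least 4x. Gene lengths
#' are uniform on `[0.2, 20]` kilobases.
#'
#' @param n_genes,n_samples positive counts.
#' @param seed integer RNG seed.
#' @return list with `counts` (genes x samples integer matrix) and
#'   `gene_lengths_kb`.
#' @export
generateCounts <- function(n_genes, n_samples, seed = 1L) {
  if (n_genes < 1 || n_samples < 1) stop("n_genes and n_samples must be >= 1")
  rng <- localRNG(seed)
  mu <- rng(function() exp(rnorm(n_genes, log(50), 1)))
  facs <- if (n_samples == 1) 1 else
    exp(seq(log(0.4), log(2.0), length.out = n_samples))
  facs <- facs * rng(function() exp(rnorm(n_samples, 0, 0.02)))
  counts <- rng(function() {
    M <- matrix(0L, n_genes, n_samples)
    for (s in seq_len(n_samples))
      M[, s] <- rnbinom(n_genes, mu = mu * facs[s], size = 5)
    M
  })
  rownames(counts) <- sprintf("g%04d", seq_len(n_genes))
  colnames(counts) <- sprintf("s%04d", seq_len(n_samples))
  lens <- rng(function() runif(n_genes, 0.2, 20))
  list(counts = counts, gene_lengths_kb = lens)
}

#' Write a cohort to disk
#'
#' Imaging and genomic tables as CSV (columns `patient_id`, `site_id`,
#' `label`, `f0001`, ...) and the planted truth indices as JSON.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(patient_id = patientIds(cohort),
                     site_id = siteIds(cohort),
                     label = cohortLabels(cohort))
  pImg <- file.path(dir, "imaging_features.csv")
  pGen <- file.path(dir, "genomic_features.csv")
  pTruth <- file.path(dir, "truth.json")
  utils::write.csv(cbind(meta, as.data.frame(imgFeatures(cohort))),
                   pImg, row.names = FALSE)
  utils::write.csv(cbind(meta, as.data.frame(genFeatures(cohort))),
                   pGen, row.names = FALSE)
  truth <- plantedTruth(cohort)
  jsonlite::write_json(list(imgInformative = truth$imgInformative,
                            genInformative = truth$genInformative,
                            redundant = truth$redundant,
                            config = cohort@config),
                       pTruth, auto_unbox = TRUE, digits = NA)
  invisible(c(imaging = pImg, genomic = pGen, truth = pTruth))
}

#' Read a cohort written by [writeCohort()]
#' @param dir directory containing the cohort files.
#' @return a [SyntheticCohort-class].
#' @export
readCohort <- function(dir) {
  img <- utils::read.csv(file.path(dir, "imaging_features.csv"),
                         check.names = FALSE)
  gen <- utils::read.csv(file.path(dir, "genomic_features.csv"),
                         check.names = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  red <- truth$redundant
  if (is.null(red) || length(red) == 0)
    red <- data.frame(modality = character(0), index = integer(0),
                      parentModality = character(0), parentIndex = integer(0))
  new("SyntheticCohort",
      patientIds = as.character(img$patient_id),
      siteIds = as.character(img$site_id),
      labels = as.integer(img$label),
      imgFeatures = as.matrix(img[, -(1:3), drop = FALSE]),
      genFeatures = as.matrix(gen[, -(1:3), drop = FALSE]),
      truth = list(imgInformative = as.integer(truth$imgInformative),
                   genInformative = as.integer(truth$genInformative),
                   redundant = as.data.frame(red)),
      config = as.list(truth$config))
}

# ---- minimal 16-bit grayscale PNG writer --------------------------------
# No installed package writes 16-bit grayscale PNG (png::writePNG is 8-bit),
# so the container format is produced directly: zlib stream via memCompress,
# CRC32 computed with the standard reflected polynomial.

.crcTable <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320 as signed 32-bit
  for (b in 0:255) {
    cr <- b
    for (k in 1:8) {
      cr <- if (bitwAnd(cr, 1L) == 1L)
        bitwXor(bitwShiftR(cr, 1L), poly) else bitwShiftR(cr, 1L)
    }
    tab[b + 1L] <- cr
  }
  tab
})

.crc32 <- function(bytes) {
  cr <- -1L
  v <- as.integer(bytes)
  for (x in v)
    cr <- bitwXor(bitwShiftR(cr, 8L),
                  .crcTable[bitwAnd(bitwXor(cr, x), 255L) + 1L])
  bitwXor(cr, -1L)
}

.u32 <- function(x) {
  # big-endian 4-byte encoding of a (possibly negative-signed) 32-bit value
  xs <- if (x < 0) x + 4294967296 else x
  as.raw(c(xs %/% 16777216, (xs %/% 65536) %% 256, (xs %/% 256) %% 256,
           xs %% 256))
}

.pngChunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(.u32(length(data)), body, .u32(.crc32(body)))
}

#' Write a matrix as a 16-bit grayscale PNG
#'
#' Values are clipped to `[0, 1]` and quantised to 16 bits. Rows of the
#' matrix map to image rows.
#'
#' @param x numeric matrix with values in `[0, 1]`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writePng16 <- function(x, path) {
  v <- round(pmin(pmax(x, 0), 1) * 65535)
  h <- nrow(x); w <- ncol(x)
  # scanlines: filter byte 0 then big-endian 16-bit samples, row-major
  scan <- raw((2L * w + 1L) * h)
  pos <- 1L
  for (r in seq_len(h)) {
    row <- v[r, ]
    scan[pos] <- as.raw(0L); pos <- pos + 1L
    bytes <- as.raw(rbind(row %/% 256, row %% 256))
    scan[pos:(pos + 2L * w - 1L)] <- bytes
    pos <- pos + 2L * w
  }
  ihdr <- c(.u32(w), .u32(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           .pngChunk("IHDR", ihdr),
           .pngChunk("IDAT", memCompress(scan, type = "gzip")),
           .pngChunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Write a patch and its mask as 16-bit grayscale PNGs
#'
#' The patch is rescaled into `[0, 1]` by its own range (recorded nowhere;
#' PNG export is for inspection, analysis always uses the in-memory values).
#'
#' @param patch numeric matrix.
#' @param mask 0/1 matrix.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the two paths.
#' @export
writePatchPng <- function(patch, mask, dir, prefix = "patch") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rngP <- range(patch)
  scaled <- if (diff(rngP) < 1e-12) patch * 0 else
    (patch - rngP[1]) / diff(rngP)
  p1 <- file.path(dir, paste0(prefix, ".png"))
  p2 <- file.path(dir, paste0(prefix, "_mask.png"))
  writePng16(scaled, p1)
  writePng16(mask, p2)
  invisible(c(patch = p1, mask = p2))
}
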