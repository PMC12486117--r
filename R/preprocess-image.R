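# Imaging preprocessing: bias-field correction, ROI extraction, harmonization
# to a common pixel spacing with per-patch z-scoring, and radiomic descriptor
# extraction. Coordinates are 0-based and boxes half-open [r0, r1) in all
# user-facing reporting.

#' Construct an image patch
#'
#' @param pixels numeric matrix of finite pixel values.
#' @param spacing pixel spacing in mm/pixel, `> 0`.
#' @return an `ImagePatch` (list with `pixels`, `spacing`).
#' @export
imagePatch <- function(pixels, spacing = 1) {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) stop("pixels must be finite")
  if (spacing <= 0) stop("spacing must be > 0")
  structure(list(pixels = pixels, spacing = spacing), class = "ImagePatch")
}

.asPatch <- function(p) {
  if (inherits(p, "ImagePatch")) p else imagePatch(p)
}

#' @export
print.ImagePatch <- function(x, ...) {
  cat("ImagePatch", nrow(x$pixels), "x", ncol(x$pixels), "@",
      x$spacing, "mm/pixel\n")
  invisible(x)
}

# polynomial design matrix over normalized coordinates in [-1, 1]
.polyDesign <- function(nr, nc, order) {
  xs <- if (nr > 1) (seq_len(nr) - (nr + 1) / 2) / ((nr - 1) / 2) else 0
  ys <- if (nc > 1) (seq_len(nc) - (nc + 1) / 2) / ((nc - 1) / 2) else 0
  X <- matrix(xs, nr, nc)
  Y <- matrix(ys, nr, nc, byrow = TRUE)
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i))
    cols[[length(cols) + 1L]] <- as.vector(X^i * Y^j)
  do.call(cbind, cols)
}

#' Log-domain polynomial bias-field correction
#'
#' Fits a 2-D polynomial of the given order to the log-intensity by least
#' squares and removes it, re-centering so mean brightness is preserved:
#' the result is `exp(log I - fitted + mean(fitted))`. Non-positive pixels
#' are shifted up by a small epsilon before taking logs.
#'
#' @param patch an `ImagePatch` (or bare matrix).
#' @param order polynomial order, one of 1, 2, 3 (default 2).
#' @return corrected `ImagePatch`; the fitted multiplicative field is attached
#'   as attribute `"field"`.
#' @export
correctBiasField <- function(patch, order = 2L) {
  patch <- .asPatch(patch)
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  px <- patch$pixels
  if (!all(is.finite(px))) stop("non-finite pixels")
  eps <- 1e-6 * max(abs(px), 1)
  if (any(px <= 0)) px <- px - min(px) + eps
  lg <- log(px)
  D <- .polyDesign(nrow(px), ncol(px), order)
  fit <- stats::lm.fit(D, as.vector(lg))
  field <- matrix(fit$fitted.values, nrow(px), ncol(px))
  corrected <- exp(lg - field + mean(field))
  # the log-domain re-centering preserves mean brightness only to first
  # order; rescale so the mean is preserved exactly
  corrected <- corrected * mean(px) / mean(corrected)
  out <- imagePatch(corrected, patch$spacing)
  attr(out, "field") <- exp(field - mean(field))
  out
}

#' Extract a region of interest around a lesion mask
#'
#' Takes the tight bounding box of the mask, dilates it by `margin` pixels and
#' clips to the image bounds. Indices in the returned `box` are 0-based with
#' half-open intervals `[r0, r1) x [c0, c1)`.
#'
#' @param patch an `ImagePatch` (or matrix).
#' @param mask 0/1 matrix of the same shape; must be nonempty.
#' @param margin nonnegative dilation in pixels.
#' @return list with `patch` (cropped `ImagePatch`), `mask` (cropped mask),
#'   and `box` (`c(r0, r1, c0, c1)`, 0-based half-open).
#' @export
extractRoi <- function(patch, mask, margin = 0L) {
  patch <- .asPatch(patch)
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(patch$pixels)))
    stop("mask shape must match patch")
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask: no lesion to extract")
  r0 <- max(min(idx[, 1]) - margin, 1L)
  r1 <- min(max(idx[, 1]) + margin, nrow(mask))
  c0 <- max(min(idx[, 2]) - margin, 1L)
  c1 <- min(max(idx[, 2]) + margin, ncol(mask))
  list(patch = imagePatch(patch$pixels[r0:r1, c0:c1, drop = FALSE],
                          patch$spacing),
       mask = mask[r0:r1, c0:c1, drop = FALSE],
       box = c(r0 - 1L, r1, c0 - 1L, c1))
}

# bilinear resampling by pixel-center alignment; identity when sizes match
.resampleBilinear <- function(px, nrOut, ncOut) {
  nr <- nrow(px); nc <- ncol(px)
  if (nrOut == nr && ncOut == nc) return(px)
  srcR <- (seq_len(nrOut) - 0.5) * nr / nrOut + 0.5
  srcC <- (seq_len(ncOut) - 0.5) * nc / ncOut + 0.5
  r0 <- pmin(pmax(floor(srcR), 1), nr); r1 <- pmin(r0 + 1, nr)
  c0 <- pmin(pmax(floor(srcC), 1), nc); c1 <- pmin(c0 + 1, nc)
  wr <- pmin(pmax(srcR - r0, 0), 1)
  wc <- pmin(pmax(srcC - c0, 0), 1)
  A <- px[r0, c0, drop = FALSE]; B <- px[r1, c0, drop = FALSE]
  C <- px[r0, c1, drop = FALSE]; D <- px[r1, c1, drop = FALSE]
  WR <- matrix(wr, nrOut, ncOut)
  WC <- matrix(wc, nrOut, ncOut, byrow = TRUE)
  A * (1 - WR) * (1 - WC) + B * WR * (1 - WC) +
    C * (1 - WR) * WC + D * WR * WC
}

#' Harmonize patches to a common pixel spacing with per-patch z-scoring
#'
#' Each patch is bilinearly resampled to `targetSpacing` and intensity
#' z-scored (mean 0, sd 1); a zero-variance patch maps to all zeros.
#'
#' @param patches list of `ImagePatch` objects (or a single one).
#' @param targetSpacing target spacing in mm/pixel.
#' @return list of harmonized `ImagePatch` objects.
#' @export
harmonizePatches <- function(patches, targetSpacing = 1) {
  if (inherits(patches, "ImagePatch")) patches <- list(patches)
  lapply(patches, function(p) {
    p <- .asPatch(p)
    sc <- p$spacing / targetSpacing
    nrOut <- max(1L, as.integer(round(nrow(p$pixels) * sc)))
    ncOut <- max(1L, as.integer(round(ncol(p$pixels) * sc)))
    px <- .resampleBilinear(p$pixels, nrOut, ncOut)
    s <- sd(px)
    px <- if (!is.finite(s) || s == 0) px * 0 else (px - mean(px)) / s
    imagePatch(px, targetSpacing)
  })
}

.skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}
.kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^4) / m2^2
}

# gray-level co-occurrence matrix: 8 levels, distance 1, 0 degrees,
# symmetrised; pairs restricted to horizontally adjacent in-mask pixels
.glcmStats <- function(px, mask, levels = 8L) {
  vals <- px[mask != 0]
  rng <- range(vals)
  q <- if (diff(rng) < 1e-12) rep(1L, length(px)) else {
    qq <- floor((px - rng[1]) / diff(rng) * levels) + 1L
    pmin(pmax(qq, 1L), levels)
  }
  q <- matrix(q, nrow(px), ncol(px))
  nc <- ncol(px)
  P <- matrix(0, levels, levels)
  if (nc >= 2) {
    left <- mask[, -nc, drop = FALSE] != 0
    right <- mask[, -1, drop = FALSE] != 0
    ok <- which(left & right)
    if (length(ok)) {
      a <- q[, -nc, drop = FALSE][ok]
      b <- q[, -1, drop = FALSE][ok]
      for (i in seq_along(a)) {
        P[a[i], b[i]] <- P[a[i], b[i]] + 1
        P[b[i], a[i]] <- P[b[i], a[i]] + 1
      }
    }
  }
  if (sum(P) == 0) return(c(contrast = 0, homogeneity = 1, energy = 1))
  P <- P / sum(P)
  ii <- matrix(seq_len(levels), levels, levels)
  jj <- t(ii)
  c(contrast = sum(P * (ii - jj)^2),
    homogeneity = sum(P / (1 + abs(ii - jj))),
    energy = sum(P^2))
}

#' Radiomic descriptors of a masked lesion
#'
#' Ten standard descriptors: intensity mean, sd, skewness and kurtosis over
#' the mask; area (`pixel count * spacing^2`), perimeter and circularity
#' (`4*pi*area / perimeter^2`); and three co-occurrence texture summaries
#' (contrast, homogeneity, energy) from an 8-level, distance-1, 0-degree
#' gray-level co-occurrence matrix restricted to the mask. The perimeter is
#' estimated from the count of boundary pixel edges with the Cauchy-Crofton
#' correction factor `pi/4`, which makes a rasterized disc score circularity
#' close to 1 (a raw edge count systematically overestimates the length of
#' diagonal boundaries).
#'
#' @param patch an `ImagePatch` (or matrix).
#' @param mask nonempty 0/1 matrix of the same shape.
#' @return named numeric vector of length 10.
#' @export
radiomicDescriptors <- function(patch, mask) {
  patch <- .asPatch(patch)
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(patch$pixels))) stop("mask shape must match patch")
  if (!any(mask != 0)) stop("empty mask")
  px <- patch$pixels
  sp <- patch$spacing
  vals <- px[mask != 0]
  m <- mask != 0
  padded <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
  padded[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  inner <- padded[2:(nrow(m) + 1), 2:(ncol(m) + 1)]
  edges <- sum(inner & !padded[1:nrow(m), 2:(ncol(m) + 1)]) +
    sum(inner & !padded[3:(nrow(m) + 2), 2:(ncol(m) + 1)]) +
    sum(inner & !padded[2:(nrow(m) + 1), 1:ncol(m)]) +
    sum(inner & !padded[2:(nrow(m) + 1), 3:(ncol(m) + 2)])
  area <- sum(m) * sp^2
  perimeter <- edges * sp * pi / 4
  circ <- if (perimeter > 0) 4 * pi * area / perimeter^2 else 0
  tex <- .glcmStats(px, mask)
  c(mean = mean(vals),
    sd = sd(vals),
    skewness = .skewness(vals),
    kurtosis = .kurtosis(vals),
    area = area,
    perimeter = perimeter,
    circularity = circ,
    tex)
}
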