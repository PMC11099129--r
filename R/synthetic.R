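#' Specify a synthetic two-class lesion dataset
#'
#' Defaults encode the study conditions the generator emulates: benign
#' lesions are near-circular (asymmetry 0.05-0.15) with mild border noise
#' (radial Fourier amplitude 0.02-0.06) and a single colour; malignant
#' lesions are asymmetric (0.35-0.60) with strong border irregularity
#' (0.12-0.30) and 2-4 intra-lesion colour patches. Both sit on a textured
#' skin background with additive Gaussian noise (sd 0.03) and dark
#' curvilinear hair strokes on 20% of images. The class regimes are disjoint
#' by construction: a threshold at asymmetry 0.25 separates them perfectly.
#'
#' @param nBenign,nMalignant class counts.
#' @param imageSize raster side length (default 224).
#' @param asymmetryBenign,asymmetryMalignant per-class asymmetry ranges.
#' @param irregularityBenign,irregularityMalignant per-class border
#'   irregularity (radial-noise amplitude) ranges.
#' @param patchesBenign,patchesMalignant per-class colour-patch count ranges.
#' @param backgroundTone RGB skin tone.
#' @param noiseSigma additive Gaussian noise sd on `[0, 1]`.
#' @param hairProb probability of hair-artifact strokes.
#' @param seed RNG seed.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nBenign, nMalignant, imageSize = 224L,
                          asymmetryBenign = c(0.05, 0.15),
                          asymmetryMalignant = c(0.35, 0.60),
                          irregularityBenign = c(0.02, 0.06),
                          irregularityMalignant = c(0.12, 0.30),
                          patchesBenign = c(1L, 1L),
                          patchesMalignant = c(2L, 4L),
                          backgroundTone = c(0.80, 0.62, 0.55),
                          noiseSigma = 0.03, hairProb = 0.2, seed = 1L) {
  new("SyntheticSpec",
      nBenign = as.integer(nBenign), nMalignant = as.integer(nMalignant),
      imageSize = as.integer(imageSize),
      asymmetryBenign = asymmetryBenign,
      asymmetryMalignant = asymmetryMalignant,
      irregularityBenign = irregularityBenign,
      irregularityMalignant = irregularityMalignant,
      patchesBenign = as.integer(patchesBenign),
      patchesMalignant = as.integer(patchesMalignant),
      backgroundTone = backgroundTone, noiseSigma = noiseSigma,
      hairProb = hairProb, seed = as.integer(seed))
}

#' Reference dataset specifications
#'
#' `paperScaleSpec()` carries the reference collection's class sizes (1800
#' benign, 1497 malignant; 3297 in total) for full-scale runs;
#' `smallSpec()` is the 60 + 50 = 110 image test-scale variant. Both share
#' the same per-class generative parameter regimes.
#'
#' @param seed RNG seed.
#' @return a [SyntheticSpec-class].
#' @export
paperScaleSpec <- function(seed = 1L) {
  syntheticSpec(nBenign = 1800L, nMalignant = 1497L, seed = seed)
}

#' @rdname paperScaleSpec
#' @export
smallSpec <- function(seed = 1L) {
  syntheticSpec(nBenign = 60L, nMalignant = 50L, seed = seed)
}

#' Draw the generative parameter manifest of a dataset
#'
#' First phase of generation: labels and all per-image generative parameters
#' (asymmetry, border irregularity, colour patch count, radius, centre,
#' orientation, hair flag and a per-image rendering seed) are drawn from the
#' dataset seed. [generateLesions()] renders rasters from exactly this
#' manifest, so the manifest is the ground truth for parameter-recovery
#' checks and carries the dataset's size contract.
#'
#' @param spec a [SyntheticSpec-class].
#' @return data.frame with one row per image.
#' @export
lesionParameters <- function(spec) {
  validObject(spec)
  n <- spec@nBenign + spec@nMalignant
  if (n == 0L) return(data.frame())
  labels <- c(rep("benign", spec@nBenign), rep("malignant", spec@nMalignant))
  withSeed(spec@seed, {
    ben <- labels == "benign"
    asym <- ifelse(ben,
                   stats::runif(n, spec@asymmetryBenign[1], spec@asymmetryBenign[2]),
                   stats::runif(n, spec@asymmetryMalignant[1], spec@asymmetryMalignant[2]))
    irr <- ifelse(ben,
                  stats::runif(n, spec@irregularityBenign[1], spec@irregularityBenign[2]),
                  stats::runif(n, spec@irregularityMalignant[1], spec@irregularityMalignant[2]))
    npat <- ifelse(ben,
                   sample(spec@patchesBenign[1]:spec@patchesBenign[2], n, TRUE),
                   sample(spec@patchesMalignant[1]:spec@patchesMalignant[2], n, TRUE))
    data.frame(
      id = seq_len(n), label = labels,
      asymmetry = asym, irregularity = irr, nPatches = as.integer(npat),
      r0 = stats::runif(n, 0.22, 0.30),
      cx = stats::runif(n, 0.45, 0.55), cy = stats::runif(n, 0.45, 0.55),
      phi = stats::runif(n, 0, 2 * pi),
      hair = stats::runif(n) < spec@hairProb,
      renderSeed = sample.int(.Machine$integer.max - 1L, n))
  })
}

# Render one image from its manifest row (deterministic via renderSeed).
renderLesion <- function(p, spec) {
  S <- spec@imageSize
  withSeed(p$renderSeed, {
    xs <- (seq_len(S) - 0.5) / S
    X <- matrix(xs, S, S, byrow = TRUE)      # column coordinate
    Y <- matrix(xs, S, S)                    # row coordinate
    dx <- X - p$cx; dy <- Y - p$cy
    rr <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)

    # shape asymmetry: eccentricity (mode 2) plus 3-fold deformation; a pure
    # mode-1 radial term would only translate the contour, not deform it
    shape <- 1 + p$asymmetry * (0.6 * cos(2 * (th - p$phi)) +
                                  0.4 * cos(3 * (th - p$phi)))
    # border irregularity: amplitude budget split over higher modes 4..7
    u <- stats::runif(4); u <- u / sum(u)
    ph <- stats::runif(4, 0, 2 * pi)
    pert <- 1
    for (m in 4:7)
      pert <- pert + p$irregularity * u[m - 3] * cos(m * th + ph[m - 3])
    R <- p$r0 * shape * pert
    mask <- 1 / (1 + exp(-(R - rr) * S / 1.5))   # soft edge ~1.5 px

    base <- c(0.45, 0.30, 0.20) + stats::runif(3, -0.05, 0.05)
    k <- p$nPatches
    pcx <- p$cx + stats::runif(k, -0.5, 0.5) * p$r0
    pcy <- p$cy + stats::runif(k, -0.5, 0.5) * p$r0
    pcol <- matrix(rep(base, each = k), k, 3) +
      matrix(stats::runif(3 * k, -0.15, 0.15), k, 3)
    pcol[1, ] <- base
    pcol[pcol < 0.02] <- 0.02; pcol[pcol > 0.95] <- 0.95
    nearest <- if (k == 1L) matrix(1L, S, S) else {
      d2 <- array(0, c(S, S, k))
      for (j in seq_len(k)) d2[, , j] <- (X - pcx[j])^2 + (Y - pcy[j])^2
      apply(d2, c(1, 2), which.min)
    }

    f1 <- stats::runif(2, 2, 6); f2 <- stats::runif(2, 2, 6)
    phase <- stats::runif(2, 0, 2 * pi)
    texture <- 0.02 * sin(2 * pi * (f1[1] * X + f1[2] * Y) + phase[1]) +
      0.02 * sin(2 * pi * (f2[1] * X - f2[2] * Y) + phase[2])

    img <- array(0, c(S, S, 3))
    for (c in 1:3) {
      lesC <- matrix(pcol[nearest, c], S, S)
      bgC <- spec@backgroundTone[c] + texture
      img[, , c] <- bgC * (1 - mask) + lesC * mask
    }
    img <- img + array(stats::rnorm(S * S * 3, 0, spec@noiseSigma), dim(img))

    if (isTRUE(p$hair)) {
      dark <- c(0.10, 0.08, 0.06)
      for (h in seq_len(sample(1:3, 1))) {
        ctrl <- matrix(stats::runif(6), 3, 2)
        t <- seq(0, 1, length.out = 4L * S)
        bx <- (1 - t)^2 * ctrl[1, 1] + 2 * t * (1 - t) * ctrl[2, 1] +
          t^2 * ctrl[3, 1]
        by <- (1 - t)^2 * ctrl[1, 2] + 2 * t * (1 - t) * ctrl[2, 2] +
          t^2 * ctrl[3, 2]
        ri <- round(by * (S - 1)) + 1L
        ci <- round(bx * (S - 1)) + 1L
        for (off in list(c(0L, 0L), c(1L, 0L), c(-1L, 0L),
                         c(0L, 1L), c(0L, -1L))) {
          r2 <- ri + off[1]; c2 <- ci + off[2]
          ok <- r2 >= 1L & r2 <= S & c2 >= 1L & c2 <= S
          for (c in 1:3) {
            lin <- cbind(r2[ok], c2[ok], c)
            img[lin] <- 0.3 * img[lin] + 0.7 * dark[c]
          }
        }
      }
    }

    img[img < 0] <- 0; img[img > 1] <- 1
    imageRaster(img, provenance = sprintf("synthetic:%s#%d", p$label, p$id))
  })
}

#' Generate the synthetic dataset
#'
#' Renders every image of the manifest drawn by [lesionParameters()]. Fully
#' reproducible: the same spec (including seed) yields pixel-identical
#' rasters. A zero total count returns an empty list.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list of [LabeledImage-class] with generative parameters attached.
#' @examples
#' imgs <- generateLesions(syntheticSpec(2, 2, imageSize = 48, seed = 3))
#' vapply(imgs, imageLabel, character(1))
#' @export
generateLesions <- function(spec) {
  pars <- lesionParameters(spec)
  if (!nrow(pars)) return(list())
  lapply(seq_len(nrow(pars)), function(i) {
    p <- pars[i, ]
    new("LabeledImage", image = renderLesion(p, spec), label = p$label,
        params = as.list(p))
  })
}

#' Labelled feature table for a synthetic dataset
#'
#' Generates the dataset, standardizes every image and extracts the
#' statistical + backbone feature vector (optionally denoising first).
#'
#' @param spec a [SyntheticSpec-class].
#' @param backbone a [Backbone-class].
#' @param denoise apply non-local-means before standardization
#'   (default `FALSE`).
#' @return data.frame with a `label` column followed by feature columns;
#'   suitable for [runHarness()] or CSV export.
#' @export
featureTable <- function(spec, backbone = descriptorBackbone(),
                         denoise = FALSE) {
  imgs <- generateLesions(spec)
  if (!length(imgs))
    return(data.frame(label = character()))
  feats <- t(vapply(imgs, function(im) {
    img <- im@image
    if (denoise) img <- denoiseImage(img)
    extractFeatures(standardizeImage(img), backbone)
  }, numeric(8L + backbone@d)))
  cbind(data.frame(label = vapply(imgs, imageLabel, character(1))),
        as.data.frame(feats))
}
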