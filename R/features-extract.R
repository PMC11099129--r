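# Backbone construction is memoised: the Gabor bank's projection matrix is
# expensive to build and deterministic for a given (d, size, seed).
.backboneCache <- new.env(parent = emptyenv())

# 3x3 grayscale dilation (max filter); suppresses thin dark structures such
# as hair strokes before shape analysis.
dilate3 <- function(L) {
  S <- nrow(L); out <- L
  for (di in -1:1) for (dj in -1:1) {
    r <- pmin(pmax(seq_len(S) + di, 1L), S)
    c <- pmin(pmax(seq_len(ncol(L)) + dj, 1L), ncol(L))
    out <- pmax(out, L[r, c])
  }
  out
}

# The 20 lesion descriptors (ABCD-style): radial border signature harmonics
# (asymmetry lives in harmonics 2-3, border irregularity in 4-7), profile
# dispersion, darkness mass, second/third/fourth moment invariants, gradient
# energy and darkness-weighted colour means/dispersions.
lesionDescriptors <- function(px) {
  L <- dilate3(luminance(px))
  S <- nrow(L)
  xs <- (seq_len(S) - 0.5) / S
  X <- matrix(xs, S, S, byrow = TRUE); Y <- matrix(xs, S, S)
  w <- pmax(0, 0.5 - L)                       # darkness map (lesion < skin)
  mass <- sum(w)
  w <- w / max(mass, 1e-9)
  mx <- sum(w * X); my <- sum(w * Y)
  dx <- X - mx; dy <- Y - my
  r <- sqrt(dx^2 + dy^2); th <- atan2(dy, dx)

  # radial signature: darkness-weighted boundary radius in 36 angular bins
  # (for a filled wedge the mean radius is 2/3 of the boundary radius)
  nbins <- 36L
  bin <- pmin(floor((th + pi) / (2 * pi) * nbins) + 1L, nbins)
  ws <- tapply(as.numeric(w), as.numeric(bin), sum)
  wr <- tapply(as.numeric(w * r), as.numeric(bin), sum)
  Rb <- rep(NA_real_, nbins)
  Rb[as.integer(names(ws))] <- 1.5 * wr / pmax(ws, 1e-12)
  Rb[is.na(Rb)] <- mean(Rb, na.rm = TRUE)
  Rn <- Rb / max(mean(Rb), 1e-12)
  amp <- 2 * Mod(stats::fft(Rn))[2:9] / nbins  # harmonics 1..8

  # moment invariants
  mu <- function(p, q) sum(w * dx^p * dy^q)
  m20 <- mu(2, 0); m02 <- mu(0, 2); m11 <- mu(1, 1)
  trc <- m20 + m02
  ecc <- sqrt(max(0, trc^2 - 4 * (m20 * m02 - m11^2))) / max(trc, 1e-12)
  s2 <- sqrt(max(trc, 1e-12))
  nrm <- function(p, q) mu(p, q) / s2^(p + q)
  i3 <- sqrt((nrm(3, 0) + nrm(1, 2))^2 + (nrm(2, 1) + nrm(0, 3))^2)
  i4 <- (nrm(3, 0) - 3 * nrm(1, 2))^2 + (3 * nrm(2, 1) - nrm(0, 3))^2

  # gradient energy (border + texture activity)
  tv <- (sum(abs(L[, -1] - L[, -ncol(L)])) + sum(abs(L[-1, ] - L[-S, ]))) / S

  # colour variegation: darkness-weighted channel means and dispersions
  cols <- numeric(0)
  nch <- dim(px)[3]
  for (c in seq_len(3)) {
    ch <- px[, , min(c, nch)]
    m <- sum(w * ch)
    cols <- c(cols, m, sqrt(sum(w * (ch - m)^2)))
  }

  c(radial = amp, radialSd = stats::sd(Rn), mass = mass / S^2,
    ecc = ecc, i3 = i3, i4 = i4, tv = tv, col = cols)
}

# Bank of random Gabor-patch rows (unit L2 norm) over a size x size grid.
gaborBank <- function(n, size, seed) {
  xs <- (seq_len(size) - 0.5) / size
  X <- matrix(xs, size, size, byrow = TRUE); Y <- matrix(xs, size, size)
  withSeed(seed, {
    P <- matrix(0, n, size * size)
    for (j in seq_len(n)) {
      cx <- stats::runif(1, 0.2, 0.8); cy <- stats::runif(1, 0.2, 0.8)
      sg <- stats::runif(1, 0.05, 0.15)
      f <- stats::runif(1, 2, 8)
      ang <- stats::runif(1, 0, pi); ph <- stats::runif(1, 0, 2 * pi)
      g <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sg^2)) *
        cos(2 * pi * f * (X * cos(ang) + Y * sin(ang)) + ph)
      P[j, ] <- as.numeric(g) / sqrt(sum(g^2))
    }
    P
  })
}

#' The default lesion descriptor backbone
#'
#' Deterministic lightweight feature map standing in for a pretrained deep
#' backbone: 20 ABCD-style lesion descriptors (radial border-signature
#' Fourier amplitudes for asymmetry and border irregularity, moment
#' invariants, darkness mass, gradient energy, and darkness-weighted colour
#' means/dispersions for variegation; a 3 x 3 grayscale dilation first
#' suppresses thin hair strokes) topped up with seeded random Gabor-patch
#' projections of the luminance plane to reach dimension `d`. With the
#' default `d = 101` the concatenated feature vector has the published total
#' length 8 + 101 = 109. Instances are memoised on `(d, size, seed)`.
#'
#' @param d output dimension (default 101; `d < 20` truncates the
#'   descriptor block).
#' @param size expected standardized side length (default 224); other sizes
#'   are resized before projection.
#' @param seed Gabor bank seed (default 17).
#' @return a [Backbone-class].
#' @export
descriptorBackbone <- function(d = 101L, size = 224L, seed = 17L) {
  d <- as.integer(d); size <- as.integer(size); seed <- as.integer(seed)
  key <- sprintf("desc_%d_%d_%d", d, size, seed)
  if (!is.null(.backboneCache[[key]])) return(.backboneCache[[key]])
  nDesc <- min(20L, d)
  nGabor <- d - nDesc
  P <- if (nGabor > 0L) gaborBank(nGabor, size, seed) else NULL
  fun <- function(image) {
    px <- image@pixels
    if (!all(dim(px)[1:2] == c(size, size)))
      px <- standardizeImage(image, size = size)@pixels
    desc <- lesionDescriptors(px)[seq_len(nDesc)]
    if (nGabor > 0L)
      c(desc, as.numeric(P %*% as.numeric(luminance(px))))
    else desc
  }
  bb <- new("Backbone", name = "descriptor", d = d, fun = fun)
  .backboneCache[[key]] <- bb
  bb
}

#' A seeded plain random-projection backbone
#'
#' Gaussian random projection of the standardized luminance plane to `d`
#' dimensions; kept as the minimal reference backbone (it carries little
#' shape information — see the methods vignette). Deterministic for a given
#' seed.
#'
#' @param d output dimension (default 101).
#' @param size expected standardized side length (default 224).
#' @param seed projection seed (default 17).
#' @return a [Backbone-class].
#' @export
randomProjectionBackbone <- function(d = 101L, size = 224L, seed = 17L) {
  d <- as.integer(d); size <- as.integer(size); seed <- as.integer(seed)
  key <- sprintf("rand_%d_%d_%d", d, size, seed)
  if (!is.null(.backboneCache[[key]])) return(.backboneCache[[key]])
  npix <- as.numeric(size)^2
  P <- if (d > 0L)
    withSeed(seed, matrix(stats::rnorm(d * npix, sd = 1 / sqrt(npix)),
                          nrow = d))
  else matrix(0, 0, npix)
  fun <- function(image) {
    lum <- luminance(image@pixels)
    if (!all(dim(lum) == c(size, size)))
      lum <- bilinearResize(lum, size, size)
    as.numeric(P %*% as.numeric(lum))
  }
  bb <- new("Backbone", name = sprintf("randproj%d", d), d = d, fun = fun)
  .backboneCache[[key]] <- bb
  bb
}

#' Extract the classifier's feature vector from an image
#'
#' Concatenates the eight statistical features of the luminance plane with
#' the backbone's deep features: `[mean, sd, var, median, skew, kurt, hmean,
#' gmean] ++ backbone(d)`. With the default backbone the vector has length
#' 109.
#'
#' @param image a standardized [ImageRaster-class].
#' @param backbone a [Backbone-class] (default [descriptorBackbone()]).
#' @return named numeric vector of length `8 + d`.
#' @export
extractFeatures <- function(image, backbone = descriptorBackbone()) {
  stopifnot(is(image, "ImageRaster"), is(backbone, "Backbone"))
  stat <- statisticalFeatures(image)
  deep <- backbone@fun(image)
  if (length(deep) != backbone@d)
    stop("backbone returned ", length(deep),
         " features but declares d = ", backbone@d)
  if (backbone@d > 0L)
    names(deep) <- sprintf("%s_%03d", backbone@name, seq_len(backbone@d))
  c(stat, deep)
}
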