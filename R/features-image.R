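#' Construct an ImageRaster
#'
#' Wraps an `H x W` matrix or `H x W x C` array of intensities. Values above
#' 1 are assumed to be on the 0-255 scale and divided by 255; everything is
#' clamped into `[0, 1]`.
#'
#' @param pixels numeric matrix or 3-d array (`C` in 1 or 3).
#' @param provenance character tag (file path or synthetic description).
#' @return an [ImageRaster-class].
#' @export
imageRaster <- function(pixels, provenance = "in-memory") {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  if (length(dim(pixels)) != 3L)
    stop("pixels must be an H x W matrix or H x W x C array")
  if (dim(pixels)[3] == 4L) pixels <- pixels[, , 1:3, drop = FALSE]  # drop alpha
  if (!all(is.finite(pixels))) stop("pixel values must be finite")
  if (max(pixels) > 1) pixels <- pixels / 255
  pixels[pixels < 0] <- 0
  pixels[pixels > 1] <- 1
  new("ImageRaster", pixels = pixels, provenance = as.character(provenance))
}

#' Non-local-means denoising
#'
#' Channel-wise non-local means: each pixel is replaced by a weighted average
#' of the pixels in its search window, weighted by the similarity of the
#' surrounding patches (`exp(-SSD / (count * strength^2))`). `strength = 0`
#' returns the input unchanged. The output always has the input's shape.
#'
#' @param image an [ImageRaster-class].
#' @param strength filtering strength `h` on the `[0, 1]` intensity scale
#'   (default `10/255`).
#' @param patch odd patch side length (default 7).
#' @param searchWindow odd search-window side length (default 21).
#' @return a denoised [ImageRaster-class] of identical shape.
#' @export
denoiseImage <- function(image, strength = 10 / 255, patch = 7L,
                         searchWindow = 21L) {
  stopifnot(is(image, "ImageRaster"))
  if (patch <= 0 || searchWindow <= 0)
    stop("patch and searchWindow must be positive")
  if (strength == 0) return(image)
  px <- image@pixels
  out <- px
  for (c in seq_len(dim(px)[3]))
    out[, , c] <- nlmeans_channel(px[, , c], strength,
                                  as.integer(patch), as.integer(searchWindow))
  new("ImageRaster", pixels = out, provenance = image@provenance)
}

# Vectorized bilinear resize of one channel matrix to newH x newW.
bilinearResize <- function(m, newH, newW) {
  H <- nrow(m); W <- ncol(m)
  if (H == newH && W == newW) return(m)
  # map target pixel centres into source coordinates
  sy <- (seq_len(newH) - 0.5) * H / newH + 0.5
  sx <- (seq_len(newW) - 0.5) * W / newW + 0.5
  y0 <- pmin(pmax(floor(sy - 0.5) + 0.5, 0.5), H - 0.5 + 1e-9)
  x0 <- pmin(pmax(floor(sx - 0.5) + 0.5, 0.5), W - 0.5 + 1e-9)
  iy <- pmin(pmax(floor(sy - 0.5), 0), H - 1)      # 0-based top index
  ix <- pmin(pmax(floor(sx - 0.5), 0), W - 1)
  wy <- pmin(pmax(sy - 0.5 - iy, 0), 1)            # weight of lower neighbour
  wx <- pmin(pmax(sx - 0.5 - ix, 0), 1)
  i1 <- pmin(iy + 1, H - 1) + 1L; i0 <- iy + 1L
  j1 <- pmin(ix + 1, W - 1) + 1L; j0 <- ix + 1L
  a <- m[i0, j0, drop = FALSE]; b <- m[i0, j1, drop = FALSE]
  c_ <- m[i1, j0, drop = FALSE]; d <- m[i1, j1, drop = FALSE]
  WY <- matrix(wy, newH, newW); WX <- matrix(wx, newH, newW, byrow = TRUE)
  (1 - WY) * ((1 - WX) * a + WX * b) + WY * ((1 - WX) * c_ + WX * d)
}

#' Standardize an image to the classifier's input convention
#'
#' Bilinear resize to `size x size`, replication of a grayscale channel to
#' three channels and normalization of intensities to `[0, 1]`.
#'
#' @param image an [ImageRaster-class] of any size, 1 or 3 channels.
#' @param size target side length (default 224).
#' @return a `size x size x 3` [ImageRaster-class].
#' @export
standardizeImage <- function(image, size = 224L) {
  stopifnot(is(image, "ImageRaster"))
  px <- image@pixels
  if (any(dim(px)[1:2] == 0L)) stop("empty image")
  chans <- lapply(seq_len(dim(px)[3]),
                  function(c) bilinearResize(px[, , c], size, size))
  if (length(chans) == 1L) chans <- chans[c(1, 1, 1)]
  out <- array(0, dim = c(size, size, 3L))
  for (c in 1:3) out[, , c] <- chans[[c]]
  out[out < 0] <- 0; out[out > 1] <- 1
  new("ImageRaster", pixels = out, provenance = image@provenance)
}

#' Read / write class-per-folder image trees
#'
#' `readImageTree` loads a directory with one sub-folder per class
#' (`benign/`, `malignant/`) of PNG or JPEG files into a list of
#' [LabeledImage-class]. `writeImageTree` writes labelled images as PNG into
#' that layout.
#'
#' @param dir directory path.
#' @param images list of [LabeledImage-class].
#' @return `readImageTree`: list of [LabeledImage-class];
#'   `writeImageTree`: the directory path, invisibly.
#' @export
readImageTree <- function(dir) {
  classes <- intersect(c("benign", "malignant"), list.dirs(dir, FALSE, FALSE))
  if (!length(classes))
    stop("no 'benign'/'malignant' class folders under ", dir)
  out <- list()
  for (cl in classes) {
    files <- list.files(file.path(dir, cl),
                        pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                        full.names = TRUE)
    for (f in files) {
      px <- if (grepl("\\.png$", f, ignore.case = TRUE))
        png::readPNG(f) else jpeg::readJPEG(f)
      out[[length(out) + 1L]] <-
        new("LabeledImage", image = imageRaster(px, provenance = f),
            label = cl, params = list())
    }
  }
  out
}

#' @rdname readImageTree
#' @export
writeImageTree <- function(images, dir) {
  for (cl in c("benign", "malignant"))
    dir.create(file.path(dir, cl), recursive = TRUE, showWarnings = FALSE)
  counts <- c(benign = 0L, malignant = 0L)
  for (im in images) {
    cl <- im@label
    counts[cl] <- counts[cl] + 1L
    px <- im@image@pixels
    if (dim(px)[3] == 1L) px <- px[, , 1L]
    png::writePNG(px, file.path(dir, cl, sprintf("%s_%04d.png", cl, counts[cl])))
  }
  invisible(dir)
}
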