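#' The eight statistical image features
#'
#' Computes, over the flattened grayscale luminance sample `Z` of size `q`:
#' mean, population standard deviation, sample variance (divisor `q - 1`),
#' median, skewness (third standardized moment `m3 / sigma^3`), kurtosis
#' (fourth standardized moment `m4 / sigma^4`, not excess), harmonic mean
#' `q / sum(1/Z)` and geometric mean `(prod Z)^(1/q)`. Zero-valued pixels are
#' offset by `eps` for the harmonic and geometric means; a constant sample
#' (`sigma = 0`) gets skewness and kurtosis 0 by convention.
#'
#' `mode = "paper_literal"` evaluates the source formulas exactly as printed
#' (several are typographical: the standard deviation lacks its square root,
#' the median formula is the middle index `(q+1)/2`, the skewness is a single
#' z-score — evaluated at the median — the kurtosis ratio uses the mean to
#' the fourth power, the harmonic mean multiplies `q` by the plain pixel sum
#' and the geometric mean omits the `q`-th root). It exists for comparison
#' only; the standard definitions are used everywhere else in the package.
#'
#' @param x an [ImageRaster-class] (its luminance is used) or a numeric
#'   vector of sample values.
#' @param mode `"standard"` (default) or `"paper_literal"`.
#' @param eps offset applied to zero pixels for the harmonic/geometric means
#'   (default 1e-8).
#' @return named numeric vector
#'   `c(mean, sd, var, median, skew, kurt, hmean, gmean)`.
#' @examples
#' statisticalFeatures(c(1, 2, 3, 4))
#' @export
statisticalFeatures <- function(x, mode = c("standard", "paper_literal"),
                                eps = 1e-8) {
  mode <- match.arg(mode)
  z <- if (is(x, "ImageRaster")) as.numeric(luminance(x@pixels))
       else as.numeric(x)
  q <- length(z)
  if (q <= 1L) stop("need a sample of size q > 1")
  mu <- mean(z)
  m2 <- mean((z - mu)^2)
  sigma <- sqrt(m2)                       # population sd
  zpos <- ifelse(z == 0, eps, z)

  if (mode == "paper_literal") {
    return(c(mean = mu,
             sd = mean(z^2) - mu^2,       # printed without the square root
             var = sum((z - mu)^2) / (q - 1),
             median = (q + 1) / 2,        # printed as the middle index
             skew = if (sigma > 0) (stats::median(z) - mu) / sigma else 0,
             kurt = if (sigma > 0) mu^4 / sigma^4 else 0,
             hmean = q * sum(z),
             gmean = exp(sum(log(zpos)))))
  }

  c(mean = mu,
    sd = sigma,
    var = sum((z - mu)^2) / (q - 1),
    median = stats::median(z),
    skew = if (sigma > 0) mean((z - mu)^3) / sigma^3 else 0,
    kurt = if (sigma > 0) mean((z - mu)^4) / sigma^4 else 0,
    hmean = q / sum(1 / zpos),
    gmean = exp(mean(log(zpos))))
}
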