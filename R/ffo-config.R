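#' Build a falcon finch optimizer configuration
#'
#' Assembles all algorithm constants with the published defaults: safety
#' threshold `pAlarm = 0.5`, besiege constant `lambda = 0.5`, producer share
#' 0.2, soft-besiege mixing constants `x1 = x2 = x3 = 1/3`, escape energy
#' initialized uniformly on `e0Range` and decayed as `E = 2 E0 (1 - k/iterMax)`,
#' jump strength `V ~ U(0, vMax)`.
#'
#' @param s dimension of the decision space.
#' @param lower,upper box bounds; scalars are recycled to length `s`.
#' @param l population size (default 30).
#' @param iterMax iterations to run (default 200).
#' @param pAlarm safety threshold in (0,1) (default 0.5).
#' @param lambda besiege constant (default 0.5).
#' @param x1,x2,x3 soft-besiege mixing constants (default 1/3 each).
#' @param producerFraction share of the population acting as producers
#'   (default 0.2).
#' @param seed RNG seed (default 1).
#' @param e0Range interval for the initial escape energy (default `c(-1, 1)`).
#' @param vMax upper end of the jump-strength draw (default 2).
#' @param ssaCompat if `TRUE`, the alarmed producer move uses the additive
#'   sparrow-search form `Y + N` instead of the multiplicative printed form
#'   `Y * N`.
#' @param besiegeEnabled allow scroungers to escalate to soft/hard besiege
#'   (default `TRUE`).
#' @param perchingEnabled apply the perching stage (default `TRUE`).
#' @param perchScope `"all"` (default) or `"producers"`.
#' @param initGuess optional length-`s` vector injected as the first
#'   individual of the initial population.
#' @return an [FFOConfig-class] object.
#' @examples
#' cfg <- ffoConfig(s = 2, lower = -5, upper = 5, seed = 7)
#' @export
ffoConfig <- function(s, lower, upper, l = 30L, iterMax = 200L,
                      pAlarm = 0.5, lambda = 0.5,
                      x1 = 1 / 3, x2 = 1 / 3, x3 = 1 / 3,
                      producerFraction = 0.2, seed = 1L,
                      e0Range = c(-1, 1), vMax = 2,
                      ssaCompat = FALSE, besiegeEnabled = TRUE,
                      perchingEnabled = TRUE, perchScope = "all",
                      initGuess = NULL) {
  s <- as.integer(s)
  lower <- rep_len(as.numeric(lower), s)
  upper <- rep_len(as.numeric(upper), s)
  new("FFOConfig",
      l = as.integer(l), s = s, iterMax = as.integer(iterMax),
      lower = lower, upper = upper,
      pAlarm = pAlarm, lambda = lambda, x1 = x1, x2 = x2, x3 = x3,
      producerFraction = producerFraction, seed = as.integer(seed),
      e0Range = as.numeric(e0Range), vMax = as.numeric(vMax),
      ssaCompat = isTRUE(ssaCompat), besiegeEnabled = isTRUE(besiegeEnabled),
      perchingEnabled = isTRUE(perchingEnabled), perchScope = perchScope,
      initGuess = if (is.null(initGuess)) numeric() else as.numeric(initGuess))
}

#' Read / write an optimizer configuration as a flat YAML file
#'
#' @param config an [FFOConfig-class].
#' @param path file path.
#' @return `readFFOConfig` returns an [FFOConfig-class];
#'   `writeFFOConfig` returns `path` invisibly.
#' @export
writeFFOConfig <- function(config, path) {
  fields <- list(
    l = config@l, s = config@s, iterMax = config@iterMax,
    lower = config@lower, upper = config@upper,
    pAlarm = config@pAlarm, lambda = config@lambda,
    x1 = config@x1, x2 = config@x2, x3 = config@x3,
    producerFraction = config@producerFraction, seed = config@seed,
    e0Range = config@e0Range, vMax = config@vMax,
    ssaCompat = config@ssaCompat, besiegeEnabled = config@besiegeEnabled,
    perchingEnabled = config@perchingEnabled, perchScope = config@perchScope)
  if (length(config@initGuess)) fields$initGuess <- config@initGuess
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' @rdname writeFFOConfig
#' @export
readFFOConfig <- function(path) {
  f <- yaml::read_yaml(path)
  ffoConfig(s = f$s, lower = f$lower, upper = f$upper, l = f$l,
            iterMax = f$iterMax, pAlarm = f$pAlarm, lambda = f$lambda,
            x1 = f$x1, x2 = f$x2, x3 = f$x3,
            producerFraction = f$producerFraction, seed = f$seed,
            e0Range = f$e0Range, vMax = f$vMax, ssaCompat = f$ssaCompat,
            besiegeEnabled = f$besiegeEnabled,
            perchingEnabled = f$perchingEnabled, perchScope = f$perchScope,
            initGuess = f$initGuess)
}

#' Escape energy decay
#'
#' `E = 2 * E0 * (1 - k / iterMax)`: the magnitude decays linearly with the
#' iteration counter and is exactly 0 at `k = iterMax`.
#'
#' @param E0 initial escape energy.
#' @param k current iteration (0-based).
#' @param iterMax total iterations.
#' @return numeric escape energy.
#' @export
escapeEnergy <- function(E0, k, iterMax) {
  2 * E0 * (1 - k / iterMax)
}

#' Pseudo-inverse of a single-row matrix
#'
#' Computes `B+ = t(B) (B t(B))^-1` for a 1 x s row vector. For rows with
#' entries in {-1, +1} the result has entries `B_j / s`.
#'
#' @param B numeric vector treated as a 1 x s row.
#' @return numeric length-`s` vector (the s x 1 pseudo-inverse).
#' @export
pseudoInverseRow <- function(B) {
  B <- as.numeric(B)
  g <- sum(B * B)
  if (g == 0) stop("zero row vector has no pseudo-inverse of this form")
  B / g
}

#' Draw the per-individual random quantities for one iteration
#'
#' Every stage decision of the optimizer for one individual in one iteration
#' is driven by this fixed-order block of draws: alarm draw `T`, besiege
#' selector `z`, perching selector `p`, producer exponent scale `beta`,
#' standard-normal `N`, perching uniforms `n1..n4`, initial escape energy
#' `E0`, jump strength `V`, normal `Q` and the +/-1 row vector `B`. All
#' fields are always consumed, whichever branch later fires, so runs are
#' bit-reproducible under a seed.
#'
#' @param s decision dimension (length of `B`).
#' @param e0Range,vMax escape-energy interval and jump-strength cap.
#' @return named list of draws.
#' @export
stageDraws <- function(s, e0Range = c(-1, 1), vMax = 2) {
  list(
    T = stats::runif(1),
    z = stats::runif(1),
    p = stats::runif(1),
    beta = 1 - stats::runif(1),          # in (0, 1]
    N = stats::rnorm(1),
    n = stats::runif(4),
    E0 = stats::runif(1, e0Range[1], e0Range[2]),
    V = stats::runif(1, 0, vMax),
    Q = stats::rnorm(1),
    B = ifelse(stats::runif(s) < 0.5, -1, 1)
  )
}
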