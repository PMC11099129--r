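#' Initialize a finch swarm
#'
#' Draws an `l x s` population uniformly inside the box `[lower, upper]`
#' from the current RNG stream (seed it with `set.seed()` or run through
#' [ffoOptimize()], which seeds from the config). Fitnesses are left as the
#' `NA` sentinel until [evaluateFitness()] is called. If the config carries an
#' `initGuess`, it replaces the first row (clipped to the bounds).
#'
#' @param config an [FFOConfig-class]; bounds must be finite with
#'   `lower <= upper`.
#' @return an unevaluated [FinchSwarm-class].
#' @examples
#' set.seed(7)
#' sw <- initializeSwarm(ffoConfig(s = 2, lower = 0, upper = 1, l = 4))
#' @export
initializeSwarm <- function(config) {
  validObject(config)
  l <- config@l; s <- config@s
  u <- matrix(stats::runif(l * s), nrow = l, ncol = s)
  pos <- sweep(sweep(u, 2, config@upper - config@lower, `*`),
               2, config@lower, `+`)
  if (length(config@initGuess))
    pos[1L, ] <- clipToBounds(config@initGuess, config@lower, config@upper)
  new("FinchSwarm",
      positions = pos, fitnesses = rep(NA_real_, l),
      bestPosition = rep(NA_real_, s), bestFitness = Inf,
      worstPosition = rep(NA_real_, s), worstFitness = -Inf,
      meanPosition = colMeans(pos), iteration = 0L, evaluations = 0L)
}

# Refresh best/worst/mean bookkeeping. The global best is elitist: it only
# improves. The worst tracks the current population.
refreshBookkeeping <- function(swarm) {
  fit <- swarm@fitnesses
  iBest <- which.min(fit)
  if (fit[iBest] <= swarm@bestFitness) {
    swarm@bestFitness <- fit[iBest]
    swarm@bestPosition <- swarm@positions[iBest, ]
  }
  iWorst <- which.max(fit)
  swarm@worstFitness <- fit[iWorst]
  swarm@worstPosition <- swarm@positions[iWorst, ]
  swarm@meanPosition <- colMeans(swarm@positions)
  swarm
}

# Stable sort of individuals by fitness (ties keep original order).
sortSwarm <- function(swarm) {
  ord <- order(swarm@fitnesses)          # radix: stable for numeric
  swarm@positions <- swarm@positions[ord, , drop = FALSE]
  swarm@fitnesses <- swarm@fitnesses[ord]
  swarm
}

# Number of producers: at least 1, at most l - 1 so scroungers exist.
producerCount <- function(config, l = config@l) {
  min(max(1L, as.integer(round(config@producerFraction * l))), l - 1L)
}

#' Evaluate the fitness of every individual
#'
#' Fills the fitness vector by applying `objective` to each row, updates the
#' elitist best / current worst / mean bookkeeping and sorts individuals by
#' fitness (stable, so equal fitnesses keep their original order); after the
#' sort the first `producerFraction * l` rows are the producers. An objective
#' returning a non-finite value gives that individual `+Inf` fitness with a
#' warning.
#'
#' @param swarm a [FinchSwarm-class].
#' @param objective function from a length-`s` numeric vector to a scalar
#'   (minimized).
#' @return the evaluated, sorted [FinchSwarm-class].
#' @export
evaluateFitness <- function(swarm, objective) {
  obj <- guardObjective(objective)
  n <- nrow(swarm@positions)
  swarm@fitnesses <- vapply(seq_len(n),
                            function(i) obj(swarm@positions[i, ]),
                            numeric(1))
  swarm@evaluations <- swarm@evaluations + n
  swarm <- sortSwarm(swarm)
  refreshBookkeeping(swarm)
}
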