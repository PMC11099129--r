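# The four position-update stages of the falcon finch optimizer. Each
# returns a candidate position clipped to the bounds; acceptance is greedy
# and happens in ffoStep().

#' Producer (foraging) update
#'
#' Safe regime (`T < pAlarm`): componentwise contraction
#' `Y_i * exp(-i / (beta * iterMax))`, with `i = 1..s` the dimension index.
#' Alarmed regime (`T >= pAlarm`): the multiplicative printed form
#' `Y * N` with a single standard-normal draw broadcast over dimensions
#' (the all-ones row `M` carries the scalar to every component); with
#' `ssaCompat = TRUE` the additive sparrow-search original `Y + N` is used
#' instead.
#'
#' @param position numeric length-`s` current position.
#' @param draws a [stageDraws()] list.
#' @param config an [FFOConfig-class].
#' @return numeric length-`s` candidate position, clipped to the bounds.
#' @export
producerUpdate <- function(position, draws, config) {
  s <- length(position)
  cand <- if (draws$T < config@pAlarm) {
    position * exp(-(seq_len(s)) / (draws$beta * config@iterMax))
  } else if (config@ssaCompat) {
    position + draws$N
  } else {
    position * draws$N
  }
  clipToBounds(cand, config@lower, config@upper)
}

#' Scrounger (accumulation) update
#'
#' Starving half (`rank > l/2`): `N * exp((Y_worst - Y) / rank^2)`
#' componentwise. Better half: move to the producers' optimum plus the
#' scalar projection of the distance onto the pseudo-inverse of the random
#' +/-1 row, `Y_opt + sum_j(|Y_j - Y_opt_j| * B+_j)` broadcast over
#' dimensions, so an individual sitting on the optimum stays there.
#'
#' @param swarm an evaluated [FinchSwarm-class].
#' @param rank 1-based fitness rank of the individual (must be a scrounger).
#' @param draws a [stageDraws()] list.
#' @param config an [FFOConfig-class].
#' @return numeric candidate position, clipped to the bounds.
#' @export
scroungerUpdate <- function(swarm, rank, draws, config) {
  l <- nrow(swarm@positions)
  if (rank < 1L || rank > l) stop("rank out of range")
  y <- swarm@positions[rank, ]
  cand <- if (rank > l / 2) {
    draws$N * exp((swarm@worstPosition - y) / rank^2)
  } else {
    bp <- pseudoInverseRow(draws$B)
    swarm@bestPosition + sum(abs(y - swarm@bestPosition) * bp)
  }
  clipToBounds(cand, config@lower, config@upper)
}

#' Soft / hard besiege update
#'
#' Invoked for scroungers in the predator regime (`T >= 0.5`). The selector
#' `z` picks the mode:
#' \itemize{
#' \item `z >= 0.5` (soft besiege): the starving-scrounger kernel, the pull
#'   towards the best scrounger and the pull away from the optimum are mixed
#'   with constants `x1, x2, x3`; the better half keeps the plain
#'   accumulation move.
#' \item `z < 0.5` (hard besiege): `(Y_scr - E|Y_opt - Y| + Y +
#'   Q |Y - Y_worst| / (S_best - S_worst)) / 2` with escape energy
#'   `E = 2 E0 (1 - k/iterMax)`; a vanishing fitness gap in the denominator
#'   is floored at 1e-12 in magnitude (logged via `message`).
#' }
#' Each mode has a rapid-dive companion move `M`; since no dive trigger is
#' defined, the dive is greedy: `M` replaces the base move only when its
#' fitness is better.
#'
#' @param swarm an evaluated [FinchSwarm-class].
#' @param rank 1-based fitness rank (a scrounger).
#' @param draws a [stageDraws()] list.
#' @param config an [FFOConfig-class].
#' @param objective the (already guarded) objective used for the greedy dive
#'   choice.
#' @return numeric candidate position, clipped to the bounds.
#' @export
besiegeUpdate <- function(swarm, rank, draws, config, objective) {
  l <- nrow(swarm@positions)
  if (rank < 1L || rank > l) stop("rank out of range")
  y <- swarm@positions[rank, ]
  yOpt <- swarm@bestPosition
  yScr <- swarm@positions[producerCount(config, l) + 1L, ]  # best scrounger
  yAvg <- swarm@meanPosition
  lam <- config@lambda
  if (draws$z >= 0.5) {
    base <- if (rank > l / 2) {
      config@x1 * (draws$N * exp((swarm@worstPosition - y) / rank^2)) +
        config@x2 * (yScr - y) + config@x3 * (y - yOpt)
    } else {
      bp <- pseudoInverseRow(draws$B)
      yOpt + sum(abs(y - yOpt) * bp)
    }
    dive <- 0.5 * (yScr + draws$T * abs(draws$V * yScr - y) +
                     yAvg + lam * (y - yOpt))
  } else {
    E <- escapeEnergy(draws$E0, swarm@iteration, config@iterMax)
    denom <- swarm@bestFitness - swarm@worstFitness
    if (abs(denom) < 1e-12) {
      if (isTRUE(getOption("falconfinch.verbose")))
        message("besiege: degenerate fitness gap; denominator floored")
      denom <- -1e-12
    }
    base <- 0.5 * (yScr - E * abs(yOpt - y) + y +
                     draws$Q * (abs(y - swarm@worstPosition) / denom))
    dive <- 0.5 * (yScr + (1 + E * draws$V) + y * (lam - E) + yAvg - yOpt)
  }
  base <- clipToBounds(base, config@lower, config@upper)
  dive <- clipToBounds(dive, config@lower, config@upper)
  if (objective(dive) < objective(base)) dive else base
}

#' Perching update
#'
#' The hybridization stage: every individual blends its move with attraction
#' towards the best-known position (the falcon). In the safe regime with the
#' falcon near its family (`T < pAlarm` and `p >= 0.5`):
#' `0.5 Y exp(-i/iterMax) + 0.5 Y_fal - n1 |Y_fal - 2 n2 Y|`, with the
#' dimension index `i = 1..s` in the exponent. Otherwise:
#' `0.5 (Y + N) + 0.5 (Y_prey - Y_avg - n3 (Z_lb + n4 (Z_ub - Z_lb)))`.
#' Both the falcon and the prey positions are bound to the elitist global
#' best.
#'
#' @inheritParams scroungerUpdate
#' @return numeric candidate position, clipped to the bounds.
#' @export
perchingUpdate <- function(swarm, rank, draws, config) {
  l <- nrow(swarm@positions)
  if (rank < 1L || rank > l) stop("rank out of range")
  y <- swarm@positions[rank, ]
  s <- length(y)
  yFal <- swarm@bestPosition          # falcon == prey == global best
  cand <- if (draws$T < config@pAlarm && draws$p >= 0.5) {
    0.5 * y * exp(-(seq_len(s)) / config@iterMax) + 0.5 * yFal -
      draws$n[1] * abs(yFal - 2 * draws$n[2] * y)
  } else {
    0.5 * (y + draws$N) +
      0.5 * (yFal - swarm@meanPosition -
               draws$n[3] * (config@lower +
                               draws$n[4] * (config@upper - config@lower)))
  }
  clipToBounds(cand, config@lower, config@upper)
}
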