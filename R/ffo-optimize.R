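#' One full iteration of the falcon finch optimizer
#'
#' Applies, in order: producer updates (first `producerFraction * l` ranks),
#' scrounger updates with escalation to soft/hard besiege when the alarm
#' draw `T >= 0.5`, and the perching stage for every individual (or only the
#' producers, per `perchScope`). All stage draws for the iteration are
#' consumed up front in rank order (see [stageDraws()]), acceptance after
#' each stage is greedy (an individual keeps its old position when the
#' candidate's fitness is worse), bookkeeping is refreshed between stages and
#' the population is re-sorted by fitness at the end.
#'
#' @param swarm an evaluated [FinchSwarm-class].
#' @param objective objective function (minimized).
#' @param config an [FFOConfig-class].
#' @return the updated [FinchSwarm-class] with `iteration` incremented.
#' @export
ffoStep <- function(swarm, objective, config) {
  if (anyNA(swarm@fitnesses))
    stop("swarm must be evaluated before stepping")
  l <- nrow(swarm@positions)
  nEval <- 0L
  obj0 <- guardObjective(objective)
  obj <- function(x) { nEval <<- nEval + 1L; obj0(x) }

  draws <- lapply(seq_len(l), function(i)
    stageDraws(config@s, config@e0Range, config@vMax))
  nP <- producerCount(config, l)

  acceptIf <- function(rank, cand) {
    f <- obj(cand)
    if (f <= swarm@fitnesses[rank]) {
      swarm@positions[rank, ] <<- cand
      swarm@fitnesses[rank] <<- f
    }
  }

  for (r in seq_len(nP))
    acceptIf(r, producerUpdate(swarm@positions[r, ], draws[[r]], config))
  swarm <- refreshBookkeeping(swarm)

  for (r in seq.int(nP + 1L, l)) {
    cand <- if (config@besiegeEnabled && draws[[r]]$T >= 0.5)
      besiegeUpdate(swarm, r, draws[[r]], config, obj)
    else
      scroungerUpdate(swarm, r, draws[[r]], config)
    acceptIf(r, cand)
  }
  swarm <- refreshBookkeeping(swarm)

  if (config@perchingEnabled) {
    perchSet <- if (config@perchScope == "producers") seq_len(nP) else seq_len(l)
    for (r in perchSet)
      acceptIf(r, perchingUpdate(swarm, r, draws[[r]], config))
    swarm <- refreshBookkeeping(swarm)
  }

  swarm <- sortSwarm(swarm)
  swarm@iteration <- swarm@iteration + 1L
  swarm@evaluations <- swarm@evaluations + nEval
  swarm
}

#' Run the falcon finch optimizer
#'
#' Seeds the RNG from the config, initializes and evaluates the population,
#' runs exactly `iterMax` iterations (the published procedure has no other
#' stopping rule) and returns the elitist best with the full convergence
#' history. Two runs with the same config are bit-identical.
#'
#' @param objective function from a length-`s` numeric vector to a scalar;
#'   minimized. Maximize by negating your objective.
#' @param config an [FFOConfig-class].
#' @return an [OptimizationResult-class].
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- ffoOptimize(sphere, ffoConfig(s = 2, lower = -5, upper = 5,
#'                                      l = 10, iterMax = 25, seed = 1))
#' bestFitness(res)
#' @export
ffoOptimize <- function(objective, config) {
  validObject(config)
  withSeed(config@seed, {
    swarm <- initializeSwarm(config)
    swarm <- evaluateFitness(swarm, objective)
    history <- numeric(config@iterMax)
    for (k in seq_len(config@iterMax)) {
      swarm <- ffoStep(swarm, objective, config)
      history[k] <- swarm@bestFitness
    }
    new("OptimizationResult",
        bestPosition = swarm@bestPosition, bestFitness = swarm@bestFitness,
        convergenceHistory = history, evaluations = swarm@evaluations,
        config = config, seed = config@seed)
  })
}

#' Serialize an optimization result
#'
#' `writeOptimizationResult` writes a JSON document (best position/fitness,
#' convergence history, evaluation count, seed and a config echo);
#' `writeConvergenceCSV` writes the per-iteration best as a two-column CSV.
#'
#' @param result an [OptimizationResult-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeOptimizationResult <- function(result, path) {
  cfg <- result@config
  doc <- list(
    best_position = result@bestPosition,
    best_fitness = result@bestFitness,
    convergence_history = result@convergenceHistory,
    evaluations = result@evaluations,
    seed = result@seed,
    config = list(l = cfg@l, s = cfg@s, iterMax = cfg@iterMax,
                  lower = cfg@lower, upper = cfg@upper,
                  pAlarm = cfg@pAlarm, lambda = cfg@lambda,
                  x1 = cfg@x1, x2 = cfg@x2, x3 = cfg@x3,
                  producerFraction = cfg@producerFraction,
                  ssaCompat = cfg@ssaCompat,
                  besiegeEnabled = cfg@besiegeEnabled,
                  perchingEnabled = cfg@perchingEnabled,
                  perchScope = cfg@perchScope))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeOptimizationResult
#' @export
writeConvergenceCSV <- function(result, path) {
  utils::write.csv(
    data.frame(iteration = seq_along(result@convergenceHistory),
               best_fitness = result@convergenceHistory),
    path, row.names = FALSE)
  invisible(path)
}
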