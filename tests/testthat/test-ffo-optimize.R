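# The outer optimization loop: convergence, invariants, reduced modes.

test_that("the optimizer solves the sphere to the spec tolerance", {
  cfg <- ffoConfig(s = 2, lower = -5, upper = 5, l = 30L, iterMax = 200L,
                   seed = 1L)
  res <- ffoOptimize(sphereFn, cfg)
  expect_lt(bestFitness(res), 1e-3)
  expect_length(convergenceHistory(res), 200L)
  expect_true(all(diff(convergenceHistory(res)) <= 0))
})

test_that("elitism, bound feasibility and determinism hold on random configs", {
  set.seed(99)
  objs <- list(sphereFn, rastriginFn,
               function(x) sum(abs(x - 0.5)),
               function(x) sum((x - 1)^4) + sum(x))
  for (case in 1:100) {
    s <- sample(1:4, 1)
    l <- sample(4:10, 1)
    lo <- runif(s, -4, 0); up <- lo + runif(s, 0.5, 6)
    seed <- sample.int(10000, 1)
    cfg <- ffoConfig(s = s, lower = lo, upper = up, l = l,
                     iterMax = 5L, seed = seed,
                     producerFraction = runif(1, 0.1, 0.8))
    obj <- objs[[sample.int(length(objs), 1)]]
    res <- ffoOptimize(obj, cfg)
    hist <- convergenceHistory(res)
    expect_true(all(diff(hist) <= 0))                      # elitism
    expect_true(all(bestPosition(res) >= lo - 1e-12 &
                      bestPosition(res) <= up + 1e-12))    # feasibility
  }
  # bit-identical reruns under a fixed seed
  cfg <- ffoConfig(s = 3, lower = -2, upper = 2, l = 12L, iterMax = 20L,
                   seed = 123L)
  r1 <- ffoOptimize(rastriginFn, cfg)
  r2 <- ffoOptimize(rastriginFn, cfg)
  expect_identical(convergenceHistory(r1), convergenceHistory(r2))
  expect_identical(bestPosition(r1), bestPosition(r2))
})

test_that("positions stay in bounds after a single step", {
  set.seed(4)
  cfg <- ffoConfig(s = 3, lower = c(-1, 0, 2), upper = c(1, 0.5, 5),
                   l = 10L, iterMax = 10L)
  sw <- evaluateFitness(initializeSwarm(cfg), sphereFn)
  before <- bestFitness(sw)
  sw2 <- ffoStep(sw, sphereFn, cfg)
  expect_lte(bestFitness(sw2), before)
  expect_true(all(sweep(positions(sw2), 2, cfg@lower, `>=`)))
  expect_true(all(sweep(positions(sw2), 2, cfg@upper, `<=`)))
  expect_identical(iteration(sw2), 1L)
})

test_that("reduced sparrow-search mode matches the standalone oracle", {
  for (seed in 1:10) {
    cfg <- ffoConfig(s = 2, lower = -3, upper = 3, l = 8L, iterMax = 15L,
                     seed = seed, besiegeEnabled = FALSE,
                     perchingEnabled = FALSE)
    res <- ffoOptimize(sphereFn, cfg)
    ora <- ssaOracle(sphereFn, l = 8, s = 2, lower = rep(-3, 2),
                     upper = rep(3, 2), iterMax = 15, seed = seed)
    expect_equal(convergenceHistory(res), ora$history, tolerance = 1e-12)
  }
})

test_that("producer-only dynamics reduce to the pure foraging recursion", {
  # producerFraction ~ 1 (all but one individual are producers), alarmed
  # branch suppressed by pAlarm ~ 1 so T < pAlarm always: every producer
  # contracts multiplicatively; the trajectory must match a standalone loop
  seed <- 21L
  cfg <- ffoConfig(s = 2, lower = -4, upper = 4, l = 6L, iterMax = 8L,
                   seed = seed, producerFraction = 0.999, pAlarm = 0.999,
                   besiegeEnabled = FALSE, perchingEnabled = FALSE)
  res <- ffoOptimize(sphereFn, cfg)
  # oracle loop
  set.seed(seed)
  l <- 6; s <- 2; iterMax <- 8
  pos <- matrix(runif(l * s), nrow = l)
  pos <- sweep(sweep(pos, 2, rep(8, s), `*`), 2, rep(-4, s), `+`)
  fit <- apply(pos, 1, sphereFn)
  ord <- order(fit); pos <- pos[ord, ]; fit <- fit[ord]
  gBestF <- fit[1]
  hist <- numeric(iterMax)
  for (k in seq_len(iterMax)) {
    draws <- lapply(seq_len(l), function(i)
      list(T = runif(1), z = runif(1), p = runif(1), beta = 1 - runif(1),
           N = rnorm(1), n = runif(4), E0 = runif(1, -1, 1),
           V = runif(1, 0, 2), Q = rnorm(1), B = ifelse(runif(s) < 0.5, -1, 1)))
    for (r in 1:(l - 1)) {
      cand <- pmin(pmax(pos[r, ] * exp(-(1:s) / (draws[[r]]$beta * iterMax)),
                        -4), 4)
      f <- sphereFn(cand)
      if (f <= fit[r]) { pos[r, ] <- cand; fit[r] <- f }
    }
    gBestF <- min(gBestF, min(fit))
    # the single scrounger (rank l > l/2): starving kernel
    worst <- pos[which.max(fit), ]
    cand <- pmin(pmax(draws[[l]]$N * exp((worst - pos[l, ]) / l^2), -4), 4)
    f <- sphereFn(cand)
    if (f <= fit[l]) { pos[l, ] <- cand; fit[l] <- f }
    gBestF <- min(gBestF, min(fit))
    ord <- order(fit); pos <- pos[ord, ]; fit <- fit[ord]
    hist[k] <- gBestF
  }
  expect_equal(convergenceHistory(res), hist, tolerance = 1e-12)
})

test_that("a zero iteration budget returns the best of the initial population", {
  cfg <- ffoConfig(s = 2, lower = -5, upper = 5, l = 10L, iterMax = 0L,
                   seed = 3L)
  res <- ffoOptimize(sphereFn, cfg)
  expect_length(convergenceHistory(res), 0L)
  set.seed(3)
  sw <- evaluateFitness(initializeSwarm(cfg), sphereFn)
  expect_equal(bestFitness(res), bestFitness(sw))
  expect_identical(evaluations(res), 10L)
})

test_that("the optimizer beats random search on the rastrigin surface", {
  ffoBest <- numeric(20); rsBest <- numeric(20)
  for (seed in 1:20) {
    cfg <- ffoConfig(s = 2, lower = -5.12, upper = 5.12, l = 30L,
                     iterMax = 200L, seed = seed)
    res <- ffoOptimize(rastriginFn, cfg)
    ffoBest[seed] <- bestFitness(res)
    rsBest[seed] <- randomSearchBest(rastriginFn, rep(-5.12, 2),
                                     rep(5.12, 2), evaluations(res),
                                     seed = seed + 5000)
  }
  expect_lt(median(ffoBest), median(rsBest))
})

test_that("config round-trips through YAML and results serialize", {
  cfg <- ffoConfig(s = 2, lower = c(-1, 0), upper = c(1, 2), l = 12L,
                   iterMax = 7L, seed = 9L, ssaCompat = TRUE,
                   perchScope = "producers")
  tmp <- tempfile(fileext = ".yaml")
  writeFFOConfig(cfg, tmp)
  cfg2 <- readFFOConfig(tmp)
  expect_equal(cfg2@lower, cfg@lower)
  expect_equal(cfg2@iterMax, cfg@iterMax)
  expect_true(cfg2@ssaCompat)
  expect_equal(cfg2@perchScope, "producers")
  res <- ffoOptimize(sphereFn, cfg)
  jt <- tempfile(fileext = ".json"); ct <- tempfile(fileext = ".csv")
  writeOptimizationResult(res, jt)
  writeConvergenceCSV(res, ct)
  doc <- jsonlite::read_json(jt, simplifyVector = TRUE)
  expect_equal(doc$best_fitness, bestFitness(res))
  expect_equal(length(doc$convergence_history), 7L)
  tab <- read.csv(ct)
  expect_equal(tab$best_fitness, convergenceHistory(res))
})
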