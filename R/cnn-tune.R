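#' Tune the output layer with the falcon finch optimizer
#'
#' Flattens the final dense layer's weights and biases (64 * 2 + 2 = 130
#' values) into the optimizer's decision vector and minimizes the model's
#' MSE on the supplied tuning fold. The activations feeding the output layer
#' do not depend on the tuned parameters, so they are computed once and the
#' fitness reduces to a cheap 64 x 2 affine map plus softmax. The current
#' head is injected into the initial population and write-back is greedy, so
#' the returned model's tuning-fold fitness never exceeds the input model's.
#'
#' @param model a trained [TrainedModel-class].
#' @param x tuning-fold input batch (`H x W x C x N` array).
#' @param y tuning-fold `N x 2` one-hot targets.
#' @param config optional [FFOConfig-class]; a dimension other than the
#'   head's 130 parameters is auto-corrected with a message. By default a
#'   config with `l = 30`, `iterMax = iterMax`, box `current +/- (1 + |current|)`
#'   and the given seed is built.
#' @param iterMax iterations for the default config (default 20).
#' @param seed seed for the default config (default 1).
#' @return the tuned [TrainedModel-class].
#' @export
ffoTune <- function(model, x, y, config = NULL, iterMax = 20L, seed = 1L) {
  layers <- model@spec@layers
  iLast <- length(layers)
  if (layers[[iLast]]@kind != "dense")
    stop("final layer must be dense")
  if (iterMax == 0L && is.null(config)) return(model)

  # cache the penultimate activations once (input of the final dense layer)
  A <- forwardModel(model, x, training = FALSE)$caches[[iLast]]$ain

  W0 <- model@weights[[iLast]]$W
  b0 <- model@weights[[iLast]]$b
  w0 <- c(as.numeric(W0), b0)
  nW <- length(W0)
  dims <- dim(W0)

  fitness <- function(w) {
    W <- matrix(w[seq_len(nW)], dims[1], dims[2])
    b <- w[(nW + 1):length(w)]
    p <- softmaxRows(sweep(A %*% W, 2, b, `+`))
    mean((p - y)^2)
  }

  s <- length(w0)
  if (is.null(config)) {
    r <- 1 + abs(w0)
    config <- ffoConfig(s = s, lower = w0 - r, upper = w0 + r, l = 30L,
                        iterMax = as.integer(iterMax), seed = seed,
                        initGuess = w0)
  } else if (config@s != s) {
    message("ffoTune: config dimension ", config@s,
            " corrected to head size ", s)
    config <- ffoConfig(s = s, lower = rep(min(config@lower), s),
                        upper = rep(max(config@upper), s), l = config@l,
                        iterMax = config@iterMax, pAlarm = config@pAlarm,
                        lambda = config@lambda, seed = config@seed,
                        initGuess = w0)
  }
  if (config@iterMax == 0L) return(model)

  res <- ffoOptimize(fitness, config)
  wBest <- bestPosition(res)
  if (fitness(wBest) <= fitness(w0)) {
    model@weights[[iLast]]$W <- matrix(wBest[seq_len(nW)], dims[1], dims[2])
    model@weights[[iLast]]$b <- wBest[(nW + 1):length(wBest)]
  }
  model
}
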