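# Minimal CNN engine (forward / backward / Adam) sized for the 22 x 11
# feature planes of the lesion classifier. Activations are H x W x C x N
# arrays until flatten, then N x F matrices.

# ---- primitive ops ----

# kernel offset ko = 1..9 <-> (di, dj), di fastest.
convOffsets <- cbind(di = rep(0:2, 3), dj = rep(0:2, each = 3))

# Row-index vectors into the zero-padded (H+2) x (W+2) x N plane (laid out as
# a ((H+2)(W+2)N) x C matrix) for each kernel offset; cached per shape.
.convIdxCache <- new.env(parent = emptyenv())
convIndices <- function(H, W, N) {
  key <- sprintf("%d_%d_%d", H, W, N)
  got <- .convIdxCache[[key]]
  if (!is.null(got)) return(got)
  Hp <- H + 2L; Wp <- W + 2L
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  planeOff <- rep((seq_len(N) - 1L) * Hp * Wp, each = H * W)
  idx <- lapply(1:9, function(ko) {
    di <- convOffsets[ko, 1]; dj <- convOffsets[ko, 2]
    base <- (i + di) + (j + dj - 1L) * Hp
    rep(base, N) + planeOff
  })
  .convIdxCache[[key]] <- idx
  idx
}

# 3x3 same-padded conv over a batch: activations move through a
# ((H W N) x C) matrix layout so each kernel offset is one row-gather plus
# one GEMM against the (Cin x Cout) weight slice.
convForward <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]; N <- d[4]
  Cout <- dim(W)[4]
  idx <- convIndices(H, Wd, N)
  xp <- aperm(x, c(1, 2, 4, 3))                 # (H, W, N, Cin)
  pad <- array(0, c(H + 2L, Wd + 2L, N, Cin))
  pad[2:(H + 1), 2:(Wd + 1), , ] <- xp
  dim(pad) <- c((H + 2L) * (Wd + 2L) * N, Cin)
  Y <- matrix(rep(b, each = H * Wd * N), H * Wd * N, Cout)
  xs <- vector("list", 9L)
  for (ko in 1:9) {
    Wk <- matrix(W[convOffsets[ko, 1] + 1L, convOffsets[ko, 2] + 1L, , ],
                 Cin, Cout)
    xs[[ko]] <- pad[idx[[ko]], , drop = FALSE]
    Y <- Y + xs[[ko]] %*% Wk
  }
  dim(Y) <- c(H, Wd, N, Cout)
  list(out = aperm(Y, c(1, 2, 4, 3)),
       cache = list(xs = xs, dimx = d))
}

convBackward <- function(dout, W, cache) {
  d <- cache$dimx; H <- d[1]; Wd <- d[2]; Cin <- d[3]; N <- d[4]
  Cout <- dim(W)[4]
  idx <- convIndices(H, Wd, N)
  dY <- aperm(dout, c(1, 2, 4, 3))
  dim(dY) <- c(H * Wd * N, Cout)
  dW <- array(0, dim(W))
  dpad <- matrix(0, (H + 2L) * (Wd + 2L) * N, Cin)
  for (ko in 1:9) {
    di <- convOffsets[ko, 1] + 1L; dj <- convOffsets[ko, 2] + 1L
    Wk <- matrix(W[di, dj, , ], Cin, Cout)
    dW[di, dj, , ] <- crossprod(cache$xs[[ko]], dY)
    dpad[idx[[ko]], ] <- dpad[idx[[ko]], , drop = FALSE] + dY %*% t(Wk)
  }
  dim(dpad) <- c(H + 2L, Wd + 2L, N, Cin)
  dx <- dpad[2:(H + 1), 2:(Wd + 1), , , drop = FALSE]
  list(dx = aperm(dx, c(1, 2, 4, 3)), dW = dW, db = colSums(dY))
}

# Shape-preserving max pool (pool 2, stride 1, windows clamped at the
# bottom/right border), done separably: row stage then column stage.
maxpoolForward <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  sU <- x[c(seq_len(H - 1) + 1L, H), , , , drop = FALSE]   # row below (clamped)
  rm_ <- pmax(x, sU)
  sL <- rm_[, c(seq_len(W - 1) + 1L, W), , , drop = FALSE] # column right
  out <- pmax(rm_, sL)
  list(out = out, cache = list(mA = x >= sU, mB = rm_ >= sL))
}

maxpoolBackward <- function(dout, cache) {
  H <- dim(dout)[1]; W <- dim(dout)[2]
  # column stage adjoint (the clamped border column always routes to self)
  dR <- dout * cache$mB
  v <- dout * !cache$mB
  dR[, 2:W, , ] <- dR[, 2:W, , , drop = FALSE] +
    v[, seq_len(W - 1), , , drop = FALSE]
  # row stage adjoint
  dx <- dR * cache$mA
  w <- dR * !cache$mA
  dx[2:H, , , ] <- dx[2:H, , , , drop = FALSE] +
    w[seq_len(H - 1), , , , drop = FALSE]
  dx
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- model construction ----

#' Build an (untrained) model from a network specification
#'
#' Initializes conv and dense weights with Glorot-uniform draws from the
#' given seed; biases start at zero. The same seed always yields identical
#' initial weights.
#'
#' @param spec a [NetworkSpec-class].
#' @param seed initialization seed.
#' @return a [TrainedModel-class] with empty training history.
#' @export
buildModel <- function(spec, seed = 1L) {
  validObject(spec)
  shapes <- outputShapes(spec)
  withSeed(seed, {
    weights <- vector("list", length(spec@layers))
    shape <- spec@inputShape
    for (i in seq_along(spec@layers)) {
      ly <- spec@layers[[i]]
      if (ly@kind == "conv") {
        fanIn <- ly@kernel[1] * ly@kernel[2] * shape[3]
        fanOut <- ly@kernel[1] * ly@kernel[2] * ly@filters
        lim <- sqrt(6 / (fanIn + fanOut))
        weights[[i]] <- list(
          W = array(stats::runif(ly@kernel[1] * ly@kernel[2] * shape[3] *
                                   ly@filters, -lim, lim),
                    c(ly@kernel[1], ly@kernel[2], shape[3], ly@filters)),
          b = numeric(ly@filters))
      } else if (ly@kind == "dense") {
        lim <- sqrt(6 / (shape[1] + ly@filters))
        weights[[i]] <- list(
          W = matrix(stats::runif(shape[1] * ly@filters, -lim, lim),
                     shape[1], ly@filters),
          b = numeric(ly@filters))
      } else weights[[i]] <- list()
      shape <- shapes[[i]]
    }
    new("TrainedModel", spec = spec, weights = weights,
        history = numeric(), seed = as.integer(seed))
  })
}

# Forward pass. training = TRUE enables dropout (consumes RNG).
forwardModel <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model@spec@layers))
  a <- x
  for (i in seq_along(model@spec@layers)) {
    ly <- model@spec@layers[[i]]
    if (ly@kind == "conv") {
      cf <- convForward(a, model@weights[[i]]$W, model@weights[[i]]$b)
      pre <- cf$out
      a <- if (ly@activation == "relu") pmax(pre, 0) else pre
      caches[[i]] <- list(conv = cf$cache, pre = pre)
    } else if (ly@kind == "maxpool") {
      mp <- maxpoolForward(a)
      a <- mp$out
      caches[[i]] <- mp$cache
    } else if (ly@kind == "dropout") {
      if (training && ly@rate > 0) {
        mask <- array((stats::runif(length(a)) >= ly@rate) / (1 - ly@rate),
                      dim(a))
        a <- a * mask
        caches[[i]] <- list(mask = mask)
      } else caches[[i]] <- list(mask = NULL)
    } else if (ly@kind == "flatten") {
      d <- dim(a)
      caches[[i]] <- list(dimx = d)
      a <- t(matrix(a, prod(d[1:3]), d[4]))
    } else if (ly@kind == "dense") {
      z <- sweep(a %*% model@weights[[i]]$W, 2, model@weights[[i]]$b, `+`)
      out <- switch(ly@activation,
                    relu = pmax(z, 0),
                    softmax = softmaxRows(z),
                    z)
      caches[[i]] <- list(ain = a, z = z, out = out)
      a <- out
    }
  }
  list(out = a, caches = caches)
}

# Backward pass from dL/d(final activation); returns per-layer grads.
backwardModel <- function(model, caches, dout) {
  layers <- model@spec@layers
  grads <- vector("list", length(layers))
  d <- dout
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly@kind == "dense") {
      cc <- caches[[i]]
      dz <- if (ly@activation == "softmax") {
        p <- cc$out
        p * (d - rowSums(d * p))
      } else if (ly@activation == "relu") {
        d * (cc$z > 0)
      } else d
      grads[[i]] <- list(dW = crossprod(cc$ain, dz), db = colSums(dz))
      d <- dz %*% t(model@weights[[i]]$W)
    } else if (ly@kind == "flatten") {
      d <- array(t(d), caches[[i]]$dimx)
    } else if (ly@kind == "dropout") {
      if (!is.null(caches[[i]]$mask)) d <- d * caches[[i]]$mask
      grads[[i]] <- list()
    } else if (ly@kind == "maxpool") {
      d <- maxpoolBackward(d, caches[[i]])
      grads[[i]] <- list()
    } else if (ly@kind == "conv") {
      cc <- caches[[i]]
      if (ly@activation == "relu") d <- d * (cc$pre > 0)
      cb <- convBackward(d, model@weights[[i]]$W, cc$conv)
      grads[[i]] <- list(dW = cb$dW, db = cb$db)
      d <- cb$dx
    }
  }
  grads
}

#' Reshape a feature vector to the classifier's input plane
#'
#' Zero-pads the vector to length 242 and fills a 22 x 11 x 1 plane
#' row-major (a length-109 vector leaves 133 trailing zeros).
#'
#' @param v numeric vector of length at most 242.
#' @return a 22 x 11 x 1 numeric array.
#' @export
reshapeFeatures <- function(v) {
  v <- as.numeric(v)
  if (length(v) > 242L) stop("feature vector longer than 242")
  v <- c(v, numeric(242L - length(v)))
  array(matrix(v, nrow = 22L, byrow = TRUE), c(22L, 11L, 1L))
}

#' Stack feature vectors into a model input batch
#'
#' @param m numeric matrix, one feature vector per row.
#' @return a 22 x 11 x 1 x N array.
#' @export
featuresToInput <- function(m) {
  m <- as.matrix(m)
  out <- array(0, c(22L, 11L, 1L, nrow(m)))
  for (n in seq_len(nrow(m))) out[, , , n] <- reshapeFeatures(m[n, ])
  out
}

#' Predict class probabilities
#'
#' Forward pass in evaluation mode (dropout off).
#'
#' @param model a [TrainedModel-class].
#' @param x input batch, `H x W x C x N` array.
#' @return `N x 2` matrix of probabilities (columns: benign, malignant).
#' @export
predictModel <- function(model, x) {
  p <- forwardModel(model, x, training = FALSE)$out
  colnames(p) <- c("benign", "malignant")
  p
}

#' Mean squared error of a model on a labelled batch
#'
#' @param model a [TrainedModel-class].
#' @param x input batch.
#' @param y `N x 2` one-hot target matrix.
#' @return scalar MSE between predicted probabilities and targets.
#' @export
modelMSE <- function(model, x, y) {
  p <- forwardModel(model, x, training = FALSE)$out
  mean((p - y)^2)
}

#' Train a model by minibatch gradient descent
#'
#' Adam updates against the spec's loss (MSE between the softmax output and
#' one-hot targets), with per-epoch shuffling and dropout, all driven by the
#' given seed (fixed seed, fixed history). `epochs = 0` returns the model
#' unchanged. A single-class target matrix triggers a warning but training
#' proceeds.
#'
#' @param model a [TrainedModel-class].
#' @param x input batch, `H x W x C x N` array.
#' @param y `N x 2` one-hot target matrix.
#' @param epochs number of epochs (default: the spec's).
#' @param batchSize minibatch size (default: the spec's).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed training seed (shuffling + dropout).
#' @return the trained [TrainedModel-class] with loss history appended.
#' @export
trainModel <- function(model, x, y, epochs = NULL, batchSize = NULL,
                       lr = 1e-3, seed = 1L) {
  spec <- model@spec
  if (is.null(epochs)) epochs <- spec@epochs
  if (is.null(batchSize)) batchSize <- spec@batchSize
  if (epochs == 0L) return(model)
  N <- dim(x)[4]
  if (nrow(y) != N) stop("x and y disagree on sample count")
  if (length(unique(max.col(y))) < 2L)
    warning("single-class targets: later sensitivity/specificity degenerate",
            call. = FALSE)

  adamState <- list()
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8; tA <- 0
  applyAdam <- function(key, w, g) {
    st <- adamState[[key]]
    if (is.null(st)) st <- list(m = w * 0, v = w * 0)
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    adamState[[key]] <<- st
    mh <- st$m / (1 - b1^tA); vh <- st$v / (1 - b2^tA)
    w - lr * mh / (sqrt(vh) + epsA)
  }

  withSeed(seed, {
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      losses <- c()
      for (start in seq(1, N, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1, N)]
        xb <- x[, , , idx, drop = FALSE]
        yb <- y[idx, , drop = FALSE]
        fw <- forwardModel(model, xb, training = TRUE)
        loss <- mean((fw$out - yb)^2)
        losses <- c(losses, loss)
        dout <- 2 * (fw$out - yb) / length(yb)
        grads <- backwardModel(model, fw$caches, dout)
        tA <- tA + 1
        for (i in seq_along(grads)) {
          if (is.null(grads[[i]]$dW)) next
          model@weights[[i]]$W <-
            applyAdam(paste0("W", i), model@weights[[i]]$W, grads[[i]]$dW)
          model@weights[[i]]$b <-
            applyAdam(paste0("b", i), model@weights[[i]]$b, grads[[i]]$db)
        }
      }
      history[ep] <- mean(losses)
    }
    model@history <- c(model@history, history)
    model
  })
}

#' Save / load a model
#'
#' Writes the weights in R's native serialization alongside a portable JSON
#' manifest of the architecture and its per-layer parameter counts.
#'
#' @param model a [TrainedModel-class].
#' @param dir output directory (created if needed).
#' @return `saveModel`: `dir` invisibly; `loadModel`: a
#'   [TrainedModel-class].
#' @export
saveModel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pc <- countParameters(model@spec)
  manifest <- list(
    input_shape = model@spec@inputShape,
    layers = lapply(model@spec@layers, function(ly)
      list(kind = ly@kind, filters = ly@filters,
           kernel = ly@kernel, activation = ly@activation, rate = ly@rate)),
    loss = model@spec@loss, optimizer = model@spec@optimizer,
    batch_size = model@spec@batchSize, epochs = model@spec@epochs,
    parameters_per_layer = as.list(pc$perLayer), parameters_total = pc$total,
    seed = model@seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(list(weights = model@weights, history = model@history),
          file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  layers <- lapply(seq_len(nrow(man$layers)), function(i)
    layerSpec(man$layers$kind[i], man$layers$filters[i],
              man$layers$kernel[[i]], man$layers$activation[i],
              man$layers$rate[i]))
  spec <- networkSpec(layers, man$input_shape, man$loss, man$optimizer,
                      man$batch_size, man$epochs)
  blob <- readRDS(file.path(dir, "weights.rds"))
  new("TrainedModel", spec = spec, weights = blob$weights,
      history = blob$history, seed = as.integer(man$seed))
}
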