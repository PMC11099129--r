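#' Construct a layer specification
#'
#' @param kind `"conv"`, `"maxpool"`, `"dropout"`, `"flatten"` or `"dense"`.
#' @param filters conv filters or dense units.
#' @param kernel integer length-2 kernel (conv only; default 3 x 3).
#' @param activation `"relu"`, `"softmax"` or `"none"`.
#' @param rate dropout rate in `[0, 1)`.
#' @return a [LayerSpec-class].
#' @export
layerSpec <- function(kind, filters = 0L, kernel = c(3L, 3L),
                      activation = "none", rate = 0) {
  new("LayerSpec", kind = kind, filters = as.integer(filters),
      kernel = as.integer(kernel), activation = activation,
      rate = as.numeric(rate))
}

#' Construct a network specification
#'
#' @param layers list of [LayerSpec-class].
#' @param inputShape integer `(H, W, C)`.
#' @param loss loss name (default `"mse"`).
#' @param optimizer optimizer name (default `"adam"`).
#' @param batchSize minibatch size (default 32).
#' @param epochs training epochs (default 100).
#' @return a [NetworkSpec-class].
#' @export
networkSpec <- function(layers, inputShape, loss = "mse", optimizer = "adam",
                        batchSize = 32L, epochs = 100L) {
  new("NetworkSpec", layers = layers, inputShape = as.integer(inputShape),
      loss = loss, optimizer = optimizer, batchSize = as.integer(batchSize),
      epochs = as.integer(epochs))
}

#' The canonical lesion-classifier architecture
#'
#' Reconstructs the published parameter table: a 22 x 11 x 1 input plane
#' through three 3 x 3 same-padded ReLU conv blocks (16, 32, 64 filters),
#' each followed by a shape-preserving max-pool (pool 2, stride 1, same
#' padding — the table shows identical shapes before and after pooling),
#' then dropout, flatten (width 15,488), a 64-unit ReLU dense layer and the
#' 2-unit softmax output. Per-layer parameter counts are
#' 160 / 0 / 4,640 / 0 / 18,496 / 0 / 0 / 0 / 991,296 / 130. The 3 x 3
#' kernel and single input channel are the only reconstruction consistent
#' with those printed counts (160 = 3*3*1*16 + 16).
#'
#' @param dropoutRate dropout rate (default 0.25).
#' @return a [NetworkSpec-class].
#' @examples
#' countParameters(canonicalSpec())$total
#' @export
canonicalSpec <- function(dropoutRate = 0.25) {
  networkSpec(
    layers = list(
      layerSpec("conv", 16L, activation = "relu"),
      layerSpec("maxpool"),
      layerSpec("conv", 32L, activation = "relu"),
      layerSpec("maxpool"),
      layerSpec("conv", 64L, activation = "relu"),
      layerSpec("maxpool"),
      layerSpec("dropout", rate = dropoutRate),
      layerSpec("flatten"),
      layerSpec("dense", 64L, activation = "relu"),
      layerSpec("dense", 2L, activation = "softmax")
    ),
    inputShape = c(22L, 11L, 1L))
}

# Propagate shapes through the layer list; errors name the offending layer.
#' @rdname outputShapes
#' @export
setMethod("outputShapes", "NetworkSpec", function(spec) {
  shape <- spec@inputShape
  out <- vector("list", length(spec@layers))
  for (i in seq_along(spec@layers)) {
    ly <- spec@layers[[i]]
    shape <- switch(ly@kind,
      conv = {
        if (length(shape) != 3L)
          stop("layer ", i, " (conv): needs a 3-d input, got rank ",
               length(shape))
        c(shape[1], shape[2], ly@filters)
      },
      maxpool = ,
      dropout = shape,
      flatten = {
        prod(shape)
      },
      dense = {
        if (length(shape) != 1L)
          stop("layer ", i, " (dense): needs a flat input, got rank ",
               length(shape))
        ly@filters
      },
      stop("layer ", i, ": unknown kind '", ly@kind, "'"))
    out[[i]] <- as.integer(shape)
  }
  out
})

#' @rdname countParameters
#' @export
setMethod("countParameters", "NetworkSpec", function(spec) {
  shapes <- outputShapes(spec)
  inC <- spec@inputShape[3]
  inFlat <- NA_integer_
  per <- integer(length(spec@layers))
  names(per) <- vapply(spec@layers, function(x) x@kind, character(1))
  shape <- spec@inputShape
  for (i in seq_along(spec@layers)) {
    ly <- spec@layers[[i]]
    per[i] <- switch(ly@kind,
      conv = ly@kernel[1] * ly@kernel[2] * shape[3] * ly@filters + ly@filters,
      dense = shape[1] * ly@filters + ly@filters,
      0L)
    shape <- shapes[[i]]
  }
  list(perLayer = per, total = sum(per))
})
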