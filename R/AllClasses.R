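#' @import methods
NULL

#' Configuration for falcon finch optimization
#'
#' Holds every algorithm constant of the falcon finch optimizer: population
#' geometry, box bounds, the safety threshold `pAlarm`, the besiege constants,
#' the producer share, stage switches and the RNG seed. Build instances with
#' [ffoConfig()].
#'
#' @slot l integer, population size.
#' @slot s integer, decision-space dimension.
#' @slot iterMax integer, number of iterations to run.
#' @slot lower,upper numeric length-`s` box bounds.
#' @slot pAlarm numeric in (0,1), safety threshold compared against the alarm
#'   draw `T`; default 0.5.
#' @slot lambda numeric, besiege constant; default 0.5.
#' @slot x1,x2,x3 numeric, soft-besiege mixing constants (default 1/3 each).
#' @slot producerFraction numeric in (0,1), share of the population acting as
#'   producers; default 0.2.
#' @slot seed integer RNG seed.
#' @slot e0Range numeric length 2, interval for the initial escape energy E0.
#' @slot vMax numeric, upper end of the uniform jump-strength draw V.
#' @slot ssaCompat logical, use the additive sparrow-search form of the
#'   alarmed producer move instead of the multiplicative form.
#' @slot besiegeEnabled logical, allow scroungers to escalate to soft/hard
#'   besiege.
#' @slot perchingEnabled logical, apply the perching stage.
#' @slot perchScope character, `"all"` or `"producers"`: who perches.
#' @slot initGuess numeric length `s` or length 0; if given, injected as the
#'   first individual of the initial population.
#' @export
setClass("FFOConfig",
  representation(
    l = "integer", s = "integer", iterMax = "integer",
    lower = "numeric", upper = "numeric",
    pAlarm = "numeric", lambda = "numeric",
    x1 = "numeric", x2 = "numeric", x3 = "numeric",
    producerFraction = "numeric", seed = "integer",
    e0Range = "numeric", vMax = "numeric",
    ssaCompat = "logical", besiegeEnabled = "logical",
    perchingEnabled = "logical", perchScope = "character",
    initGuess = "numeric"
  )
)

setValidity("FFOConfig", function(object) {
  msg <- character()
  if (object@l < 2L) msg <- c(msg, "population size l must be >= 2")
  if (object@s < 1L) msg <- c(msg, "dimension s must be >= 1")
  if (object@iterMax < 0L) msg <- c(msg, "iterMax must be >= 0")
  if (length(object@lower) != object@s || length(object@upper) != object@s)
    msg <- c(msg, "lower/upper bounds must have length s")
  if (!all(is.finite(object@lower)) || !all(is.finite(object@upper)))
    msg <- c(msg, "bounds must be finite")
  else if (any(object@lower > object@upper))
    msg <- c(msg, "lower bound exceeds upper bound in some dimension")
  if (!(object@pAlarm > 0 && object@pAlarm < 1))
    msg <- c(msg, "pAlarm must lie in (0,1)")
  if (!(object@producerFraction > 0 && object@producerFraction < 1))
    msg <- c(msg, "producerFraction must lie in (0,1)")
  if (!object@perchScope %in% c("all", "producers"))
    msg <- c(msg, "perchScope must be 'all' or 'producers'")
  if (length(object@initGuess) &&
      length(object@initGuess) != object@s)
    msg <- c(msg, "initGuess must have length s")
  if (length(msg)) msg else TRUE
})

#' A population of candidate solutions (the finch swarm)
#'
#' The working state of the optimizer: an `l x s` matrix of positions, their
#' fitness values, the elitist global best, the current worst, the column-mean
#' position and the iteration counter. Rows are kept sorted by fitness after
#' each evaluation so that the first `producerFraction * l` rows are the
#' producers.
#'
#' @slot positions numeric matrix, `l` individuals by `s` dimensions.
#' @slot fitnesses numeric length `l` (`NA` before evaluation).
#' @slot bestPosition,bestFitness elitist global best (never worsens).
#' @slot worstPosition,worstFitness current global worst.
#' @slot meanPosition column-wise mean of `positions`.
#' @slot iteration integer iteration counter, starts at 0.
#' @slot evaluations integer, cumulative objective calls.
#' @export
setClass("FinchSwarm",
  representation(
    positions = "matrix", fitnesses = "numeric",
    bestPosition = "numeric", bestFitness = "numeric",
    worstPosition = "numeric", worstFitness = "numeric",
    meanPosition = "numeric", iteration = "integer",
    evaluations = "integer"
  )
)

setValidity("FinchSwarm", function(object) {
  msg <- character()
  if (length(object@fitnesses) != nrow(object@positions))
    msg <- c(msg, "fitnesses length must equal number of rows in positions")
  if (length(object@meanPosition) &&
      length(object@meanPosition) != ncol(object@positions))
    msg <- c(msg, "meanPosition length must equal s")
  if (object@iteration < 0L) msg <- c(msg, "iteration must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Result of a falcon finch optimization run
#'
#' @slot bestPosition,bestFitness elitist optimum found.
#' @slot convergenceHistory numeric, best fitness after each iteration
#'   (non-increasing; length equals iterations executed).
#' @slot evaluations integer, total objective calls.
#' @slot config the [FFOConfig-class] used.
#' @slot seed integer seed the run used.
#' @export
setClass("OptimizationResult",
  representation(
    bestPosition = "numeric", bestFitness = "numeric",
    convergenceHistory = "numeric", evaluations = "integer",
    config = "FFOConfig", seed = "integer"
  )
)

#' An RGB or grayscale image with intensities in [0, 1]
#'
#' Thin S4 wrapper around an `H x W x C` array (`C` is 1 or 3) carrying a
#' provenance tag (file path or synthetic description). Build with
#' [imageRaster()].
#'
#' @slot pixels numeric `H x W x C` array in `[0, 1]`.
#' @slot provenance character tag.
#' @export
setClass("ImageRaster",
  representation(pixels = "array", provenance = "character")
)

setValidity("ImageRaster", function(object) {
  d <- dim(object@pixels)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "pixels must be an H x W x C array")
  else if (!d[3] %in% c(1L, 3L)) msg <- c(msg, "channel count must be 1 or 3")
  if (anyNA(object@pixels) || any(!is.finite(object@pixels)))
    msg <- c(msg, "pixel values must be finite")
  if (length(msg)) msg else TRUE
})

#' A deterministic deep-feature backbone
#'
#' Maps a standardized [ImageRaster-class] to a fixed-length real vector.
#' The default implementation is a seeded random projection
#' ([descriptorBackbone()]); any drop-in (e.g. a pretrained network
#' wrapper) satisfying the same contract can be supplied.
#'
#' @slot name character identifier.
#' @slot d integer output dimension.
#' @slot fun function from `ImageRaster` to numeric length `d`.
#' @export
setClass("Backbone",
  representation(name = "character", d = "integer", fun = "function")
)

setValidity("Backbone", function(object) {
  if (object@d < 0L) "backbone dimension must be >= 0" else TRUE
})

#' A single network layer
#'
#' @slot kind one of `"conv"`, `"maxpool"`, `"dropout"`, `"flatten"`,
#'   `"dense"`.
#' @slot filters integer: conv filters or dense units (0 otherwise).
#' @slot kernel integer length 2 kernel size (conv only).
#' @slot activation `"relu"`, `"softmax"` or `"none"`.
#' @slot rate numeric dropout rate in `[0, 1)`.
#' @export
setClass("LayerSpec",
  representation(kind = "character", filters = "integer",
                 kernel = "integer", activation = "character",
                 rate = "numeric")
)

setValidity("LayerSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("conv", "maxpool", "dropout", "flatten", "dense"))
    msg <- c(msg, "unknown layer kind")
  if (object@kind %in% c("conv", "dense") && object@filters < 1L)
    msg <- c(msg, "conv/dense layers need positive filters/units")
  if (object@rate < 0 || object@rate >= 1)
    msg <- c(msg, "dropout rate must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' A declarative network architecture
#'
#' Ordered layer list plus training hyper-parameters. The canonical instance
#' ([canonicalSpec()]) reconstructs the published parameter table exactly.
#'
#' @slot layers list of [LayerSpec-class].
#' @slot inputShape integer length 3, `(H, W, C)`.
#' @slot loss character loss name (`"mse"`).
#' @slot optimizer character optimizer name (`"adam"`).
#' @slot batchSize integer.
#' @slot epochs integer.
#' @export
setClass("NetworkSpec",
  representation(layers = "list", inputShape = "integer",
                 loss = "character", optimizer = "character",
                 batchSize = "integer", epochs = "integer")
)

setValidity("NetworkSpec", function(object) {
  msg <- character()
  if (length(object@inputShape) != 3L)
    msg <- c(msg, "inputShape must be (H, W, C)")
  if (length(object@layers)) {
    last <- object@layers[[length(object@layers)]]
    if (!(last@kind == "dense" && last@filters == 2L &&
          last@activation == "softmax"))
      msg <- c(msg, "last layer must be dense(2, softmax)")
  }
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@epochs < 0L) msg <- c(msg, "epochs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A (possibly trained) realization of a NetworkSpec
#'
#' @slot spec the [NetworkSpec-class].
#' @slot weights list of per-layer weight lists (`W`, `b`) or `NULL` entries.
#' @slot history numeric, training loss per epoch.
#' @slot seed integer initialization seed.
#' @export
setClass("TrainedModel",
  representation(spec = "NetworkSpec", weights = "list",
                 history = "numeric", seed = "integer")
)

#' Specification of a synthetic two-class dermoscopy-like dataset
#'
#' Encodes the study conditions under which the pipeline is exercised:
#' class counts, raster size, per-class generative parameter ranges
#' (asymmetry, border irregularity amplitude, number of intra-lesion colour
#' patches), background tone, additive noise and hair-artifact probability.
#' The class regimes are disjoint by construction (benign asymmetry at most
#' 0.15, malignant at least 0.35), so a threshold on the stored asymmetry
#' parameter separates the classes perfectly.
#'
#' @slot nBenign,nMalignant integer class counts.
#' @slot imageSize integer raster side length.
#' @slot asymmetryBenign,asymmetryMalignant numeric length-2 ranges.
#' @slot irregularityBenign,irregularityMalignant numeric length-2 ranges.
#' @slot patchesBenign,patchesMalignant integer length-2 ranges of colour
#'   patch counts.
#' @slot backgroundTone numeric length 3 RGB skin tone.
#' @slot noiseSigma numeric additive Gaussian noise sd on the `[0,1]` scale.
#' @slot hairProb numeric probability of hair-like occluding strokes.
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticSpec",
  representation(
    nBenign = "integer", nMalignant = "integer", imageSize = "integer",
    asymmetryBenign = "numeric", asymmetryMalignant = "numeric",
    irregularityBenign = "numeric", irregularityMalignant = "numeric",
    patchesBenign = "integer", patchesMalignant = "integer",
    backgroundTone = "numeric", noiseSigma = "numeric",
    hairProb = "numeric", seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nBenign < 0L || object@nMalignant < 0L)
    msg <- c(msg, "class counts must be >= 0")
  if (object@imageSize < 16L) msg <- c(msg, "imageSize must be >= 16")
  if (max(object@asymmetryBenign) >= min(object@asymmetryMalignant))
    msg <- c(msg, "class asymmetry ranges must be disjoint (benign < malignant)")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@hairProb < 0 || object@hairProb > 1)
    msg <- c(msg, "hairProb must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' A labelled (synthetic or loaded) lesion image
#'
#' @slot image an [ImageRaster-class].
#' @slot label `"benign"` or `"malignant"`.
#' @slot params named list of generative parameters (empty for loaded images).
#' @export
setClass("LabeledImage",
  representation(image = "ImageRaster", label = "character", params = "list")
)

setValidity("LabeledImage", function(object) {
  if (!object@label %in% c("benign", "malignant"))
    "label must be 'benign' or 'malignant'" else TRUE
})

#' Confusion counts for a two-class problem
#'
#' Malignant is the positive class: `Pt` true positives, `Nt` true negatives,
#' `Pf` false positives, `Nf` false negatives.
#'
#' @slot Pt,Nt,Pf,Nf non-negative integer counts.
#' @export
setClass("ConfusionCounts",
  representation(Pt = "integer", Nt = "integer", Pf = "integer", Nf = "integer")
)

setValidity("ConfusionCounts", function(object) {
  if (any(c(object@Pt, object@Nt, object@Pf, object@Nf) < 0L))
    "counts must be non-negative" else TRUE
})

#' Evaluation report over folds or splits
#'
#' @slot mode `"kfold"` or `"split"`.
#' @slot folds list of [ConfusionCounts-class], one per fold/split.
#' @slot perFold data.frame of per-fold accuracy/sensitivity/specificity (%).
#' @slot pooled [ConfusionCounts-class] summed over folds.
#' @slot mean numeric named vector, mean metrics across folds (%).
#' @slot seed integer.
#' @slot config named list echo of the harness configuration.
#' @export
setClass("EvaluationReport",
  representation(mode = "character", folds = "list", perFold = "data.frame",
                 pooled = "ConfusionCounts", mean = "numeric",
                 seed = "integer", config = "list")
)
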