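# Accessor generics (Bioconductor style: accessors, not slot access).

#' @rdname FinchSwarm-class
#' @param object,x an object.
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
#' @rdname FinchSwarm-class
#' @export
setGeneric("fitnesses", function(object) standardGeneric("fitnesses"))
#' @rdname FinchSwarm-class
#' @export
setGeneric("bestPosition", function(object) standardGeneric("bestPosition"))
#' @rdname FinchSwarm-class
#' @export
setGeneric("bestFitness", function(object) standardGeneric("bestFitness"))
#' @rdname FinchSwarm-class
#' @export
setGeneric("worstPosition", function(object) standardGeneric("worstPosition"))
#' @rdname FinchSwarm-class
#' @export
setGeneric("worstFitness", function(object) standardGeneric("worstFitness"))
#' @rdname FinchSwarm-class
#' @export
setGeneric("meanPosition", function(object) standardGeneric("meanPosition"))
#' @rdname FinchSwarm-class
#' @export
setGeneric("iteration", function(object) standardGeneric("iteration"))
#' @rdname OptimizationResult-class
#' @export
setGeneric("evaluations", function(object) standardGeneric("evaluations"))
#' @rdname OptimizationResult-class
#' @export
setGeneric("convergenceHistory",
           function(object) standardGeneric("convergenceHistory"))
#' @rdname ImageRaster-class
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname ImageRaster-class
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname LabeledImage-class
#' @export
setGeneric("imageLabel", function(object) standardGeneric("imageLabel"))
#' @rdname LabeledImage-class
#' @export
setGeneric("generativeParams",
           function(object) standardGeneric("generativeParams"))

#' Count trainable parameters of a network
#'
#' Conv layers contribute `kh * kw * C_in * filters + filters`, dense layers
#' `inputs * units + units`; pooling, dropout and flatten contribute nothing.
#'
#' @param spec a [NetworkSpec-class].
#' @return list with `perLayer` (named integer vector) and `total`.
#' @export
setGeneric("countParameters", function(spec) standardGeneric("countParameters"))

#' Per-layer output shapes of a network
#'
#' @param spec a [NetworkSpec-class].
#' @return list of integer shape vectors, one per layer.
#' @export
setGeneric("outputShapes", function(spec) standardGeneric("outputShapes"))

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy = (Pt+Nt)/(Pt+Nt+Pf+Nf), sensitivity = Pt/(Pt+Nf),
#' specificity = Nt/(Nt+Pf), all reported in percent. A zero denominator
#' makes the metric `NA` with its name listed in the `undefined` attribute —
#' never silently 0 or 100.
#'
#' @param counts a [ConfusionCounts-class].
#' @return named numeric (percent) with attribute `undefined`.
#' @export
setGeneric("classMetrics", function(counts) standardGeneric("classMetrics"))

# ---- accessor methods ----

#' @rdname FinchSwarm-class
#' @export
setMethod("positions", "FinchSwarm", function(object) object@positions)
#' @rdname FinchSwarm-class
#' @export
setMethod("fitnesses", "FinchSwarm", function(object) object@fitnesses)
#' @rdname FinchSwarm-class
#' @export
setMethod("bestPosition", "FinchSwarm", function(object) object@bestPosition)
#' @rdname FinchSwarm-class
#' @export
setMethod("bestFitness", "FinchSwarm", function(object) object@bestFitness)
#' @rdname FinchSwarm-class
#' @export
setMethod("worstPosition", "FinchSwarm", function(object) object@worstPosition)
#' @rdname FinchSwarm-class
#' @export
setMethod("worstFitness", "FinchSwarm", function(object) object@worstFitness)
#' @rdname FinchSwarm-class
#' @export
setMethod("meanPosition", "FinchSwarm", function(object) object@meanPosition)
#' @rdname FinchSwarm-class
#' @export
setMethod("iteration", "FinchSwarm", function(object) object@iteration)
#' @rdname FinchSwarm-class
#' @export
setMethod("evaluations", "FinchSwarm", function(object) object@evaluations)

#' @rdname OptimizationResult-class
#' @export
setMethod("bestPosition", "OptimizationResult",
          function(object) object@bestPosition)
#' @rdname OptimizationResult-class
#' @export
setMethod("bestFitness", "OptimizationResult",
          function(object) object@bestFitness)
#' @rdname OptimizationResult-class
#' @export
setMethod("convergenceHistory", "OptimizationResult",
          function(object) object@convergenceHistory)
#' @rdname OptimizationResult-class
#' @export
setMethod("evaluations", "OptimizationResult",
          function(object) object@evaluations)

#' @rdname ImageRaster-class
#' @export
setMethod("pixels", "ImageRaster", function(object) object@pixels)
#' @rdname ImageRaster-class
#' @export
setMethod("provenance", "ImageRaster", function(object) object@provenance)
#' @rdname LabeledImage-class
#' @export
setMethod("pixels", "LabeledImage", function(object) object@image@pixels)
#' @rdname LabeledImage-class
#' @export
setMethod("imageLabel", "LabeledImage", function(object) object@label)
#' @rdname LabeledImage-class
#' @export
setMethod("generativeParams", "LabeledImage", function(object) object@params)

# ---- show methods ----

setMethod("show", "FFOConfig", function(object) {
  cat("FFOConfig: l =", object@l, ", s =", object@s,
      ", iterMax =", object@iterMax, "\n")
  cat("  bounds: [", paste(signif(object@lower, 4), collapse = ", "), "] .. [",
      paste(signif(object@upper, 4), collapse = ", "), "]\n")
  cat("  pAlarm =", object@pAlarm, ", lambda =", object@lambda,
      ", producerFraction =", object@producerFraction,
      ", seed =", object@seed, "\n")
  cat("  stages: besiege =", object@besiegeEnabled,
      ", perching =", object@perchingEnabled,
      "(", object@perchScope, "), ssaCompat =", object@ssaCompat, "\n")
})

setMethod("show", "FinchSwarm", function(object) {
  cat("FinchSwarm:", nrow(object@positions), "individuals x",
      ncol(object@positions), "dims, iteration", object@iteration, "\n")
  if (all(is.finite(object@bestFitness)))
    cat("  best fitness:", format(object@bestFitness), "\n")
})

setMethod("show", "OptimizationResult", function(object) {
  cat("OptimizationResult:", length(object@convergenceHistory),
      "iterations,", object@evaluations, "objective evaluations\n")
  cat("  best fitness:", format(object@bestFitness), "\n")
  cat("  best position:", paste(signif(object@bestPosition, 5),
                                collapse = ", "), "\n")
})

setMethod("show", "ImageRaster", function(object) {
  d <- dim(object@pixels)
  cat("ImageRaster:", d[1], "x", d[2], "x", d[3],
      " [", object@provenance, "]\n")
})

setMethod("show", "LabeledImage", function(object) {
  d <- dim(object@image@pixels)
  cat("LabeledImage (", object@label, "): ", d[1], "x", d[2], "x", d[3], "\n",
      sep = "")
})

setMethod("show", "Backbone", function(object) {
  cat("Backbone '", object@name, "': d = ", object@d, "\n", sep = "")
})

setMethod("show", "NetworkSpec", function(object) {
  cat("NetworkSpec: input", paste(object@inputShape, collapse = "x"),
      "->", length(object@layers), "layers\n")
  for (ly in object@layers)
    cat("  ", ly@kind,
        if (ly@kind %in% c("conv", "dense")) paste0("(", ly@filters, ")") else "",
        "\n")
  cat("  loss =", object@loss, ", optimizer =", object@optimizer,
      ", batch =", object@batchSize, ", epochs =", object@epochs, "\n")
})

setMethod("show", "TrainedModel", function(object) {
  tot <- countParameters(object@spec)$total
  cat("TrainedModel:", tot, "parameters,",
      length(object@history), "training epochs recorded\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@nBenign, "benign +", object@nMalignant,
      "malignant,", object@imageSize, "px, seed", object@seed, "\n")
})

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts: Pt =", object@Pt, ", Nt =", object@Nt,
      ", Pf =", object@Pf, ", Nf =", object@Nf, "\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport (", object@mode, "): ",
      length(object@folds), " partitions\n", sep = "")
  print(object@perFold, digits = 4)
  cat("mean: ", paste(names(object@mean),
                      sprintf("%.2f", object@mean), collapse = ", "), "\n")
})
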