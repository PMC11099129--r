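#' Confusion counts from truth / prediction label vectors
#'
#' Malignant is the positive class (clinical convention): `Pt` counts
#' malignant called malignant, `Nt` benign called benign.
#'
#' @param truth,pred character vectors with values `"benign"`/`"malignant"`.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  new("ConfusionCounts",
      Pt = sum(truth == "malignant" & pred == "malignant"),
      Nt = sum(truth == "benign" & pred == "benign"),
      Pf = sum(truth == "benign" & pred == "malignant"),
      Nf = sum(truth == "malignant" & pred == "benign"))
}

#' @rdname classMetrics
#' @export
setMethod("classMetrics", "ConfusionCounts", function(counts) {
  Pt <- counts@Pt; Nt <- counts@Nt; Pf <- counts@Pf; Nf <- counts@Nf
  total <- Pt + Nt + Pf + Nf
  if (total == 0L) stop("no evaluated samples")
  undef <- character()
  acc <- 100 * (Pt + Nt) / total
  sen <- if (Pt + Nf > 0) 100 * Pt / (Pt + Nf) else {
    undef <- c(undef, "sensitivity"); NA_real_
  }
  spec <- if (Nt + Pf > 0) 100 * Nt / (Nt + Pf) else {
    undef <- c(undef, "specificity"); NA_real_
  }
  out <- c(accuracy = acc, sensitivity = sen, specificity = spec)
  attr(out, "undefined") <- undef
  out
})

#' Stratified k-fold partition
#'
#' Shuffles indices within each class and deals them round-robin into `k`
#' disjoint folds, so every fold's class ratio is within one sample of the
#' global ratio. With `labels = NULL` the split is unstratified (this is the
#' route to `k = n` leave-one-out).
#'
#' @param n sample count.
#' @param k number of folds, `2 <= k <= n`.
#' @param labels optional length-`n` class labels; every class must have at
#'   least `k` members when given.
#' @param seed shuffle seed.
#' @return list of `k` integer index vectors (a partition of `1:n`).
#' @export
kfoldSplit <- function(n, k, labels = NULL, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L || k > n) stop("need 2 <= k <= n")
  folds <- vector("list", k)
  withSeed(seed, {
    if (is.null(labels)) {
      idx <- sample.int(n)
      for (i in seq_len(n))
        folds[[(i - 1L) %% k + 1L]] <- c(folds[[(i - 1L) %% k + 1L]], idx[i])
    } else {
      stopifnot(length(labels) == n)
      tab <- table(labels)
      if (any(tab < k))
        stop("class '", names(tab)[which.min(tab)],
             "' has fewer than k members; cannot stratify")
      for (cl in names(tab)) {
        idx <- sample(which(labels == cl))
        for (i in seq_along(idx))
          folds[[(i - 1L) %% k + 1L]] <-
            c(folds[[(i - 1L) %% k + 1L]], idx[i])
      }
    }
  })
  folds
}

# Fit + tune on the training indices, predict the held-out indices.
# feat: N x F feature matrix, labels: character vector.
evalPartition <- function(feat, labels, trainIdx, testIdx, epochs, tuneIters,
                          seed, batchSize = 32L) {
  mu <- colMeans(feat[trainIdx, , drop = FALSE])
  sd_ <- apply(feat[trainIdx, , drop = FALSE], 2, stats::sd)
  sd_[sd_ < 1e-12] <- 1                    # constant features pass through
  zs <- function(m) sweep(sweep(m, 2, mu), 2, sd_, `/`)

  oneHot <- function(lab)
    cbind(benign = as.numeric(lab == "benign"),
          malignant = as.numeric(lab == "malignant"))

  # inner stratified 80/20 carve-out of the training partition for the
  # tuning fold (both classes must be represented or head tuning collapses
  # to the majority class)
  tuneIdx <- withSeed(seed + 31L, {
    unlist(lapply(unique(labels[trainIdx]), function(cl) {
      ofClass <- trainIdx[labels[trainIdx] == cl]
      sample(ofClass, max(1L, round(0.2 * length(ofClass))))
    }))
  })
  fitIdx <- setdiff(trainIdx, tuneIdx)

  xFit <- featuresToInput(zs(feat[fitIdx, , drop = FALSE]))
  yFit <- oneHot(labels[fitIdx])
  xTune <- featuresToInput(zs(feat[tuneIdx, , drop = FALSE]))
  yTune <- oneHot(labels[tuneIdx])
  xTest <- featuresToInput(zs(feat[testIdx, , drop = FALSE]))

  spec <- canonicalSpec()
  model <- buildModel(spec, seed = seed)
  model <- trainModel(model, xFit, yFit, epochs = epochs,
                      batchSize = batchSize, seed = seed)
  if (tuneIters > 0L)
    model <- ffoTune(model, xTune, yTune, iterMax = tuneIters, seed = seed)
  p <- predictModel(model, xTest)
  pred <- c("benign", "malignant")[max.col(p, ties.method = "first")]
  confusionCounts(labels[testIdx], pred)
}

#' Run the full evaluation harness
#'
#' For each fold (`mode = "kfold"`) or for the single training-percentage
#' split (`mode = "split"`): preprocess and extract features (once, shared
#' across folds since they are deterministic), z-score them on the training
#' partition, train the canonical classifier, tune its output layer with the
#' falcon finch optimizer on an inner carve-out of the training data, and
#' predict the held-out samples. Reports per-fold confusion counts with
#' accuracy / sensitivity / specificity in percent and their mean across
#' folds.
#'
#' @param dataset one of: a directory with `benign/` / `malignant/` image
#'   folders, a list of [LabeledImage-class], or a data.frame with a `label`
#'   column plus numeric feature columns (as from [featureTable()]).
#' @param mode `"kfold"` or `"split"`.
#' @param k folds for `mode = "kfold"` (default 5).
#' @param trainPct training percentage in (0, 100) for `mode = "split"`
#'   (default 80); 100 is rejected (no test data).
#' @param epochs training epochs per fold (default 30).
#' @param tuneIters optimizer iterations for output-layer tuning
#'   (default 20; 0 disables tuning).
#' @param denoise apply non-local-means denoising before standardization
#'   when `dataset` is images (default `TRUE`).
#' @param backbone a [Backbone-class] for feature extraction.
#' @param seed master seed (splits, init, training, tuning).
#' @param shuffleLabels permute the labels before splitting (chance-level
#'   null check).
#' @return an [EvaluationReport-class].
#' @export
runHarness <- function(dataset, mode = c("kfold", "split"), k = 5L,
                       trainPct = 80, epochs = 30L, tuneIters = 20L,
                       denoise = TRUE, backbone = descriptorBackbone(),
                       seed = 1L, shuffleLabels = FALSE) {
  mode <- match.arg(mode)

  if (is.character(dataset) && length(dataset) == 1L)
    dataset <- readImageTree(dataset)
  if (is.data.frame(dataset)) {
    labels <- as.character(dataset$label)
    feat <- as.matrix(dataset[setdiff(names(dataset), "label")])
  } else {
    labels <- vapply(dataset, imageLabel, character(1))
    feat <- t(vapply(dataset, function(im) {
      img <- im@image
      if (denoise) img <- denoiseImage(img)
      extractFeatures(standardizeImage(img), backbone)
    }, numeric(8L + backbone@d)))
  }
  n <- length(labels)
  if (n < 4L) stop("need at least 4 labelled samples")
  if (shuffleLabels)
    labels <- withSeed(seed + 77L, sample(labels))

  if (mode == "kfold") {
    folds <- kfoldSplit(n, k, labels, seed = seed)
    parts <- lapply(folds, function(te) list(train = setdiff(seq_len(n), te),
                                             test = te))
  } else {
    if (trainPct <= 0 || trainPct >= 100)
      stop("trainPct must lie strictly between 0 and 100")
    nTrain <- round(n * trainPct / 100)
    if (nTrain < 2L || nTrain > n - 1L) stop("degenerate split")
    ord <- withSeed(seed, sample.int(n))
    parts <- list(list(train = ord[seq_len(nTrain)],
                       test = ord[(nTrain + 1L):n]))
  }

  counts <- lapply(seq_along(parts), function(i)
    evalPartition(feat, labels, parts[[i]]$train, parts[[i]]$test,
                  epochs = epochs, tuneIters = tuneIters, seed = seed + i))

  perFold <- do.call(rbind, lapply(seq_along(counts), function(i) {
    m <- classMetrics(counts[[i]])
    data.frame(fold = i, Pt = counts[[i]]@Pt, Nt = counts[[i]]@Nt,
               Pf = counts[[i]]@Pf, Nf = counts[[i]]@Nf,
               accuracy = m[["accuracy"]], sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]])
  }))
  pooled <- new("ConfusionCounts",
                Pt = sum(vapply(counts, function(cc) cc@Pt, integer(1))),
                Nt = sum(vapply(counts, function(cc) cc@Nt, integer(1))),
                Pf = sum(vapply(counts, function(cc) cc@Pf, integer(1))),
                Nf = sum(vapply(counts, function(cc) cc@Nf, integer(1))))
  meanM <- colMeans(perFold[, c("accuracy", "sensitivity", "specificity")],
                    na.rm = TRUE)
  new("EvaluationReport", mode = mode, folds = counts, perFold = perFold,
      pooled = pooled, mean = meanM, seed = as.integer(seed),
      config = list(mode = mode, k = if (mode == "kfold") k else NULL,
                    trainPct = if (mode == "split") trainPct else NULL,
                    epochs = epochs, tuneIters = tuneIters,
                    denoise = denoise, backbone = backbone@name,
                    shuffleLabels = shuffleLabels, n = n))
}

#' Serialize an evaluation report
#'
#' JSON carries the full report (per-fold counts and metrics, pooled counts,
#' means, seed, config echo); the CSV mirrors the published table layout
#' (one row per fold plus a mean row, metric columns in percent to two
#' decimals).
#'
#' @param report an [EvaluationReport-class].
#' @param jsonPath,csvPath output paths (either may be `NULL` to skip).
#' @return invisible list of the written paths.
#' @export
writeEvaluationReport <- function(report, jsonPath = NULL, csvPath = NULL) {
  if (!is.null(jsonPath)) {
    doc <- list(mode = report@mode, seed = report@seed,
                config = report@config,
                per_fold = report@perFold,
                pooled = list(Pt = report@pooled@Pt, Nt = report@pooled@Nt,
                              Pf = report@pooled@Pf, Nf = report@pooled@Nf),
                mean = as.list(report@mean))
    jsonlite::write_json(doc, jsonPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(csvPath)) {
    tab <- report@perFold[, c("fold", "accuracy", "sensitivity",
                              "specificity")]
    tab[-1] <- lapply(tab[-1], function(v) round(v, 2))
    tab$fold <- as.character(tab$fold)
    tab <- rbind(tab, data.frame(fold = "mean",
                                 accuracy = round(report@mean[["accuracy"]], 2),
                                 sensitivity = round(report@mean[["sensitivity"]], 2),
                                 specificity = round(report@mean[["specificity"]], 2)))
    utils::write.csv(tab, csvPath, row.names = FALSE)
  }
  invisible(list(json = jsonPath, csv = csvPath))
}
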