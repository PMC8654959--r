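#' Build the multi-headed convolutional classifier
#'
#' Constructs the network described by `config`: per active representation a
#' branch of two stacked 1-D valid convolutions (stride 1, ReLU, no pooling,
#' dropout after each layer), flattened and concatenated across branches,
#' followed by dense recombination layers with ReLU and dropout, and a
#' two-unit softmax head.  An L2 penalty is attached to every convolutional
#' and dense weight matrix.  Weights are initialised (Glorot uniform) from
#' `config@seed`, so building twice gives identical untrained models.
#'
#' @param config A [ModelConfig-class].
#' @return An untrained [MHCNN-class].
#' @examples
#' m <- buildMHCNN(presetConfig("acp740", combination = "C1"))
#' countParameters(m)
#' @seealso [trainMHCNN()], [predictProba()]
#' @export
buildMHCNN <- function(config) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  .branchDims(config)  # errors if kernels exhaust k
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(config@seed)
  new("MHCNN", config = config, params = .initParams(config),
      trained = FALSE,
      history = data.frame(epoch = integer(), trainLoss = numeric(),
                           trainAcc = numeric(), valLoss = numeric(),
                           valAcc = numeric()))
}

.saveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restoreRNG <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

## check that stacks match what the model expects
.checkStacks <- function(cfg, data) {
  stopifnot(is(data, "EncodedStacks"))
  missing <- setdiff(cfg@combination, names(data@stacks))
  if (length(missing))
    .dataError(sprintf("encoded stacks lack representation(s): %s",
                       paste(missing, collapse = ", ")))
  if (data@k != cfg@k)
    .dataError(sprintf("stacks have k = %d but the model expects k = %d",
                       data@k, cfg@k))
  for (r in cfg@combination) {
    d <- dim(data@stacks[[r]])
    if (d[3] != .REP_WIDTHS[[r]])
      .dataError(sprintf("%s stack has %d columns, expected %d", r, d[3],
                         .REP_WIDTHS[[r]]))
  }
}

.accuracyFromProbs <- function(probs, y) mean((probs[, 2L] > 0.5) == (y == 1L))

#' Train the classifier
#'
#' Jointly optimises all branches and the recombination layers by minimising
#' the softmax cross-entropy plus the L2 penalty with Adam.  Dropout is
#' active only during training.  Unless `validation` is given (or
#' `validationFraction` is 0), a stratified fraction of the training data is
#' held out and training stops early when its loss has not improved for
#' `patience` epochs (the stop is only armed after the `minEpochs` warm-up,
#' since the high dropout rates leave the first epochs on a loss plateau);
#' the best-validation-loss weights are restored.  All
#' randomness (validation split, shuffling, dropout) is seeded from
#' `config@seed`, so identical inputs reproduce identical models.
#'
#' @param model An [MHCNN-class] from [buildMHCNN()].
#' @param data An [EncodedStacks-class] with complete 0/1 labels covering
#'   both classes.
#' @param validation Optional [EncodedStacks-class] used for early stopping
#'   instead of an internal split.
#' @param verbose Log per-epoch progress via `message()`.
#' @return The trained [MHCNN-class] with its `history` filled in.
#' @examples
#' ps <- generateSynthetic(syntheticSpec(nPos = 20, nNeg = 20, seed = 1))
#' es <- encodeDataset(ps, "C1")
#' cfg <- presetConfig("acp740", combination = "C1", maxEpochs = 3)
#' fit <- trainMHCNN(buildMHCNN(cfg), es)
#' @export
trainMHCNN <- function(model, data, validation = NULL, verbose = FALSE) {
  stopifnot(is(model, "MHCNN"))
  cfg <- model@config
  .checkStacks(cfg, data)
  y <- data@labels
  if (anyNA(y)) .dataError("training data must be fully labelled")
  if (length(unique(y)) < 2L)
    .dataError("training labels contain a single class")

  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(cfg@seed)

  n <- length(y)
  sub <- function(idx) lapply(data@stacks[cfg@combination],
                              function(a) a[idx, , , drop = FALSE])
  if (is.null(validation) && cfg@validationFraction > 0) {
    valIdx <- integer(0)
    for (cls in c(1L, 0L)) {
      members <- which(y == cls)
      nVal <- max(1L, floor(cfg@validationFraction * length(members)))
      valIdx <- c(valIdx, sample(members, nVal))
    }
    trIdx <- setdiff(seq_len(n), valIdx)
    valStacks <- sub(valIdx); valY <- y[valIdx]
    trStacks <- sub(trIdx); trY <- y[trIdx]
  } else if (!is.null(validation)) {
    .checkStacks(cfg, validation)
    valStacks <- validation@stacks[cfg@combination]
    valY <- validation@labels
    trStacks <- sub(seq_len(n)); trY <- y
  } else {
    valStacks <- NULL; valY <- NULL
    trStacks <- sub(seq_len(n)); trY <- y
  }

  params <- model@params
  state <- .adamInit(params)
  nTr <- length(trY)
  bestLoss <- Inf; bestParams <- params; wait <- 0L
  hist <- vector("list", cfg@maxEpochs)

  for (epoch in seq_len(cfg@maxEpochs)) {
    perm <- sample(nTr)
    starts <- seq(1L, nTr, by = cfg@batchSize)
    for (s in starts) {
      idx <- perm[s:min(s + cfg@batchSize - 1L, nTr)]
      batch <- lapply(trStacks, function(a) a[idx, , , drop = FALSE])
      fwd <- .forwardPass(params, cfg, batch, training = TRUE)
      grads <- .backwardPass(params, cfg, fwd, trY[idx], cfg@l2Lambda)
      stepped <- .adamStep(params, grads, state, cfg@learningRate)
      params <- stepped$params; state <- stepped$state
    }
    trEval <- .forwardPass(params, cfg, trStacks, training = FALSE)
    trLoss <- .lossFromProbs(trEval$probs, trY, params, cfg@l2Lambda)
    trAcc <- .accuracyFromProbs(trEval$probs, trY)
    if (!is.null(valY)) {
      vEval <- .forwardPass(params, cfg, valStacks, training = FALSE)
      vLoss <- .lossFromProbs(vEval$probs, valY, params, cfg@l2Lambda)
      vAcc <- .accuracyFromProbs(vEval$probs, valY)
    } else {
      vLoss <- NA_real_; vAcc <- NA_real_
    }
    hist[[epoch]] <- data.frame(epoch = epoch, trainLoss = trLoss,
                                trainAcc = trAcc, valLoss = vLoss,
                                valAcc = vAcc)
    if (verbose)
      message(sprintf("epoch %3d: train loss %.4f acc %.3f%s", epoch, trLoss,
                      trAcc,
                      if (!is.null(valY))
                        sprintf(" | val loss %.4f acc %.3f", vLoss, vAcc)
                      else ""))
    if (!is.null(valY)) {
      if (vLoss < bestLoss - 1e-12) {
        bestLoss <- vLoss; bestParams <- params; wait <- 0L
      } else {
        wait <- wait + 1L
        ## patience is only armed after the warm-up epochs; the published
        ## high dropout rates leave early epochs on a loss plateau
        if (epoch > cfg@minEpochs && wait >= cfg@patience) break
      }
    }
  }
  if (!is.null(valY)) params <- bestParams

  model@params <- params
  model@trained <- TRUE
  model@history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  model
}

#' Class probabilities for encoded peptides
#'
#' Runs the network in inference mode (dropout disabled); a pure function of
#' the inputs, so repeated calls give identical output.
#'
#' @param model A built [MHCNN-class].
#' @param data An [EncodedStacks-class] matching the model's combination and
#'   `k`.
#' @return Numeric `n x 2` matrix with columns `neg`, `pos`; rows are
#'   non-negative and sum to 1.
#' @seealso [predictLabel()]
#' @export
predictProba <- function(model, data) {
  stopifnot(is(model, "MHCNN"))
  .checkStacks(model@config, data)
  probs <- .forwardPass(model@params, model@config,
                        data@stacks[model@config@combination],
                        training = FALSE)$probs
  dimnames(probs) <- list(data@ids, c("neg", "pos"))
  probs
}

#' Hard labels from class probabilities
#'
#' Label 1 iff the positive-class probability strictly exceeds `threshold`;
#' an exact tie yields 0 (conservative positive calls).
#'
#' @param probs Output of [predictProba()] (or a numeric vector of
#'   positive-class probabilities).
#' @param threshold Decision threshold, default 0.5.
#' @return Integer vector of 0/1 labels.
#' @examples
#' predictLabel(c(0.49, 0.5, 0.51))   # 0 0 1
#' @export
predictLabel <- function(probs, threshold = 0.5) {
  p <- if (is.matrix(probs)) probs[, "pos"] else as.numeric(probs)
  as.integer(p > threshold)
}

#' Count trainable parameters
#'
#' Total number of scalar weights and biases; matches the closed form
#' `filters * (kernel * inChannels + 1)` per convolutional layer and
#' `units * (in + 1)` per dense layer.
#'
#' @param model An [MHCNN-class].
#' @return Integer count.
#' @export
countParameters <- function(model) {
  stopifnot(is(model, "MHCNN"))
  cnt <- 0L
  walk <- function(x) {
    if (is.list(x)) for (el in x) walk(el) else cnt <<- cnt + length(x)
  }
  walk(model@params)
  cnt
}

#' Effective receptive field of stacked 1-D convolutions
#'
#' The number of consecutive input rows influencing one unit of the final
#' layer of a stack of valid convolutions.  For stride-1 stacks this is
#' `1 + sum(kernels - 1)`; the default two-layer stack (length-4 then
#' length-3 kernels) spans 6 residues.
#'
#' @param kernels Kernel lengths, outermost layer first.
#' @param strides Strides, same length as `kernels` (default all 1).
#' @return Integer receptive-field length in input rows.
#' @examples
#' effectiveReceptiveField(c(4, 3))   # 6
#' @export
effectiveReceptiveField <- function(kernels, strides = rep(1L, length(kernels))) {
  kernels <- as.integer(kernels); strides <- as.integer(strides)
  if (length(kernels) < 1L) .configError("need at least one kernel length")
  if (length(strides) != length(kernels))
    .configError("kernels and strides must have equal length")
  if (any(kernels < 1L) || any(strides < 1L))
    .configError("kernel lengths and strides must be >= 1")
  rf <- 1L; jump <- 1L
  for (i in seq_along(kernels)) {
    rf <- rf + (kernels[i] - 1L) * jump
    jump <- jump * strides[i]
  }
  rf
}

setMethod("show", "MHCNN", function(object) {
  cat(sprintf("MHCNN (%s): combination {%s}, %d parameters\n",
              if (object@trained) "trained" else "untrained",
              paste(object@config@combination, collapse = ", "),
              countParameters(object)))
  if (object@trained && nrow(object@history) > 0) {
    last <- tail(object@history, 1L)
    cat(sprintf("  %d epoch(s); final train acc %.3f%s\n", nrow(object@history),
                last$trainAcc,
                if (!is.na(last$valAcc))
                  sprintf(", val acc %.3f", last$valAcc) else ""))
  }
})

#' Save / load a model archive
#'
#' `saveMHCNN()` stores the architecture, weights, history and config
#' snapshot in a single RDS archive; `readMHCNN()` restores it.
#' [exportConfig()] additionally writes the configuration as human-readable
#' YAML.
#'
#' @param model An [MHCNN-class].
#' @param path File path.
#' @return `path` (save) or the restored [MHCNN-class] (read).
#' @export
saveMHCNN <- function(model, path) {
  stopifnot(is(model, "MHCNN"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveMHCNN
#' @export
readMHCNN <- function(path) {
  if (!file.exists(path)) .dataError(sprintf("model archive not found: %s", path))
  model <- readRDS(path)
  if (!is(model, "MHCNN")) .dataError(sprintf("not a model archive: %s", path))
  model
}

#' Serialise a configuration as YAML
#'
#' @param config A [ModelConfig-class].
#' @param path Output file; omit to get the YAML string.
#' @return The YAML string, invisibly when written to a file.
#' @export
exportConfig <- function(config, path = NULL) {
  stopifnot(is(config, "ModelConfig"))
  lst <- list(
    k = config@k, combination = as.list(config@combination),
    groups = lapply(config@groups, function(g)
      list(conv1 = list(filters = g@conv1Filters, kernel = g@conv1Kernel,
                        dropout = g@conv1Dropout),
           conv2 = list(filters = g@conv2Filters, kernel = g@conv2Kernel,
                        dropout = g@conv2Dropout))),
    denseLayers = config@denseLayers, l2Lambda = config@l2Lambda,
    learningRate = config@learningRate, batchSize = config@batchSize,
    maxEpochs = config@maxEpochs, patience = config@patience,
    minEpochs = config@minEpochs,
    validationFraction = config@validationFraction, seed = config@seed)
  txt <- yaml::as.yaml(lst)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
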