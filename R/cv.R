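#' Stratified k-fold partition
#'
#' Shuffles each class with the given seed (positives first, then
#' negatives) and deals the records round-robin across folds, continuing the
#' deal from one class to the next.  This makes the folds a partition whose
#' per-class counts — and total sizes — differ by at most 1.
#'
#' @param labels Binary 0/1 vector, or a labelled [PeptideSet-class].
#' @param nFolds Number of folds (default 5).
#' @param seed Integer seed; identical inputs give identical splits.
#' @return A [FoldSplit-class].
#' @examples
#' fs <- stratifiedKFold(rep(c(1, 0), c(6, 4)), nFolds = 2, seed = 1)
#' table(fs@assignments, rep(c(1, 0), c(6, 4)))
#' @export
stratifiedKFold <- function(labels, nFolds = 5L, seed = 1L) {
  if (is(labels, "PeptideSet")) labels <- labels(labels)
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    .dataError("labels must be complete and binary")
  nFolds <- as.integer(nFolds)
  if (nFolds < 2L) .configError("nFolds must be >= 2")
  for (cls in c(1L, 0L))
    if (sum(labels == cls) < nFolds)
      .dataError(sprintf("class %d has fewer members (%d) than folds (%d)",
                         cls, sum(labels == cls), nFolds))
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(seed)
  assignments <- integer(length(labels))
  counter <- 0L
  for (cls in c(1L, 0L)) {
    members <- sample(which(labels == cls))
    assignments[members] <- (counter + seq_along(members) - 1L) %% nFolds + 1L
    counter <- counter + length(members)
  }
  new("FoldSplit", nFolds = nFolds, assignments = assignments,
      seed = as.integer(seed))
}

setMethod("show", "FoldSplit", function(object) {
  cat(sprintf("FoldSplit: %d folds over %d records (seed %d); sizes %s\n",
              object@nFolds, length(object@assignments), object@seed,
              paste(tabulate(object@assignments, object@nFolds),
                    collapse = ", ")))
})

## shared: encode once, train on an index subset, score another subset
.subsetStacks <- function(es, idx) {
  new("EncodedStacks",
      stacks = lapply(es@stacks, function(a) a[idx, , , drop = FALSE]),
      labels = es@labels[idx], k = es@k, ids = es@ids[idx])
}

#' Stratified cross-validation of the classifier
#'
#' Encodes the dataset once, then per fold trains a fresh model on the
#' in-fold records (with its own internal stratified validation split for
#' early stopping) and scores the untouched out-of-fold records.  Reports
#' per-fold metrics, their mean and standard deviation, and the ROC/AUC of
#' the pooled out-of-fold scores (the package's convention for a single
#' per-dataset curve; per-fold AUCs are also kept).  Fold `f` trains with
#' seed `seed + f` so the whole run is reproducible.
#'
#' @param x A labelled [PeptideSet-class].
#' @param config A [ModelConfig-class] (its `combination` is evaluated).
#' @param nFolds Number of folds (default 5).
#' @param seed Seed for the fold split and per-fold training; defaults to
#'   `config@seed`.
#' @param table,matrix Encoding resources; defaults are the shipped files.
#' @param verbose Log progress.
#' @return A [CVResult-class].
#' @seealso [stratifiedKFold()], [independentTest()], [combinationSweep()]
#' @export
crossValidate <- function(x, config, nFolds = 5L, seed = config@seed,
                          table = loadPropertyTable(),
                          matrix = loadSubstitutionMatrix(),
                          verbose = FALSE) {
  stopifnot(is(x, "PeptideSet"), is(config, "ModelConfig"))
  folds <- stratifiedKFold(labels(x), nFolds = nFolds, seed = seed)
  es <- encodeDataset(x, config@combination, k = config@k, table = table,
                      matrix = matrix)
  reports <- vector("list", folds@nFolds)
  pooled <- vector("list", folds@nFolds)
  for (f in seq_len(folds@nFolds)) {
    if (verbose) message(sprintf("fold %d/%d", f, folds@nFolds))
    testIdx <- which(folds@assignments == f)
    trainIdx <- which(folds@assignments != f)
    cfg <- config
    cfg@seed <- as.integer(seed + f)
    fit <- trainMHCNN(buildMHCNN(cfg), .subsetStacks(es, trainIdx),
                      verbose = FALSE)
    probs <- predictProba(fit, .subsetStacks(es, testIdx))
    truth <- es@labels[testIdx]
    reports[[f]] <- evaluatePredictions(truth, probs[, "pos"])
    pooled[[f]] <- data.frame(id = es@ids[testIdx], fold = f, truth = truth,
                              score = probs[, "pos"],
                              pred = predictLabel(probs))
  }
  pooled <- do.call(rbind, pooled)
  rownames(pooled) <- NULL
  metrics <- c("accuracy", "sensitivity", "specificity", "precision", "mcc",
               "auc")
  perFold <- vapply(reports, function(r)
    c(r@accuracy, r@sensitivity, r@specificity, r@precision, r@mcc, r@auc),
    numeric(6))
  summary <- data.frame(metric = metrics,
                        mean = apply(perFold, 1L, mean),
                        sd = apply(perFold, 1L, sd))
  new("CVResult", folds = folds, reports = reports, summary = summary,
      pooled = pooled, auc = rocAuc(pooled$truth, pooled$score)$auc,
      combination = config@combination)
}

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d-fold CV, combination {%s}\n", object@folds@nFolds,
              paste(object@combination, collapse = ", ")))
  s <- object@summary
  for (i in seq_len(nrow(s))) {
    digits <- if (s$metric[i] %in% c("mcc", "auc")) 2L else 1L
    cat(sprintf("  %-12s %s (%s)\n", s$metric[i],
                formatC(s$mean[i], format = "f", digits = digits),
                formatC(s$sd[i], format = "f", digits = digits)))
  }
  cat(sprintf("  pooled out-of-fold AUC: %.2f\n", object@auc))
})

#' Cross-validation report table
#'
#' Formats a [CVResult-class] the way benchmark tables are usually printed:
#' one row per fold plus a mean (STD) row, percent metrics to 1 decimal
#' place and MCC/AUC to 2.
#'
#' @param cv A [CVResult-class].
#' @return Data frame of formatted strings.
#' @export
cvReportTable <- function(cv) {
  stopifnot(is(cv, "CVResult"))
  rows <- lapply(seq_along(cv@reports), function(f) {
    r <- cv@reports[[f]]
    data.frame(fold = as.character(f),
               accuracy = sprintf("%.1f", r@accuracy),
               sensitivity = sprintf("%.1f", r@sensitivity),
               specificity = sprintf("%.1f", r@specificity),
               precision = sprintf("%.1f", r@precision),
               mcc = sprintf("%.2f", r@mcc),
               auc = sprintf("%.2f", r@auc))
  })
  s <- cv@summary; m <- setNames(s$mean, s$metric); sdv <- setNames(s$sd, s$metric)
  rows[[length(rows) + 1L]] <- data.frame(
    fold = "mean (STD)",
    accuracy = sprintf("%.1f (%.1f)", m["accuracy"], sdv["accuracy"]),
    sensitivity = sprintf("%.1f (%.1f)", m["sensitivity"], sdv["sensitivity"]),
    specificity = sprintf("%.1f (%.1f)", m["specificity"], sdv["specificity"]),
    precision = sprintf("%.1f (%.1f)", m["precision"], sdv["precision"]),
    mcc = sprintf("%.2f (%.2f)", m["mcc"], sdv["mcc"]),
    auc = sprintf("%.2f (%.2f)", m["auc"], sdv["auc"]))
  do.call(rbind, rows)
}

#' Train on one dataset, test once on another
#'
#' Trains a single model on the training dataset (internal stratified
#' validation split for early stopping) and evaluates it exactly once on the
#' untouched test dataset.  Overlapping record ids trigger a leakage
#' warning.
#'
#' @param train,test Labelled [PeptideSet-class] objects.
#' @param config A [ModelConfig-class].
#' @param table,matrix Encoding resources.
#' @param returnModel Also return the fitted model.
#' @return An [EvaluationReport-class], or
#'   `list(report, model, scores)` when `returnModel = TRUE`.
#' @seealso [crossValidate()]
#' @export
independentTest <- function(train, test, config,
                            table = loadPropertyTable(),
                            matrix = loadSubstitutionMatrix(),
                            returnModel = FALSE) {
  stopifnot(is(train, "PeptideSet"), is(test, "PeptideSet"),
            is(config, "ModelConfig"))
  shared <- intersect(names(train), names(test))
  if (length(shared))
    warning(sprintf("possible leakage: %d record id(s) shared between train and test (e.g. %s)",
                    length(shared), shared[1]))
  k <- config@k
  trainEs <- encodeDataset(train, config@combination, k = k, table = table,
                           matrix = matrix)
  testEs <- encodeDataset(test, config@combination, k = k, table = table,
                          matrix = matrix)
  fit <- trainMHCNN(buildMHCNN(config), trainEs)
  probs <- predictProba(fit, testEs)
  report <- evaluatePredictions(testEs@labels, probs[, "pos"])
  if (returnModel)
    list(report = report, model = fit,
         scores = data.frame(id = testEs@ids, truth = testEs@labels,
                             score = probs[, "pos"],
                             pred = predictLabel(probs)))
  else report
}

#' Sweep the seven representation combinations
#'
#' Runs the evaluation once per non-empty subset of the three
#' representations (C1..C7) — cross-validation on `x`, or independent
#' testing when `test` is supplied — and tabulates the metric suite per
#' combination (with STD columns in CV mode).
#'
#' @param x Labelled [PeptideSet-class]: the CV dataset, or the training set
#'   in independent mode.
#' @param config Base [ModelConfig-class]; its `combination` is overridden
#'   per sweep row while the branch architecture is reused.
#' @param test Optional test [PeptideSet-class]; switches to independent
#'   mode.
#' @param nFolds Folds for CV mode.
#' @param seed Seed; defaults to `config@seed`.
#' @param table,matrix Encoding resources.
#' @param verbose Log progress.
#' @return Data frame with one row per combination C1..C7.
#' @export
combinationSweep <- function(x, config, test = NULL, nFolds = 5L,
                             seed = config@seed,
                             table = loadPropertyTable(),
                             matrix = loadSubstitutionMatrix(),
                             verbose = FALSE) {
  stopifnot(is(x, "PeptideSet"), is(config, "ModelConfig"))
  combos <- combinationSets()
  baseGroup <- config@groups[[1]]
  rows <- list()
  for (cname in names(combos)) {
    if (verbose) message(sprintf("combination %s {%s}", cname,
                                 paste(combos[[cname]], collapse = ", ")))
    cfg <- mhcnnConfig(k = config@k, combination = combos[[cname]],
                       groups = baseGroup, denseLayers = config@denseLayers,
                       l2Lambda = config@l2Lambda,
                       learningRate = config@learningRate,
                       batchSize = config@batchSize,
                       maxEpochs = config@maxEpochs, patience = config@patience,
                       minEpochs = config@minEpochs,
                       validationFraction = config@validationFraction,
                       seed = seed)
    if (is.null(test)) {
      cv <- crossValidate(x, cfg, nFolds = nFolds, seed = seed, table = table,
                          matrix = matrix)
      s <- cv@summary
      row <- data.frame(combination = cname,
                        representations = paste(combos[[cname]], collapse = "+"),
                        t(setNames(s$mean, s$metric)),
                        t(setNames(s$sd, paste0(s$metric, "_sd"))))
      row$auc_pooled <- cv@auc
    } else {
      r <- independentTest(x, test, cfg, table = table, matrix = matrix)
      row <- cbind(data.frame(combination = cname,
                              representations = paste(combos[[cname]],
                                                      collapse = "+")),
                   reportRow(r))
    }
    rows[[cname]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
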