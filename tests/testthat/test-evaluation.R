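test_that("stratified folds are balanced partitions for random cases", {
  set.seed(13)
  for (i in 1:30) {
    nPos <- sample(10:80, 1); nNeg <- sample(10:80, 1)
    nFolds <- sample(2:5, 1)
    labs <- sample(rep(c(1L, 0L), c(nPos, nNeg)))
    fs <- stratifiedKFold(labs, nFolds = nFolds, seed = i)
    expect_equal(length(fs@assignments), nPos + nNeg)
    expect_true(all(fs@assignments %in% seq_len(nFolds)))
    ## per-class counts and total sizes each differ by at most 1
    for (cls in c(0L, 1L)) {
      counts <- tabulate(fs@assignments[labs == cls], nFolds)
      expect_lte(max(counts) - min(counts), 1L)
    }
    sizes <- tabulate(fs@assignments, nFolds)
    expect_lte(max(sizes) - min(sizes), 1L)
  }
  ## exact divisibility: 5/5 in 5 folds -> one of each class per fold
  fs <- stratifiedKFold(rep(c(1L, 0L), 5), nFolds = 5, seed = 1)
  labs <- rep(c(1L, 0L), 5)
  for (f in 1:5)
    expect_equal(sort(labs[fs@assignments == f]), c(0L, 1L))
  ## determinism and guards
  expect_identical(stratifiedKFold(labs, 5, seed = 9)@assignments,
                   stratifiedKFold(labs, 5, seed = 9)@assignments)
  expect_error(stratifiedKFold(c(1, 1, 1, 0), nFolds = 2), "fewer members")
})

test_that("cross-validation is internally consistent", {
  ps <- generateSynthetic(syntheticSpec(nPos = 30, nNeg = 30, seed = 21))
  cfg <- presetConfig("acp740", combination = "C1", maxEpochs = 5L,
                      patience = 3L, seed = 2)
  cv <- crossValidate(ps, cfg, nFolds = 3L, seed = 5)
  expect_length(cv@reports, 3L)
  ## folds reproduce stratifiedKFold with the same inputs
  expect_identical(cv@folds@assignments,
                   stratifiedKFold(labels(ps), 3L, seed = 5)@assignments)
  ## out-of-fold scores cover the dataset exactly once
  expect_setequal(cv@pooled$id, names(ps))
  ## per-fold metrics recompute from the stored fold predictions
  for (f in 1:3) {
    sub <- cv@pooled[cv@pooled$fold == f, ]
    redo <- computeMetrics(confusionCounts(sub$truth, sub$pred))
    expect_equal(cv@reports[[f]]@accuracy, redo@accuracy)
    expect_equal(cv@reports[[f]]@mcc, redo@mcc)
  }
  ## summary mean/sd recompute from per-fold values
  accs <- vapply(cv@reports, function(r) r@accuracy, 1)
  expect_equal(cv@summary$mean[cv@summary$metric == "accuracy"], mean(accs))
  expect_equal(cv@summary$sd[cv@summary$metric == "accuracy"], sd(accs))
  ## formatted table: one row per fold plus the mean (STD) row
  tab <- cvReportTable(cv)
  expect_equal(nrow(tab), 4L)
  expect_match(tab$accuracy[4], "^[0-9.]+ \\([0-9.]+\\)$")
})

test_that("independent testing trains once and scores reproducibly", {
  train <- generateSynthetic(syntheticSpec(nPos = 25, nNeg = 25, seed = 31))
  test <- generateSynthetic(syntheticSpec(nPos = 10, nNeg = 10, seed = 32))
  test <- PeptideSet(unname(sequences(test)),
                     ids = paste0("t_", names(test)), labels = labels(test))
  cfg <- presetConfig("acp740", combination = "C1", maxEpochs = 5L,
                      patience = 3L, seed = 3)
  res <- independentTest(train, test, cfg, returnModel = TRUE)
  ## scoring the untouched test set again changes nothing
  es <- encodeDataset(test, "C1")
  again <- predictProba(res$model, es)
  expect_identical(unname(again[, "pos"]), unname(res$scores$score))
  ## shared record ids trigger a leakage warning
  expect_warning(independentTest(train, train[1:10], cfg), "leakage")
})

test_that("the combination sweep covers C1..C7 with the right branch counts", {
  ps <- generateSynthetic(syntheticSpec(nPos = 12, nNeg = 12, seed = 41,
                                        lengthRange = c(10L, 20L)))
  cfg <- presetConfig("acp740", maxEpochs = 2L, patience = 2L, seed = 1)
  tab <- combinationSweep(ps, cfg, nFolds = 2L, seed = 4)
  expect_equal(nrow(tab), 7L)
  expect_equal(tab$combination, paste0("C", 1:7))
  expect_equal(tab$representations[5], "BPF+BLO62")          # C5: 2 branches
  expect_true(all(c("accuracy", "accuracy_sd", "mcc") %in% names(tab)))
  ## C5 really uses exactly two convolutional groups
  m <- buildMHCNN(presetConfig("acp740", combination = "C5"))
  expect_length(m@params$groups, 2L)
})
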