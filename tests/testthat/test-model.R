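test_that("effective receptive field matches the perturbation oracle", {
  expect_equal(effectiveReceptiveField(c(4, 3)), 6L)
  expect_equal(effectiveReceptiveField(c(3, 3)), 5L)
  expect_equal(effectiveReceptiveField(7), 7L)
  ## all kernel stacks with lengths <= 7, depth <= 3, strides in {1, 2}
  set.seed(42)
  for (rep in 1:25) {
    depth <- sample(1:3, 1)
    kernels <- sample(1:7, depth, replace = TRUE)
    strides <- sample(1:2, depth, replace = TRUE)
    expect_equal(effectiveReceptiveField(kernels, strides),
                 bruteForceReceptiveField(kernels, strides),
                 info = paste("kernels", paste(kernels, collapse = ","),
                              "strides", paste(strides, collapse = ",")))
  }
  expect_error(effectiveReceptiveField(integer(0)), "kernel")
  expect_error(effectiveReceptiveField(c(3, 3), 1), "equal length")
})

test_that("parameter counts match the closed form for both presets", {
  closedForm <- function(cfg) {
    widths <- c(BPF = 20L, PHYSCHEM = 31L, BLO62 = 20L)
    total <- 0L; flat <- 0L
    for (r in cfg@combination) {
      g <- cfg@groups[[r]]
      total <- total + g@conv1Filters * (g@conv1Kernel * widths[[r]] + 1L)
      total <- total + g@conv2Filters * (g@conv2Kernel * g@conv1Filters + 1L)
      P2 <- cfg@k - g@conv1Kernel - g@conv2Kernel + 2L
      flat <- flat + P2 * g@conv2Filters
    }
    nin <- flat
    for (d in cfg@denseLayers) {
      total <- total + d$units * (nin + 1L)
      nin <- d$units
    }
    total + 2L * (nin + 1L)
  }
  for (preset in c("acp740", "acp500"))
    for (comb in c("C1", "C5", "C7")) {
      cfg <- presetConfig(preset, combination = comb)
      expect_equal(countParameters(buildMHCNN(cfg)), closedForm(cfg),
                   info = paste(preset, comb))
    }
  ## spot checks of the closed form itself: one conv layer 8x3 on 20
  ## channels is 8*(3*20+1) = 488; dense 8 on 24 inputs is 8*25 = 200
  expect_equal(8 * (3 * 20 + 1), 488)
  expect_equal(8 * (24 + 1), 200)
})

test_that("both Table-style presets build and a single branch feeds C3", {
  m740 <- buildMHCNN(presetConfig("acp740"))
  expect_length(m740@params$groups, 3L)
  expect_length(m740@params$dense, 1L)
  m500 <- buildMHCNN(presetConfig("acp500"))
  expect_length(m500@params$dense, 2L)
  expect_equal(m500@config@denseLayers[[1]]$units, 16L)
  mC3 <- buildMHCNN(presetConfig("acp740", combination = "C3"))
  expect_named(mC3@params$groups, "BLO62")
  ## kernel longer than k is refused
  expect_error(mhcnnConfig(k = 3, combination = "C1",
                           groups = convGroupConfig(conv1Kernel = 5)),
               "kernel")
})

test_that("inference is a normalized, pure function of its input", {
  ps <- tinyMotifSet(12)
  es <- encodeDataset(ps, "C5")
  m <- buildMHCNN(presetConfig("acp740", combination = "C5", seed = 2))
  p <- predictProba(m, es)
  expect_equal(dim(p), c(12L, 2L))
  expect_true(all(p >= 0))
  expect_equal(unname(rowSums(p)), rep(1, 12), tolerance = 1e-6)
  ## duplicated record (under fresh ids) -> identical probability pair
  dup <- PeptideSet(rep(sequences(ps)[1], 2), ids = c("d1", "d2"),
                    labels = c(1, 1))
  es2 <- encodeDataset(dup, "C5")
  p2 <- predictProba(m, es2)
  expect_equal(p2[1, ], p2[2, ], ignore_attr = TRUE)
  ## representation / shape mismatches are refused
  expect_error(predictProba(m, encodeDataset(ps, "C1")), "lack")
  expect_error(predictProba(m, encodeDataset(ps, "C5", k = 12)), "k = 12")
})

test_that("hard labels use a strict 0.5 threshold with ties to negative", {
  expect_equal(predictLabel(c(0.2, 0.5, 0.51, 0.49)), c(0L, 0L, 1L, 0L))
  probs <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2, byrow = TRUE,
                  dimnames = list(NULL, c("neg", "pos")))
  expect_equal(predictLabel(probs), c(1L, 0L))
})

test_that("the network can memorise a tiny set with regularisation off", {
  ps <- tinyMotifSet(20)
  es <- encodeDataset(ps, "C1")
  cfg <- mhcnnConfig(combination = "C1",
                     groups = convGroupConfig(conv1Dropout = 0,
                                              conv2Dropout = 0),
                     denseLayers = list(list(units = 8L, dropout = 0)),
                     l2Lambda = 0, maxEpochs = 500L,
                     validationFraction = 0, seed = 4)
  fit <- trainMHCNN(buildMHCNN(cfg), es)
  acc <- mean(predictLabel(predictProba(fit, es)) == labels(ps))
  expect_equal(acc, 1)
  expect_true(any(fit@history$trainAcc == 1))
})

test_that("training is deterministic given config and seed", {
  ps <- tinyMotifSet(30, seed = 6)
  es <- encodeDataset(ps, "C1")
  cfg <- presetConfig("acp740", combination = "C1", maxEpochs = 15L, seed = 11)
  run <- function() {
    fit <- trainMHCNN(buildMHCNN(cfg), es)
    predictProba(fit, es)
  }
  expect_identical(run(), run())   # bitwise-equal probabilities
})

test_that("degenerate training inputs are refused", {
  ps <- tinyMotifSet(10)
  es <- encodeDataset(ps, "C1")
  esOne <- es
  esOne@labels <- rep(1L, length(es@labels))
  m <- buildMHCNN(presetConfig("acp740", combination = "C1"))
  expect_error(trainMHCNN(m, esOne), "single class")
})

test_that("model archives round-trip through save and read", {
  ps <- tinyMotifSet(10)
  es <- encodeDataset(ps, "C1")
  cfg <- presetConfig("acp740", combination = "C1", maxEpochs = 2L, seed = 1)
  fit <- trainMHCNN(buildMHCNN(cfg), es)
  f <- tempfile(fileext = ".rds")
  saveMHCNN(fit, f)
  back <- readMHCNN(f)
  expect_identical(predictProba(back, es), predictProba(fit, es))
  ## config snapshot serialises to readable YAML
  y <- yaml::yaml.load(exportConfig(cfg))
  expect_equal(y$k, 15)
  expect_equal(y$groups$BPF$conv1$dropout, 0.8)
})
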