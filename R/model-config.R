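#' Configure one convolutional branch
#'
#' @param conv1Filters,conv1Kernel,conv1Dropout First layer: filter count,
#'   kernel length (residues), post-layer dropout rate.
#' @param conv2Filters,conv2Kernel,conv2Dropout Second layer, likewise.
#' @return A [ConvGroupConfig-class].
#' @examples
#' convGroupConfig()   # the 10x4 / 8x3 default branch
#' @export
convGroupConfig <- function(conv1Filters = 10L, conv1Kernel = 4L,
                            conv1Dropout = 0.8, conv2Filters = 8L,
                            conv2Kernel = 3L, conv2Dropout = 0.7) {
  new("ConvGroupConfig",
      conv1Filters = as.integer(conv1Filters),
      conv1Kernel = as.integer(conv1Kernel), conv1Dropout = conv1Dropout,
      conv2Filters = as.integer(conv2Filters),
      conv2Kernel = as.integer(conv2Kernel), conv2Dropout = conv2Dropout)
}

#' Configure the multi-headed classifier
#'
#' Assembles a full [ModelConfig-class].  Architecture hyperparameters
#' default to the ACP-740 profile (see [presetConfig()]); training
#' hyperparameters default to Adam at learning rate 1e-3, minibatches of 32,
#' up to 200 epochs with early stopping at patience 20 on validation loss,
#' and an L2 penalty weight of 1e-3.
#'
#' @param k Encoded rows per peptide.
#' @param combination Combination code (`"C1"`..`"C7"`) or subset of
#'   `c("BPF", "PHYSCHEM", "BLO62")`.
#' @param groups A single [ConvGroupConfig-class] applied to every branch, or
#'   a named list with one per active representation.
#' @param denseLayers List of dense recombination layers, each
#'   `list(units =, dropout =)` (a plain numeric `c(units, dropout)` is also
#'   accepted).
#' @param l2Lambda,learningRate,batchSize,maxEpochs,patience,validationFraction,seed
#'   Training hyperparameters; see [ModelConfig-class].
#' @param minEpochs Early-stopping warm-up: the patience counter cannot halt
#'   training before this epoch.  The high published dropout rates make the
#'   first few dozen epochs a loss plateau; stopping is only armed once the
#'   plateau can have been left.  Capped at `maxEpochs`.
#' @return A validated [ModelConfig-class].
#' @examples
#' mhcnnConfig(combination = "C1", seed = 7)
#' @export
mhcnnConfig <- function(k = 15L, combination = "C7",
                        groups = convGroupConfig(),
                        denseLayers = list(list(units = 8L, dropout = 0.7)),
                        l2Lambda = 1e-3, learningRate = 1e-3,
                        batchSize = 32L, maxEpochs = 200L, patience = 20L,
                        minEpochs = 50L, validationFraction = 0.1,
                        seed = 1L) {
  reps <- .resolveCombination(combination)
  if (is(groups, "ConvGroupConfig"))
    groups <- setNames(rep(list(groups), length(reps)), reps)
  denseLayers <- lapply(denseLayers, function(d) {
    if (!is.list(d)) d <- list(units = d[[1]], dropout = d[[2]])
    list(units = as.integer(d$units), dropout = as.numeric(d$dropout))
  })
  cfg <- new("ModelConfig", k = as.integer(k), combination = reps,
             groups = groups[reps], denseLayers = denseLayers,
             l2Lambda = l2Lambda, learningRate = learningRate,
             batchSize = as.integer(batchSize),
             maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
             minEpochs = min(as.integer(minEpochs), as.integer(maxEpochs)),
             validationFraction = validationFraction, seed = as.integer(seed))
  validObject(cfg)
  cfg
}

#' Published hyperparameter presets
#'
#' The two tuned architecture profiles: `"acp740"` (used for the ACP-740 and
#' ACP-240 benchmarks) with branches of 10 length-4 filters (dropout 0.8)
#' then 8 length-3 filters (dropout 0.7) and one dense recombination layer of
#' 8 units (dropout 0.7); `"acp500"` (used for ACP-500/ACP-164) with branches
#' of 16 length-3 filters (dropout 0.7) then 8 length-3 filters (dropout 0.5)
#' and two dense layers of 16 (dropout 0.6) and 8 (dropout 0.5) units.  Both
#' use k = 15.
#'
#' @param name `"acp740"` or `"acp500"`.
#' @param combination Combination code or representation subset (default C7).
#' @param ... Overrides passed on to [mhcnnConfig()] (e.g. `seed`,
#'   `maxEpochs`).
#' @return A [ModelConfig-class].
#' @examples
#' presetConfig("acp740", combination = "C1")@groups$BPF@conv1Dropout  # 0.8
#' @export
presetConfig <- function(name, combination = "C7", ...) {
  presets <- list(
    acp740 = list(
      groups = convGroupConfig(10L, 4L, 0.8, 8L, 3L, 0.7),
      denseLayers = list(list(units = 8L, dropout = 0.7))),
    acp500 = list(
      groups = convGroupConfig(16L, 3L, 0.7, 8L, 3L, 0.5),
      denseLayers = list(list(units = 16L, dropout = 0.6),
                         list(units = 8L, dropout = 0.5))))
  if (!name %in% names(presets))
    .configError(sprintf("unknown preset '%s'; valid presets: %s", name,
                         paste(names(presets), collapse = ", ")))
  p <- presets[[name]]
  args <- utils::modifyList(
    list(k = 15L, combination = combination, groups = p$groups,
         denseLayers = p$denseLayers),
    list(...))
  do.call(mhcnnConfig, args)
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig: k = %d, combination = {%s}\n", object@k,
              paste(object@combination, collapse = ", ")))
  for (r in object@combination) {
    g <- object@groups[[r]]
    cat(sprintf("  %s branch: conv %dx%d (drop %.1f) -> conv %dx%d (drop %.1f)\n",
                r, g@conv1Filters, g@conv1Kernel, g@conv1Dropout,
                g@conv2Filters, g@conv2Kernel, g@conv2Dropout))
  }
  for (d in object@denseLayers)
    cat(sprintf("  dense: %d units (drop %.1f)\n", d$units, d$dropout))
  cat(sprintf("  softmax head: 2 units; L2 %.1e, lr %.1e, batch %d, epochs <= %d, patience %d, seed %d\n",
              object@l2Lambda, object@learningRate, object@batchSize,
              object@maxEpochs, object@patience, object@seed))
})
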