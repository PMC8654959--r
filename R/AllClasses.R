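#' @import methods
#' @importFrom stats runif sd setNames
#' @importFrom utils head tail read.table write.table packageVersion
#' @importClassesFrom Biostrings AAStringSet
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' PeptideSet: labelled peptide sequences
#'
#' A set of validated peptide sequences (wrapping a
#' [Biostrings::AAStringSet]) with unique identifiers and an optional binary
#' label per record (1 = anticancer peptide, 0 = non-ACP, `NA` = unlabelled).
#' Sequences may contain only the 20 canonical residues plus `X`, which marks
#' a masked (nonstandard) residue admitted under the `"zero"` invalid-residue
#' policy and encodes to an all-zero row.
#'
#' @slot sequences An `AAStringSet`; element names are the record ids.
#' @slot labels Integer vector aligned with `sequences` (0, 1 or `NA`).
#' @seealso [readFasta()], [writeFasta()], [generateSynthetic()]
#' @export
setClass("PeptideSet",
  representation(sequences = "AAStringSet", labels = "integer"))

setValidity("PeptideSet", function(object) {
  msgs <- character()
  n <- length(object@sequences)
  ids <- names(object@sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msgs <- c(msgs, "every record needs a non-empty id")
  else if (anyDuplicated(ids))
    msgs <- c(msgs, sprintf("duplicated record ids: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@labels) != n)
    msgs <- c(msgs, "labels must align with sequences")
  if (!all(object@labels %in% c(0L, 1L, NA_integer_)))
    msgs <- c(msgs, "labels must be 0, 1 or NA")
  if (n > 0) {
    w <- Biostrings::width(object@sequences)
    if (any(w < 1)) msgs <- c(msgs, "sequences must have length >= 1")
    letters <- unique(unlist(strsplit(as.character(object@sequences), "",
                                      fixed = TRUE)))
    bad <- setdiff(letters, c(aminoAcidOrder(), .MASK))
    if (length(bad) > 0)
      msgs <- c(msgs, sprintf("non-canonical residue(s): %s",
                              paste(bad, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' SyntheticSpec: parameters of the synthetic peptide generator
#'
#' Describes a synthetic two-class peptide dataset: class sizes, length range,
#' an N-terminal motif implanted into positives with probability `signalProb`
#' within `motifWindow` residues of the N-terminus, background residue
#' frequencies and a seed.
#'
#' @slot nPos,nNeg Class sizes.
#' @slot lengthRange Integer `[min, max]` peptide length in residues.
#' @slot motif Residue string implanted into positives.
#' @slot motifWindow Maximum start offset (0-based) of the motif from the
#'   N-terminus.
#' @slot signalProb Probability that a positive carries the motif.
#' @slot backgroundFreqs Named numeric vector of 20 residue probabilities
#'   summing to 1.
#' @slot seed Integer seed.
#' @seealso [syntheticSpec()], [generateSynthetic()]
#' @export
setClass("SyntheticSpec",
  representation(nPos = "integer", nNeg = "integer", lengthRange = "integer",
                 motif = "character", motifWindow = "integer",
                 signalProb = "numeric", backgroundFreqs = "numeric",
                 seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msgs <- character()
  if (object@nPos < 1L || object@nNeg < 1L)
    msgs <- c(msgs, "nPos and nNeg must be >= 1")
  if (length(object@lengthRange) != 2L ||
      object@lengthRange[1] > object@lengthRange[2] ||
      object@lengthRange[1] < 1L)
    msgs <- c(msgs, "lengthRange must be [min, max] with 1 <= min <= max")
  if (nchar(object@motif) < 1L ||
      !all(.isCanonical(strsplit(object@motif, "", fixed = TRUE)[[1]])))
    msgs <- c(msgs, "motif must be a non-empty canonical residue string")
  if (length(object@lengthRange) == 2L &&
      nchar(object@motif) > object@lengthRange[1])
    msgs <- c(msgs, "motif longer than minimum sequence length (infeasible)")
  if (object@motifWindow < 0L)
    msgs <- c(msgs, "motifWindow must be >= 0")
  if (object@signalProb < 0 || object@signalProb > 1)
    msgs <- c(msgs, "signalProb must be in [0, 1]")
  if (length(object@backgroundFreqs) != 20L ||
      !identical(names(object@backgroundFreqs), aminoAcidOrder()) ||
      any(object@backgroundFreqs < 0) ||
      abs(sum(object@backgroundFreqs) - 1) > 1e-9)
    msgs <- c(msgs, "backgroundFreqs must be 20 probabilities (canonical order) summing to 1")
  if (length(msgs)) msgs else TRUE
})

#' PropertyTable: physicochemical group memberships
#'
#' Backs the 31-bit physicochemical encoding: 10 (possibly overlapping)
#' residue classes plus 7 attributes, each a partition of the 20 canonical
#' residues into exactly 3 disjoint, exhaustive groups.  Validity enforces the
#' structure, not the chemistry, so the shipped table can be replaced.
#'
#' @slot overlapGroups Named list of 10 character vectors of residues.
#' @slot attributes Named list of 7 attributes; each element is a list of 3
#'   residue vectors forming a partition.
#' @slot source Path the table was loaded from.
#' @seealso [loadPropertyTable()], [encodePhyschem()]
#' @export
setClass("PropertyTable",
  representation(overlapGroups = "list", attributes = "list",
                 source = "character"))

setValidity("PropertyTable", function(object) {
  msgs <- character()
  aa <- aminoAcidOrder()
  if (length(object@overlapGroups) != 10L)
    msgs <- c(msgs, sprintf("need exactly 10 overlap groups, got %d",
                            length(object@overlapGroups)))
  for (g in names(object@overlapGroups)) {
    bad <- setdiff(object@overlapGroups[[g]], aa)
    if (length(bad))
      msgs <- c(msgs, sprintf("overlap group '%s': unknown residue(s) %s",
                              g, paste(bad, collapse = ", ")))
  }
  if (length(object@attributes) != 7L)
    msgs <- c(msgs, sprintf("need exactly 7 attributes, got %d",
                            length(object@attributes)))
  for (a in names(object@attributes)) {
    groups <- object@attributes[[a]]
    if (length(groups) != 3L) {
      msgs <- c(msgs, sprintf("attribute '%s' must have exactly 3 groups", a))
      next
    }
    members <- unlist(groups)
    dup <- unique(members[duplicated(members)])
    if (length(dup))
      msgs <- c(msgs, sprintf("attribute '%s' is not a partition: %s in more than one group",
                              a, paste(dup, collapse = ", ")))
    missing <- setdiff(aa, members)
    if (length(missing))
      msgs <- c(msgs, sprintf("attribute '%s' is not exhaustive: missing %s",
                              a, paste(missing, collapse = ", ")))
    bad <- setdiff(members, aa)
    if (length(bad))
      msgs <- c(msgs, sprintf("attribute '%s': unknown residue(s) %s",
                              a, paste(bad, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' SubstitutionMatrix: residue substitution scores
#'
#' A symmetric 20 x 20 integer score matrix over the canonical alphabet in
#' [aminoAcidOrder()]; rows serve as evolutionary per-residue feature vectors.
#'
#' @slot scores 20 x 20 symmetric matrix, dimnames in canonical order.
#' @slot name Free-text matrix name (e.g. "BLOSUM62").
#' @seealso [loadSubstitutionMatrix()], [encodeBlosum()]
#' @export
setClass("SubstitutionMatrix",
  representation(scores = "matrix", name = "character"))

setValidity("SubstitutionMatrix", function(object) {
  msgs <- character()
  s <- object@scores
  aa <- aminoAcidOrder()
  if (!identical(dim(s), c(20L, 20L)))
    msgs <- c(msgs, "scores must be 20 x 20")
  else {
    if (!identical(rownames(s), aa) || !identical(colnames(s), aa))
      msgs <- c(msgs, "scores dimnames must be the canonical alphabet in order")
    if (!isTRUE(all.equal(s, t(s))))
      msgs <- c(msgs, "scores must be symmetric")
  }
  if (length(msgs)) msgs else TRUE
})

#' EncodedStacks: per-representation encoded matrices for a dataset
#'
#' One 3-D array per active representation (`n` records x `k` rows x `d`
#' columns; `d` = 20 for BPF and BLO62, 31 for PHYSCHEM), with an aligned
#' label vector.  Row `i` of every stack encodes the same peptide.
#'
#' @slot stacks Named list of 3-D numeric arrays.
#' @slot labels Integer labels aligned with the first array dimension.
#' @slot k Number of encoded rows per peptide.
#' @slot ids Record ids aligned with the first array dimension.
#' @seealso [encodeDataset()]
#' @export
setClass("EncodedStacks",
  representation(stacks = "list", labels = "integer", k = "integer",
                 ids = "character"))

setValidity("EncodedStacks", function(object) {
  msgs <- character()
  widths <- c(BPF = 20L, PHYSCHEM = 31L, BLO62 = 20L)
  if (length(object@stacks) < 1L)
    msgs <- c(msgs, "at least one representation stack required")
  bad <- setdiff(names(object@stacks), names(widths))
  if (length(bad))
    msgs <- c(msgs, sprintf("unknown representation(s): %s",
                            paste(bad, collapse = ", ")))
  for (r in intersect(names(object@stacks), names(widths))) {
    d <- dim(object@stacks[[r]])
    if (length(d) != 3L || d[2] != object@k || d[3] != widths[[r]])
      msgs <- c(msgs, sprintf("%s stack must be n x %d x %d", r, object@k,
                              widths[[r]]))
    if (d[1] != length(object@labels))
      msgs <- c(msgs, sprintf("%s stack row count disagrees with labels", r))
  }
  if (length(msgs)) msgs else TRUE
})

#' ConvGroupConfig: one convolutional branch
#'
#' Hyperparameters of a two-layer convolutional group (one branch of the
#' multi-headed network): filter counts, kernel lengths (in residues) and
#' post-layer dropout rates.
#'
#' @slot conv1Filters,conv2Filters Filter counts.
#' @slot conv1Kernel,conv2Kernel Kernel lengths in residues.
#' @slot conv1Dropout,conv2Dropout Dropout rates in `[0, 1)`.
#' @seealso [convGroupConfig()], [mhcnnConfig()]
#' @export
setClass("ConvGroupConfig",
  representation(conv1Filters = "integer", conv1Kernel = "integer",
                 conv1Dropout = "numeric", conv2Filters = "integer",
                 conv2Kernel = "integer", conv2Dropout = "numeric"))

setValidity("ConvGroupConfig", function(object) {
  msgs <- character()
  if (object@conv1Filters < 1L || object@conv2Filters < 1L)
    msgs <- c(msgs, "filter counts must be >= 1")
  if (object@conv1Kernel < 1L || object@conv2Kernel < 1L)
    msgs <- c(msgs, "kernel lengths must be >= 1")
  if (any(c(object@conv1Dropout, object@conv2Dropout) < 0) ||
      any(c(object@conv1Dropout, object@conv2Dropout) >= 1))
    msgs <- c(msgs, "dropout rates must be in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' ModelConfig: full architecture and training configuration
#'
#' Everything needed to build and train the classifier: input rows `k`, the
#' active representation combination, one [ConvGroupConfig-class] per branch,
#' the dense recombination layers, regularisation and optimiser settings, and
#' the seed.
#'
#' @slot k Encoded rows per peptide.
#' @slot combination Character subset of `c("BPF", "PHYSCHEM", "BLO62")`.
#' @slot groups Named list of `ConvGroupConfig`, one per active representation.
#' @slot denseLayers List of `list(units =, dropout =)` recombination layers.
#' @slot l2Lambda L2 penalty weight (penalty is `l2Lambda * sum(w^2)`).
#' @slot learningRate,batchSize,maxEpochs,patience Adam learning rate,
#'   minibatch size, epoch cap and early-stopping patience (epochs).
#' @slot minEpochs Early-stopping warm-up: the patience counter cannot halt
#'   training before this epoch (high dropout rates make the first epochs a
#'   loss plateau).
#' @slot validationFraction Fraction of the training set held out (stratified)
#'   for early stopping when no explicit validation set is given; 0 disables
#'   early stopping.
#' @slot seed Integer seed for initialisation, shuffling and dropout.
#' @seealso [mhcnnConfig()], [presetConfig()], [buildMHCNN()]
#' @export
setClass("ModelConfig",
  representation(k = "integer", combination = "character", groups = "list",
                 denseLayers = "list", l2Lambda = "numeric",
                 learningRate = "numeric", batchSize = "integer",
                 maxEpochs = "integer", patience = "integer",
                 minEpochs = "integer", validationFraction = "numeric",
                 seed = "integer"))

setValidity("ModelConfig", function(object) {
  msgs <- character()
  reps <- c("BPF", "PHYSCHEM", "BLO62")
  if (length(object@combination) < 1L ||
      !all(object@combination %in% reps) ||
      anyDuplicated(object@combination))
    msgs <- c(msgs, "combination must be a non-empty subset of BPF/PHYSCHEM/BLO62")
  if (length(object@groups) != length(object@combination) ||
      !identical(sort(names(object@groups)), sort(object@combination)))
    msgs <- c(msgs, "need exactly one ConvGroupConfig per active representation")
  if (length(object@denseLayers) < 1L)
    msgs <- c(msgs, "at least one dense recombination layer required")
  for (g in object@groups) {
    if (!is(g, "ConvGroupConfig")) {
      msgs <- c(msgs, "groups must be ConvGroupConfig objects"); next
    }
    if (g@conv1Kernel > object@k)
      msgs <- c(msgs, sprintf("conv1 kernel (%d) longer than k (%d)",
                              g@conv1Kernel, object@k))
    else if (g@conv2Kernel > object@k - g@conv1Kernel + 1L)
      msgs <- c(msgs, "conv2 kernel longer than the conv1 output length")
  }
  for (d in object@denseLayers) {
    if (!is.list(d) || is.null(d$units) || is.null(d$dropout) ||
        d$units < 1 || d$dropout < 0 || d$dropout >= 1)
      msgs <- c(msgs, "dense layers must be list(units >= 1, dropout in [0,1))")
  }
  if (object@k < 1L) msgs <- c(msgs, "k must be >= 1")
  if (object@l2Lambda < 0) msgs <- c(msgs, "l2Lambda must be >= 0")
  if (object@learningRate <= 0) msgs <- c(msgs, "learningRate must be > 0")
  if (object@batchSize < 1L) msgs <- c(msgs, "batchSize must be >= 1")
  if (object@maxEpochs < 1L) msgs <- c(msgs, "maxEpochs must be >= 1")
  if (object@patience < 1L) msgs <- c(msgs, "patience must be >= 1")
  if (object@minEpochs < 0L) msgs <- c(msgs, "minEpochs must be >= 0")
  if (object@validationFraction < 0 || object@validationFraction >= 1)
    msgs <- c(msgs, "validationFraction must be in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' MHCNN: the multi-headed convolutional classifier
#'
#' A built (and possibly trained) multi-headed convolutional network.  Weights
#' live in `params`; `history` records per-epoch training/validation loss and
#' accuracy once trained.
#'
#' @slot config The [ModelConfig-class] snapshot.
#' @slot params Named list of weight matrices and bias vectors.
#' @slot trained Logical.
#' @slot history Data frame of per-epoch loss/accuracy (empty until trained).
#' @seealso [buildMHCNN()], [trainMHCNN()], [predictProba()]
#' @export
setClass("MHCNN",
  representation(config = "ModelConfig", params = "list", trained = "logical",
                 history = "data.frame"))

#' ConfusionCounts: the 2 x 2 confusion table
#'
#' @slot tp,tn,fp,fn Non-negative integer counts (positive class = ACP = 1).
#' @seealso [confusionCounts()], [computeMetrics()]
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", tn = "integer", fp = "integer",
                 fn = "integer"))

setValidity("ConfusionCounts", function(object) {
  if (any(c(object@tp, object@tn, object@fp, object@fn) < 0L))
    "counts must be non-negative" else TRUE
})

#' EvaluationReport: metric suite for one evaluation
#'
#' Accuracy, sensitivity, specificity and precision on the percent scale,
#' Matthews correlation coefficient in `[-1, 1]`, optional AUC in `[0, 1]`,
#' plus the underlying confusion counts.
#'
#' @slot accuracy,sensitivity,specificity,precision Percentages in `[0, 100]`.
#' @slot mcc Matthews correlation coefficient.
#' @slot auc Area under the ROC curve (`NA` when scores were unavailable).
#' @slot counts A [ConfusionCounts-class].
#' @seealso [computeMetrics()], [evaluatePredictions()]
#' @export
setClass("EvaluationReport",
  representation(accuracy = "numeric", sensitivity = "numeric",
                 specificity = "numeric", precision = "numeric",
                 mcc = "numeric", auc = "numeric", counts = "ConfusionCounts"))

#' FoldSplit: a stratified k-fold partition
#'
#' @slot nFolds Number of folds.
#' @slot assignments Integer fold index (1..nFolds) per record.
#' @slot seed Seed the split was drawn with.
#' @seealso [stratifiedKFold()]
#' @export
setClass("FoldSplit",
  representation(nFolds = "integer", assignments = "integer",
                 seed = "integer"))

#' CVResult: stratified cross-validation output
#'
#' Per-fold [EvaluationReport-class]s, their mean/STD summary, and pooled
#' out-of-fold scores for the dataset-level ROC curve.
#'
#' @slot folds The [FoldSplit-class] used.
#' @slot reports List of per-fold reports.
#' @slot summary Data frame: metric, mean, sd.
#' @slot pooled Data frame of out-of-fold id, fold, truth, score, pred.
#' @slot auc AUC of the pooled out-of-fold scores.
#' @slot combination Representation combination evaluated.
#' @seealso [crossValidate()]
#' @export
setClass("CVResult",
  representation(folds = "FoldSplit", reports = "list", summary = "data.frame",
                 pooled = "data.frame", auc = "numeric",
                 combination = "character"))
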