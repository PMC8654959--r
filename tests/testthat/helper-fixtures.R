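## Shared fixtures and independent oracles used across the test files.

writeTempFasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

## NCBI-format identity-like substitution matrix (diag 1, off-diag 0)
writeIdentityMatrixFile <- function() {
  aa <- aminoAcidOrder()
  f <- tempfile(fileext = ".txt")
  con <- file(f, "w")
  writeLines(c("# identity toy matrix",
               paste(" ", paste(aa, collapse = "  "))), con)
  eye <- diag(20)
  for (i in seq_along(aa))
    writeLines(paste(aa[i], paste(eye[i, ], collapse = "  ")), con)
  close(con)
  f
}

## brute-force receptive field: run a stack of valid stride-1 convolutions
## with all-ones kernels on a one-hot input impulse and count which input
## rows reach output unit 1 of the final layer
bruteForceReceptiveField <- function(kernels, strides) {
  n <- 64L
  convOnes <- function(x, kl, stride) {
    starts <- seq(1L, length(x) - kl + 1L, by = stride)
    vapply(starts, function(s) sum(x[s:(s + kl - 1L)]), 1)
  }
  affected <- logical(n)
  for (r in seq_len(n)) {
    x <- numeric(n); x[r] <- 1
    for (i in seq_along(kernels)) x <- convOnes(x, kernels[i], strides[i])
    affected[r] <- x[1] != 0
  }
  sum(affected)
}

## pairwise-concordance AUC: fraction of (positive, negative) pairs ranked
## correctly, ties counting one half
concordanceAUC <- function(truth, scores) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

## direct recount of the metric formulas from raw prediction vectors
bruteForceMetrics <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1); tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  c(accuracy = (tp + tn) / (tp + tn + fp + fn) * 100,
    sensitivity = tp / (tp + fn) * 100,
    specificity = tn / (tn + fp) * 100,
    precision = tp / (tp + fp) * 100,
    mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

## small labelled set with a deterministic composition-shifted signal, for
## cheap training tests that should not depend on the motif generator
tinyMotifSet <- function(n = 20L, seed = 5L) {
  generateSynthetic(syntheticSpec(nPos = ceiling(n / 2), nNeg = floor(n / 2),
                                  lengthRange = c(10L, 20L), seed = seed))
}
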