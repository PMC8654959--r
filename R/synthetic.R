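#' Specify a synthetic peptide dataset
#'
#' Builds a [SyntheticSpec-class] for the motif-implant generator.  Defaults
#' emulate the anticancer-peptide setting: short peptides of 10-50 residues
#' drawn from a uniform background, positives carrying a length-6 N-terminal
#' motif (matching the default network's effective receptive field of 6) at a
#' configurable signal strength.
#'
#' @param nPos,nNeg Number of positive / negative records.
#' @param lengthRange Integer `[min, max]` peptide length.
#' @param motif Residue string implanted into positives.
#' @param motifWindow Maximum 0-based start offset of the motif from the
#'   N-terminus (start position is uniform on `0..motifWindow`).
#' @param signalProb Probability a positive carries the motif; the remaining
#'   positives and all negatives are pure background.
#' @param backgroundFreqs Named numeric vector of 20 residue probabilities in
#'   canonical order, summing to 1.  Default: uniform.
#' @param seed Integer seed; identical specs generate byte-identical data.
#' @return A [SyntheticSpec-class].
#' @examples
#' syntheticSpec(nPos = 5, nNeg = 5, seed = 7)
#' @seealso [generateSynthetic()]
#' @export
syntheticSpec <- function(nPos = 300L, nNeg = 300L, lengthRange = c(10L, 50L),
                          motif = "KWKLFK", motifWindow = 5L,
                          signalProb = 1.0,
                          backgroundFreqs = NULL, seed = 1L) {
  if (is.null(backgroundFreqs))
    backgroundFreqs <- setNames(rep(1 / 20, 20L), aminoAcidOrder())
  new("SyntheticSpec", nPos = as.integer(nPos), nNeg = as.integer(nNeg),
      lengthRange = as.integer(lengthRange), motif = toupper(motif),
      motifWindow = as.integer(motifWindow), signalProb = signalProb,
      backgroundFreqs = backgroundFreqs, seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0("SyntheticSpec: %d positives + %d negatives, lengths %d-%d,\n",
                     "  motif '%s' within %d residue(s) of the N-terminus,",
                     " signalProb %.2f, seed %d\n"),
              object@nPos, object@nNeg, object@lengthRange[1],
              object@lengthRange[2], object@motif, object@motifWindow,
              object@signalProb, object@seed))
})

#' Generate a synthetic labelled peptide dataset
#'
#' Draws `nPos` positives and `nNeg` negatives from the background residue
#' distribution; each positive carries the motif (implanted by overwriting
#' background residues at a start offset uniform on `0..motifWindow`) with
#' probability `signalProb`.  With `signalProb = 0` the two classes are
#' distributionally identical.  Fully deterministic given the spec's seed.
#'
#' @param spec A [SyntheticSpec-class].
#' @return A labelled [PeptideSet-class] (`pos_*` then `neg_*` records).
#' @examples
#' ps <- generateSynthetic(syntheticSpec(nPos = 3, nNeg = 3, seed = 42))
#' sequences(ps)
#' @export
generateSynthetic <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  aa <- aminoAcidOrder()
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldseed)) assign(".Random.seed", oldseed, envir = globalenv())
  })
  set.seed(spec@seed)

  drawBackground <- function(len)
    paste(sample(aa, len, replace = TRUE, prob = spec@backgroundFreqs),
          collapse = "")
  drawLength <- function()
    sample(seq(spec@lengthRange[1], spec@lengthRange[2]), 1L)

  motifChars <- strsplit(spec@motif, "", fixed = TRUE)[[1]]
  mlen <- length(motifChars)

  n <- spec@nPos + spec@nNeg
  seqs <- character(n)
  for (i in seq_len(spec@nPos)) {
    len <- drawLength()
    s <- strsplit(drawBackground(len), "", fixed = TRUE)[[1]]
    if (runif(1) < spec@signalProb) {
      maxStart <- min(spec@motifWindow, len - mlen)
      start <- if (maxStart > 0) sample(0:maxStart, 1L) else 0L
      s[(start + 1):(start + mlen)] <- motifChars
    }
    seqs[i] <- paste(s, collapse = "")
  }
  for (i in seq_len(spec@nNeg))
    seqs[spec@nPos + i] <- drawBackground(drawLength())

  ids <- c(sprintf("pos_%04d", seq_len(spec@nPos)),
           sprintf("neg_%04d", seq_len(spec@nNeg)))
  PeptideSet(seqs, ids = ids,
             labels = rep(c(1L, 0L), c(spec@nPos, spec@nNeg)))
}
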