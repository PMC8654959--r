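#' Tokenize a peptide to k N-terminal residues with post-padding
#'
#' Keeps the first `min(length, k)` residues and appends PAD tokens (`"-"`)
#' so every peptide becomes exactly `k` tokens; PAD occupies only a
#' contiguous suffix.
#'
#' @param sequence A residue string (canonical alphabet, optionally `X`).
#' @param k Number of tokens (default 15, the standard truncation depth for
#'   this classifier).
#' @return Character vector of `k` tokens.
#' @examples
#' tokenize("FLPKA")         # 5 residues + 10 PAD
#' tokenize("ACDEFGHIKLMNPQRSTVWY", k = 15)
#' @export
tokenize <- function(sequence, k = 15L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) .configError("k must be a positive integer")
  sequence <- toupper(trimws(sequence))
  if (nchar(sequence) < 1L) .dataError("cannot tokenize an empty sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- unique(chars[!(chars %in% c(aminoAcidOrder(), .MASK))])
  if (length(bad))
    .dataError(sprintf("non-canonical residue(s): %s", paste(bad, collapse = ", ")))
  c(head(chars, k), rep(.PAD, max(0L, k - length(chars))))
}

## shared row-lookup encoder: rows for the 20 residues from `lookup`,
## all-zero rows for PAD and masked residues
.encodeTokens <- function(tokens, lookup, representation) {
  d <- ncol(lookup)
  full <- rbind(lookup,
                matrix(0, 2L, d, dimnames = list(c(.PAD, .MASK), NULL)))
  idx <- match(tokens, rownames(full))
  if (anyNA(idx))
    .dataError(sprintf("%s encoding: residue(s) %s not in table", representation,
                       paste(unique(tokens[is.na(idx)]), collapse = ", ")))
  m <- full[idx, , drop = FALSE]
  rownames(m) <- tokens
  pad <- which(tokens == .PAD)
  if (length(pad) && (min(pad) + length(pad) - 1L) != length(tokens))
    .dataError("PAD tokens must form a contiguous suffix (post-padding)")
  m
}

#' Binary profile (one-hot) encoding
#'
#' Encodes tokens into a `k x 20` matrix: each residue row is one-hot in the
#' canonical order ([aminoAcidOrder()]); PAD (and masked `X`) rows are
#' all-zero.
#'
#' @param tokens Output of [tokenize()].
#' @return Numeric `k x 20` matrix.
#' @examples
#' encodeBPF(tokenize("AV", k = 4))   # hot at columns 1 and 20, then zeros
#' @export
encodeBPF <- function(tokens) {
  aa <- aminoAcidOrder()
  eye <- diag(20)
  dimnames(eye) <- list(aa, aa)
  .encodeTokens(tokens, eye, "BPF")
}

#' Physicochemical 31-bit encoding
#'
#' Encodes tokens into a `k x 31` 0/1 matrix: per residue, columns 1-10 are
#' overlap-group membership bits and columns 11-31 the 21 attribute-partition
#' bits (exactly 7 ones: one group per attribute).  PAD rows are all-zero.
#'
#' @param tokens Output of [tokenize()].
#' @param table A [PropertyTable-class]; default is the shipped table.
#' @return Numeric `k x 31` matrix.
#' @examples
#' m <- encodePhyschem(tokenize("KDE", k = 5))
#' rowSums(m[1:3, 11:31])   # 7 7 7
#' @export
encodePhyschem <- function(tokens, table = loadPropertyTable()) {
  .encodeTokens(tokens, propertyBits(table), "PHYSCHEM")
}

#' Substitution-matrix (evolutionary) encoding
#'
#' Encodes tokens into a `k x 20` matrix whose residue rows are the raw
#' integer substitution-matrix rows (no rescaling); PAD rows are all-zero.
#'
#' @param tokens Output of [tokenize()].
#' @param matrix A [SubstitutionMatrix-class]; default is the shipped
#'   BLOSUM62.
#' @return Numeric `k x 20` matrix.
#' @examples
#' m <- encodeBlosum(tokenize("A", k = 2))
#' m["A", "A"]   # the BLOSUM62 A<->A score, 4
#' @export
encodeBlosum <- function(tokens, matrix = loadSubstitutionMatrix()) {
  stopifnot(is(matrix, "SubstitutionMatrix"))
  .encodeTokens(tokens, matrix@scores, "BLO62")
}

## canonical names of the three representations and the C1..C7 subsets
.REPS <- c("BPF", "PHYSCHEM", "BLO62")

#' The seven representation combinations
#'
#' Named list mapping the combination codes C1..C7 to the corresponding
#' non-empty subsets of the three representations: C1 = BPF, C2 = PHYSCHEM,
#' C3 = BLO62, C4 = BPF+PHYSCHEM, C5 = BPF+BLO62, C6 = PHYSCHEM+BLO62,
#' C7 = all three.
#'
#' @return Named list of character vectors.
#' @examples
#' combinationSets()$C5
#' @export
combinationSets <- function() {
  list(C1 = "BPF", C2 = "PHYSCHEM", C3 = "BLO62",
       C4 = c("BPF", "PHYSCHEM"), C5 = c("BPF", "BLO62"),
       C6 = c("PHYSCHEM", "BLO62"), C7 = .REPS)
}

## accept either a combination code ("C5") or a vector of representation names
.resolveCombination <- function(combination) {
  if (length(combination) == 1L && grepl("^C[1-7]$", combination))
    return(combinationSets()[[combination]])
  combination <- toupper(combination)
  if (length(combination) < 1L || !all(combination %in% .REPS))
    .configError(sprintf(
      "combination must be C1..C7 or a non-empty subset of %s",
      paste(.REPS, collapse = "/")))
  .REPS[.REPS %in% combination]   # canonical order, deduplicated
}

#' Encode a dataset into per-representation matrix stacks
#'
#' Tokenizes every peptide to `k` N-terminal residues (post-padded) and
#' builds one `n x k x d` array per selected representation, all sharing the
#' dataset's record order, plus the aligned label vector.
#'
#' @param x A [PeptideSet-class].
#' @param combination A combination code (`"C1"`..`"C7"`) or a subset of
#'   `c("BPF", "PHYSCHEM", "BLO62")`.
#' @param k Rows per peptide (default 15), or `"max"` for full-sequence mode
#'   (`k` = longest sequence in `x`).
#' @param table,matrix Property table / substitution matrix to encode with;
#'   defaults are the shipped files.
#' @return An [EncodedStacks-class].
#' @examples
#' ps <- generateSynthetic(syntheticSpec(nPos = 3, nNeg = 3, seed = 1))
#' es <- encodeDataset(ps, "C7")
#' vapply(es@stacks, function(a) dim(a)[3], 1)   # 20, 31, 20
#' @export
encodeDataset <- function(x, combination = "C7", k = 15L,
                          table = loadPropertyTable(),
                          matrix = loadSubstitutionMatrix()) {
  stopifnot(is(x, "PeptideSet"))
  if (length(x) == 0L) .dataError("cannot encode an empty PeptideSet")
  reps <- .resolveCombination(combination)
  seqs <- sequences(x)
  if (identical(k, "max")) k <- max(nchar(seqs))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) .configError("k must be a positive integer or \"max\"")

  lookups <- list(
    BPF = `dimnames<-`(diag(20), list(aminoAcidOrder(), aminoAcidOrder())),
    PHYSCHEM = propertyBits(table),
    BLO62 = matrix@scores)

  ## token index matrix (n x k) into lookup rows; 21/22 = PAD/MASK zero rows
  n <- length(seqs)
  aaIdx <- setNames(seq_len(22L), c(aminoAcidOrder(), .PAD, .MASK))
  tokIdx <- base::matrix(aaIdx[[.PAD]], nrow = n, ncol = k)
  for (i in seq_len(n)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    take <- head(chars, k)
    tokIdx[i, seq_along(take)] <- aaIdx[take]
  }

  stacks <- lapply(lookups[reps], function(L) {
    full <- rbind(L, base::matrix(0, 2L, ncol(L)))
    array(full[as.vector(tokIdx), ], dim = c(n, k, ncol(L)),
          dimnames = list(names(seqs), NULL, colnames(L)))
  })
  out <- new("EncodedStacks", stacks = stacks, labels = labels(x),
             k = k, ids = names(x))
  validObject(out)
  out
}

setMethod("show", "EncodedStacks", function(object) {
  dims <- vapply(object@stacks,
                 function(a) sprintf("%d x %d x %d", dim(a)[1], dim(a)[2],
                                     dim(a)[3]), "")
  cat(sprintf("EncodedStacks (k = %d): %s\n", object@k,
              paste(sprintf("%s [%s]", names(dims), dims), collapse = ", ")))
  cat(sprintf("  labels: %d positive / %d negative / %d NA\n",
              sum(object@labels == 1L, na.rm = TRUE),
              sum(object@labels == 0L, na.rm = TRUE), sum(is.na(object@labels))))
})

#' Export encoded stacks as delimited matrix dumps
#'
#' Writes one tab-delimited file per representation (`<prefix>_<REP>.tsv`):
#' one row per record, columns are the flattened `k x d` matrix in
#' column-major order (`pos1.col1, pos2.col1, ...`), preceded by id and
#' label.
#'
#' @param stacks An [EncodedStacks-class].
#' @param prefix Output path prefix.
#' @return Paths written, invisibly.
#' @export
exportEncoded <- function(stacks, prefix) {
  stopifnot(is(stacks, "EncodedStacks"))
  paths <- character(0)
  for (r in names(stacks@stacks)) {
    a <- stacks@stacks[[r]]
    flat <- base::matrix(a, nrow = dim(a)[1])
    df <- data.frame(id = stacks@ids, label = stacks@labels, flat,
                     check.names = FALSE)
    p <- sprintf("%s_%s.tsv", prefix, r)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
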