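#' Construct a PeptideSet
#'
#' Normalises sequences (uppercase, whitespace stripped, trailing `*` stop
#' characters stripped with a warning) and validates them against the
#' canonical 20-letter alphabet.
#'
#' @param sequences Character vector of residue strings (or an
#'   `AAStringSet`).
#' @param ids Character vector of unique record identifiers; defaults to the
#'   names of `sequences` or `seq1..seqN`.
#' @param labels Binary labels (0/1/`NA`), recycled if scalar.
#' @param onInvalid What to do with records containing residues outside the
#'   canonical alphabet: `"error"` (default) fails naming the record and
#'   character, `"skip"` drops the record with a warning, `"zero"` keeps the
#'   record with offending residues masked as `X` (encoded as all-zero rows).
#' @return A [PeptideSet-class].
#' @examples
#' ps <- PeptideSet(c(p1 = "FLPKA", p2 = "GGGG"), labels = c(1, 0))
#' ps
#' @export
PeptideSet <- function(sequences, ids = NULL, labels = NA,
                       onInvalid = c("error", "skip", "zero")) {
  onInvalid <- match.arg(onInvalid)
  seqs <- toupper(trimws(as.character(sequences)))
  if (is.null(ids)) ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  ids <- as.character(ids)
  if (any(grepl("\\*", seqs))) {
    warning("stripping '*' stop character(s)")
    seqs <- gsub("\\*", "", seqs)
  }
  labels <- suppressWarnings(as.integer(labels))
  if (length(labels) == 1L) labels <- rep(labels, length(seqs))
  if (length(labels) != length(seqs))
    .dataError("labels must have length 1 or match the number of sequences")

  keep <- rep(TRUE, length(seqs))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    bad <- unique(chars[!.isCanonical(chars)])
    if (length(bad) == 0) next
    switch(onInvalid,
      error = .dataError(sprintf(
        "record '%s' contains non-canonical residue(s): %s",
        ids[i], paste(bad, collapse = ", "))),
      skip = {
        warning(sprintf("skipping record '%s' (non-canonical residue(s): %s)",
                        ids[i], paste(bad, collapse = ", ")))
        keep[i] <- FALSE
      },
      zero = {
        warning(sprintf("masking residue(s) %s in record '%s' as X",
                        paste(bad, collapse = ", "), ids[i]))
        chars[!.isCanonical(chars)] <- .MASK
        seqs[i] <- paste(chars, collapse = "")
      })
  }
  seqs <- seqs[keep]; ids <- ids[keep]; labels <- labels[keep]
  aas <- Biostrings::AAStringSet(setNames(seqs, ids))
  new("PeptideSet", sequences = aas, labels = labels)
}

#' @describeIn PeptideSet-class Number of records.
#' @param x A `PeptideSet`.
#' @export
setMethod("length", "PeptideSet", function(x) length(x@sequences))

#' @describeIn PeptideSet-class Record identifiers.
#' @export
setMethod("names", "PeptideSet", function(x) names(x@sequences))

#' @describeIn PeptideSet-class Binary labels (0/1/`NA`).
#' @param object A `PeptideSet`.
#' @param ... Ignored.
#' @export
setMethod("labels", "PeptideSet", function(object, ...) object@labels)

#' Peptide sequences as a character vector
#'
#' @param x A [PeptideSet-class].
#' @return Named character vector of residue strings.
#' @export
sequences <- function(x) {
  stopifnot(is(x, "PeptideSet"))
  setNames(as.character(x@sequences), names(x@sequences))
}

#' @describeIn PeptideSet-class Subset records.
#' @param i Index vector.
#' @param j,drop Ignored.
#' @export
setMethod("[", "PeptideSet", function(x, i, j, ..., drop = TRUE) {
  new("PeptideSet", sequences = x@sequences[i], labels = x@labels[i])
})

setMethod("show", "PeptideSet", function(object) {
  n <- length(object)
  npos <- sum(object@labels == 1L, na.rm = TRUE)
  nneg <- sum(object@labels == 0L, na.rm = TRUE)
  cat(sprintf("PeptideSet with %d record(s): %d positive, %d negative, %d unlabelled\n",
              n, npos, nneg, n - npos - nneg))
  if (n > 0) {
    w <- Biostrings::width(object@sequences)
    cat(sprintf("  lengths: %d-%d residues\n", min(w), max(w)))
    shown <- head(seq_len(n), 3L)
    for (i in shown)
      cat(sprintf("  %s [%s] %s\n", names(object)[i],
                  ifelse(is.na(object@labels[i]), "?", object@labels[i]),
                  as.character(object@sequences[[i]])))
    if (n > 3L) cat(sprintf("  ... and %d more\n", n - 3L))
  }
})

#' Read peptides from FASTA
#'
#' Reads a (possibly multi-line) FASTA file into a [PeptideSet-class].
#' Labels are taken from a trailing `|1` / `|0` token on the header, unless
#' `label` is supplied, in which case it applies to every record (the usual
#' paired-file layout: one positive and one negative FASTA).
#'
#' @param path FASTA file path.
#' @param label Optional 0/1 label applied to all records.
#' @param onInvalid Policy for non-canonical residues; see [PeptideSet()].
#' @return A [PeptideSet-class].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1|1", "FLPK", ">p2|0", "GGGG"), f)
#' readFasta(f)
#' @seealso [writeFasta()]
#' @export
readFasta <- function(path, label = NULL,
                      onInvalid = c("error", "skip", "zero")) {
  onInvalid <- match.arg(onInvalid)
  if (!file.exists(path)) .dataError(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L) .dataError(sprintf("empty FASTA file: %s", path))
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    .dataError(sprintf("malformed FASTA in %s: line %d does not start a record ('>')",
                       path, nonblank[1]))
  aas <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e)
                    .dataError(sprintf("malformed FASTA in %s: %s", path,
                                       conditionMessage(e))))
  headers <- names(aas)
  ids <- headers
  labs <- rep(NA_integer_, length(aas))
  tok <- regmatches(headers, regexpr("\\|[01]$", headers))
  hasTok <- grepl("\\|[01]$", headers)
  labs[hasTok] <- as.integer(sub("\\|", "", tok))
  ids[hasTok] <- sub("\\|[01]$", "", headers[hasTok])
  ids <- trimws(vapply(strsplit(ids, "\\s+"), `[`, "", 1L))
  if (!is.null(label)) {
    if (!label %in% c(0, 1)) .configError("label must be 0 or 1")
    labs <- rep(as.integer(label), length(aas))
  }
  PeptideSet(as.character(aas), ids = ids, labels = labs,
             onInvalid = onInvalid)
}

#' Write peptides to FASTA
#'
#' Writes single-line FASTA; labelled records get a trailing `|<label>` on
#' the header so that [readFasta()] round-trips ids, sequences and labels.
#'
#' @param x A non-empty [PeptideSet-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [readFasta()]
#' @export
writeFasta <- function(x, path) {
  stopifnot(is(x, "PeptideSet"))
  if (length(x) == 0L) .dataError("refusing to write an empty PeptideSet")
  hdr <- names(x)
  lab <- labels(x)
  hdr[!is.na(lab)] <- paste0(hdr[!is.na(lab)], "|", lab[!is.na(lab)])
  out <- x@sequences
  names(out) <- hdr
  Biostrings::writeXStringSet(out, filepath = path, width = 100000L)
  invisible(path)
}

#' Apply labels from a two-column manifest
#'
#' Alternative label source: a delimited file (or data frame) with columns
#' `id` and `label`.
#'
#' @param x A [PeptideSet-class].
#' @param manifest Path to a whitespace/tab-delimited two-column file
#'   (id, label; `#` comments allowed) or a data frame.
#' @return `x` with labels replaced where the manifest provides them.
#' @export
applyLabelManifest <- function(x, manifest) {
  stopifnot(is(x, "PeptideSet"))
  if (is.character(manifest)) {
    if (!file.exists(manifest))
      .dataError(sprintf("manifest not found: %s", manifest))
    manifest <- read.table(manifest, header = FALSE, comment.char = "#",
                           col.names = c("id", "label"),
                           colClasses = c("character", "integer"))
  }
  if (!all(c("id", "label") %in% names(manifest)))
    .dataError("manifest needs columns id, label")
  m <- match(names(x), manifest$id)
  labs <- labels(x)
  labs[!is.na(m)] <- as.integer(manifest$label[m[!is.na(m)]])
  if (!all(labs %in% c(0L, 1L, NA_integer_)))
    .dataError("manifest labels must be 0 or 1")
  new("PeptideSet", sequences = x@sequences, labels = labs)
}
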