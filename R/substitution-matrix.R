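#' Load a substitution matrix in NCBI text format
#'
#' Reads a square substitution matrix in the standard NCBI layout (`#`
#' comment lines, a header row of residue letters, one row of integer scores
#' per residue).  Rows/columns outside the canonical 20-letter alphabet
#' (B, Z, X, `*`, ...) are dropped, and the matrix is re-indexed to the
#' package's canonical residue order.  Symmetry and completeness are
#' enforced.
#'
#' @param path Matrix file; default is the BLOSUM62 file shipped with the
#'   package (standard published half-bit scores).
#' @param name Matrix name recorded on the object.
#' @return A validated [SubstitutionMatrix-class].
#' @examples
#' blosum62 <- loadSubstitutionMatrix()
#' blosum62@scores["A", "A"]   # 4
#' @seealso [encodeBlosum()]
#' @export
loadSubstitutionMatrix <- function(path = system.file("extdata",
                                                      "BLOSUM62.txt",
                                                      package = "ACPcnn"),
                                   name = "BLOSUM62") {
  if (!file.exists(path)) .dataError(sprintf("matrix file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & trimws(lines) != ""]
  if (length(lines) < 2L) .dataError(sprintf("not a matrix file: %s", path))
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  rowNames <- vapply(rows, `[`, "", 1L)
  vals <- lapply(rows, function(r) suppressWarnings(as.integer(r[-1])))
  if (any(vapply(vals, length, 1L) != length(header)) ||
      anyNA(unlist(vals)))
    .dataError(sprintf("malformed matrix rows in %s", path))
  m <- do.call(rbind, vals)
  dimnames(m) <- list(rowNames, header)

  aa <- aminoAcidOrder()
  missing <- setdiff(aa, intersect(rownames(m), colnames(m)))
  if (length(missing))
    .dataError(sprintf("matrix %s missing canonical residue(s): %s", path,
                       paste(missing, collapse = ", ")))
  m <- m[aa, aa]
  asym <- which(m != t(m), arr.ind = TRUE)
  if (nrow(asym) > 0) {
    i <- asym[1, 1]; j <- asym[1, 2]
    .dataError(sprintf("asymmetric matrix: (%s,%s)=%d but (%s,%s)=%d",
                       aa[i], aa[j], m[i, j], aa[j], aa[i], m[j, i]))
  }
  new("SubstitutionMatrix", scores = m, name = name)
}

setMethod("show", "SubstitutionMatrix", function(object) {
  cat(sprintf("SubstitutionMatrix '%s': symmetric 20 x 20, scores %d..%d\n",
              object@name, min(object@scores), max(object@scores)))
})
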