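#' Canonical residue order
#'
#' The 20 canonical amino acids in the fixed column order used by every
#' encoder in the package (A, R, N, D, C, Q, E, G, H, I, L, K, M, F, P, S, T,
#' W, Y, V).  Substitution matrices are re-indexed to this order on load, so a
#' residue's one-hot column and its substitution-matrix column always agree.
#'
#' @return Character vector of length 20.
#' @examples
#' aminoAcidOrder()
#' @export
aminoAcidOrder <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

## PAD marks post-padding positions; MASK ("X") marks a residue kept under the
## "zero" invalid-residue policy.  Both encode to all-zero rows.
.PAD <- "-"
.MASK <- "X"

.isCanonical <- function(chars) chars %in% aminoAcidOrder()

## condition constructors used for CLI exit-code mapping
.configError <- function(msg) {
  stop(structure(class = c("acpConfigError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
.dataError <- function(msg) {
  stop(structure(class = c("acpDataError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
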