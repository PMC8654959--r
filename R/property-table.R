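#' Load a physicochemical property-group table
#'
#' Parses the delimited group-membership format (one line per group:
#' `group_id <TAB> segment <TAB> members`, where `segment` is either
#' `overlap` or `attribute:<name>:<index>`), and validates the structure:
#' exactly 10 overlap groups, exactly 7 attributes, each attribute's 3 groups
#' disjoint and exhaustive over the 20 canonical residues.  The shipped
#' default combines a Taylor-style overlapping classification with the
#' canonical CTD three-group attribute tables; any file passing the
#' structural checks can be substituted.
#'
#' @param path Table file; default is the table shipped with the package.
#' @return A validated [PropertyTable-class].
#' @examples
#' tab <- loadPropertyTable()
#' names(tab@attributes)
#' @seealso [encodePhyschem()], [propertyBits()]
#' @export
loadPropertyTable <- function(path = system.file("extdata",
                                                 "property_groups.tsv",
                                                 package = "ACPcnn")) {
  if (!file.exists(path)) .dataError(sprintf("property table not found: %s", path))
  tab <- read.table(path, sep = "\t", comment.char = "#",
                    col.names = c("group", "segment", "members"),
                    colClasses = "character")
  overlap <- list()
  attrGroups <- list()   # attrGroups[[name]][[index]] <- members
  attrOrder <- character()
  for (r in seq_len(nrow(tab))) {
    members <- strsplit(toupper(trimws(tab$members[r])), "", fixed = TRUE)[[1]]
    seg <- trimws(tab$segment[r])
    if (seg == "overlap") {
      overlap[[tab$group[r]]] <- members
    } else if (grepl("^attribute:[^:]+:[123]$", seg)) {
      parts <- strsplit(seg, ":", fixed = TRUE)[[1]]
      aname <- parts[2]; idx <- as.integer(parts[3])
      if (!aname %in% attrOrder) attrOrder <- c(attrOrder, aname)
      if (is.null(attrGroups[[aname]])) attrGroups[[aname]] <- vector("list", 3L)
      if (!is.null(attrGroups[[aname]][[idx]]))
        .dataError(sprintf("property table: duplicate group %d of attribute '%s'",
                           idx, aname))
      attrGroups[[aname]][[idx]] <- members
      names(attrGroups[[aname]])[idx] <- tab$group[r]
    } else {
      .dataError(sprintf("property table line %d: bad segment '%s'", r, seg))
    }
  }
  for (a in attrOrder)
    if (any(vapply(attrGroups[[a]], is.null, TRUE)))
      .dataError(sprintf("attribute '%s' does not define all 3 groups", a))
  obj <- new("PropertyTable", overlapGroups = overlap,
             attributes = attrGroups[attrOrder], source = path)
  validObject(obj)
  obj
}

#' Per-residue 31-bit property vectors
#'
#' The 20 x 31 0/1 matrix behind [encodePhyschem()]: for each canonical
#' residue, bits 1-10 are the overlap-group memberships and bits 11-31 the 21
#' attribute-partition bits (attributes in table order, each attribute's 3
#' groups in order).  Every row's 21-bit segment has exactly 7 ones, one per
#' attribute.
#'
#' @param table A [PropertyTable-class] (default: the shipped table).
#' @return Numeric 20 x 31 matrix, rows named by residue.
#' @examples
#' bits <- propertyBits()
#' rowSums(bits[, 11:31])   # all 7
#' @export
propertyBits <- function(table = loadPropertyTable()) {
  stopifnot(is(table, "PropertyTable"))
  aa <- aminoAcidOrder()
  m <- matrix(0, nrow = 20L, ncol = 31L, dimnames = list(aa, NULL))
  cols <- character(31L)
  for (g in seq_along(table@overlapGroups)) {
    m[aa %in% table@overlapGroups[[g]], g] <- 1
    cols[g] <- names(table@overlapGroups)[g]
  }
  col <- 10L
  for (a in names(table@attributes)) {
    for (i in 1:3) {
      col <- col + 1L
      m[aa %in% table@attributes[[a]][[i]], col] <- 1
      cols[col] <- sprintf("%s.%d", a, i)
    }
  }
  colnames(m) <- cols
  m
}

setMethod("show", "PropertyTable", function(object) {
  cat(sprintf("PropertyTable: 10 overlap groups + 7 attributes (31 bits/residue)\n"))
  cat("  overlap: ", paste(names(object@overlapGroups), collapse = ", "), "\n")
  cat("  attributes: ", paste(names(object@attributes), collapse = ", "), "\n")
  cat("  source: ", object@source, "\n")
})
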