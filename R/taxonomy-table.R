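#' Construct a taxonomy table
#'
#' Either from a list of [Lineage-class] objects or directly from label /
#' informative matrices.
#'
#' @param ids character vector of unique record identifiers.
#' @param lineages list of [Lineage-class], parallel to `ids` (alternative
#'   to `labels`).
#' @param labels character matrix (records x ranks).
#' @param informative logical matrix parallel to `labels`; when omitted it is
#'   recomputed from `labels` against the ambiguous vocabulary.
#' @param schema a [RankSchema-class]; defaults to the first lineage's schema.
#' @param ambiguousVocab vocabulary used when `informative` is recomputed.
#' @return A [TaxonomyTable-class].
#' @export
taxonomyTable <- function(ids, lineages = NULL, labels = NULL,
                          informative = NULL, schema = NULL,
                          ambiguousVocab = ambiguousLabelVocabulary()) {
  ids <- as.character(ids)
  if (!is.null(lineages)) {
    stopifnot(length(lineages) == length(ids))
    lm <- if (length(lineages)) .lineageMatrix(lineages) else
      list(labels = matrix(character(0), 0L, length(schema)),
           informative = matrix(logical(0), 0L, length(schema)),
           schema = schema)
    labels <- lm$labels
    informative <- lm$informative
    if (is.null(schema)) schema <- lm$schema
  }
  stopifnot(is(schema, "RankSchema"), is.matrix(labels))
  if (is.null(informative)) {
    informative <- matrix(.informativeLabels(labels, ambiguousVocab),
                          nrow = nrow(labels))
  }
  rownames(labels) <- ids
  rownames(informative) <- ids
  colnames(labels) <- schema@ranks
  colnames(informative) <- schema@ranks
  new("TaxonomyTable", schema = schema, labels = labels,
      informative = informative)
}

#' @describeIn taxonomyTable record identifiers.
#' @param x a [TaxonomyTable-class].
#' @export
taxIds <- function(x) rownames(x@labels)

#' @describeIn taxonomyTable the table's [RankSchema-class].
#' @export
taxSchema <- function(x) x@schema

#' @describeIn taxonomyTable label matrix accessor (records x ranks).
#' @export
taxLabels <- function(x) x@labels

#' @describeIn taxonomyTable informative mask accessor.
#' @export
taxInformative <- function(x) x@informative

#' Number of records in a taxonomy table
#' @param x a [TaxonomyTable-class].
#' @export
setMethod("length", "TaxonomyTable", function(x) nrow(x@labels))

#' Subset a taxonomy table by identifier or index
#'
#' @param x a [TaxonomyTable-class].
#' @param i character identifiers or integer/logical indices.
#' @param j,drop,... ignored.
#' @return A [TaxonomyTable-class].
#' @export
setMethod("[", "TaxonomyTable", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i) && !all(i %in% rownames(x@labels)))
    stop("unknown identifiers: ",
         paste(setdiff(i, rownames(x@labels)), collapse = ", "))
  initialize(x, labels = x@labels[i, , drop = FALSE],
             informative = x@informative[i, , drop = FALSE])
})

#' Extract one record as a Lineage
#'
#' @param x a [TaxonomyTable-class].
#' @param id identifier or single index.
#' @return A [Lineage-class].
#' @export
getLineage <- function(x, id) {
  stopifnot(is(x, "TaxonomyTable"))
  .newLineage(x@labels[id, ], x@informative[id, ], x@schema)
}

#' Serialized lineage strings of a taxonomy table
#'
#' @param x a [TaxonomyTable-class].
#' @return named character vector (identifier -> lineage string).
#' @export
lineageStrings <- function(x) {
  stopifnot(is(x, "TaxonomyTable"))
  n <- length(x@schema)
  if (nrow(x@labels) == 0L) return(setNames(character(0), character(0)))
  parts <- vapply(seq_len(n), function(r)
    paste0(x@schema@handles[r], x@labels[, r]), character(nrow(x@labels)))
  if (nrow(x@labels) == 1L) parts <- matrix(parts, nrow = 1L)
  setNames(apply(parts, 1L, paste, collapse = "; "), rownames(x@labels))
}

## internal: full-lineage keys used for grouping/stratification
.lineageKeys <- function(x) {
  apply(x@labels, 1L, paste, collapse = "\x1f")
}

#' Deepest informative rank per record
#'
#' @param x a [TaxonomyTable-class].
#' @return integer vector (0 for records with no informative rank).
#' @export
terminalDepths <- function(x) {
  stopifnot(is(x, "TaxonomyTable"))
  if (nrow(x@informative) == 0L) return(integer(0))
  apply(x@informative, 1L, function(v) {
    w <- which(v)
    if (length(w)) max(w) else 0L
  })
}

setMethod("show", "TaxonomyTable", function(object) {
  cat("TaxonomyTable with", nrow(object@labels), "records over",
      length(object@schema), "ranks (",
      paste(object@schema@ranks, collapse = ", "), ")\n")
  n <- min(3L, nrow(object@labels))
  if (n > 0L) {
    s <- lineageStrings(object[seq_len(n)])
    for (i in seq_len(n)) cat("  ", names(s)[i], ": ", s[i], "\n", sep = "")
    if (nrow(object@labels) > n) cat("  ...\n")
  }
})

#' Combine taxonomy tables sharing a schema
#'
#' @param x,... [TaxonomyTable-class] objects.
#' @return A [TaxonomyTable-class].
#' @export
setMethod("rbind2", signature("TaxonomyTable", "TaxonomyTable"),
  function(x, y) {
    stopifnot(identical(x@schema@handles, y@schema@handles))
    initialize(x, labels = rbind(x@labels, y@labels),
               informative = rbind(x@informative, y@informative))
  })
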