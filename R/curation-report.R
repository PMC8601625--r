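.curationReport <- function(keptIds, removed) {
  removed <- removed[vapply(removed, length, integer(1)) > 0L]
  new("CurationReport", keptIds = as.character(keptIds),
      removed = lapply(removed, as.character))
}

#' @describeIn CurationReport-class number of records kept.
#' @param x a [CurationReport-class].
#' @export
keptCount <- function(x) length(x@keptIds)

#' @describeIn CurationReport-class identifiers kept, in input order.
#' @export
keptIds <- function(x) x@keptIds

#' @describeIn CurationReport-class named list, reason -> removed identifiers.
#' @export
removedIds <- function(x) x@removed

#' @describeIn CurationReport-class total number of removed records.
#' @export
removedCount <- function(x) length(unlist(x@removed, use.names = FALSE))

setMethod("show", "CurationReport", function(object) {
  cat("CurationReport:", keptCount(object), "kept,",
      removedCount(object), "removed\n")
  for (reason in names(object@removed)) {
    cat("  ", reason, ": ", length(object@removed[[reason]]), "\n", sep = "")
  }
})

#' Tabular view of a curation report
#'
#' @param x a [CurationReport-class].
#' @param row.names,optional,... passed through (unused).
#' @return data.frame with columns `id` and `reason` (removed records only).
#' @export
setMethod("as.data.frame", "CurationReport",
  function(x, row.names = NULL, optional = FALSE, ...) {
    if (length(x@removed) == 0L)
      return(data.frame(id = character(0), reason = character(0),
                        stringsAsFactors = FALSE))
    data.frame(
      id = unlist(x@removed, use.names = FALSE),
      reason = rep(names(x@removed),
                   vapply(x@removed, length, integer(1))),
      stringsAsFactors = FALSE)
  })

#' Write a curation report as TSV (identifier, reason)
#'
#' @param report a [CurationReport-class].
#' @param path output file path.
#' @export
writeCurationReportTsv <- function(report, path) {
  df <- as.data.frame(report)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
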