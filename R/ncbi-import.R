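## read a taxdump-style table: either the classic "<TAB>|<TAB>"-delimited
## dialect or plain TSV; returns a character data.frame of the fields
.readDumpTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(data.frame())
  pipe <- grepl("\t\\|", lines[1]) || grepl("\\|$", trimws(lines[1]))
  if (pipe) {
    lines <- sub("\t?\\|$", "", lines)
    parts <- strsplit(lines, "\t\\|\t")
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
  }
  nc <- max(lengths(parts))
  df <- as.data.frame(do.call(rbind, lapply(parts, function(p)
    c(trimws(p), rep("", nc - length(p))))), stringsAsFactors = FALSE)
  names(df) <- paste0("V", seq_len(nc))
  df
}

#' Read NCBI taxdump-style tables
#'
#' `nodes` (taxid, parent taxid, rank) and `names` (taxid, name, and, in the
#' four-column taxdump dialect, a name class restricted to
#' `"scientific name"`) are accepted both in the classic
#' `|`-delimited taxdump dialect and as plain TSV; the accession-to-taxid
#' map is a two-column TSV (a header line is skipped if present).
#'
#' @param nodesPath,namesPath,acc2taxidPath file paths.
#' @return list with `nodes` (data.frame: taxid, parent, rank), `names`
#'   (data.frame: taxid, name) and `acc2taxid` (data.frame: accession,
#'   taxid).
#' @export
readTaxdumpFiles <- function(nodesPath, namesPath, acc2taxidPath) {
  nd <- .readDumpTable(nodesPath)
  if (ncol(nd) < 3L) stop("nodes table must have >= 3 columns")
  nodes <- data.frame(taxid = as.integer(nd[[1]]),
                      parent = as.integer(nd[[2]]),
                      rank = tolower(nd[[3]]), stringsAsFactors = FALSE)
  nm <- .readDumpTable(namesPath)
  if (ncol(nm) >= 4L) nm <- nm[tolower(nm[[4]]) == "scientific name", ]
  names_ <- data.frame(taxid = as.integer(nm[[1]]), name = nm[[2]],
                       stringsAsFactors = FALSE)
  am <- utils::read.delim(acc2taxidPath, header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(am) < 2L) stop("acc2taxid table must have >= 2 columns")
  if (nrow(am) && is.na(suppressWarnings(as.integer(am[1, 2])))) {
    am <- am[-1L, , drop = FALSE]  # header row
  }
  acc2taxid <- data.frame(accession = am[[1]], taxid = as.integer(am[[2]]),
                          stringsAsFactors = FALSE)
  list(nodes = nodes, names = names_, acc2taxid = acc2taxid)
}

#' Build a rank-standardized taxonomy table from NCBI taxdump tables
#'
#' For each accession the parent chain is ascended to the root, collecting
#' (rank, name) pairs, which are then projected onto the schema ranks
#' (exact, case-insensitive match, after applying `rankAliases` — by
#' default NCBI's "superkingdom" feeds the schema's "kingdom" rank). With
#' `propagate = TRUE` a rank absent from the chain is propagated down from
#' the nearest annotated higher rank. Ranks below species (strain,
#' subspecies, unranked clades) are dropped.
#'
#' @param tables the [readTaxdumpFiles()] list (`nodes`, `names`,
#'   `acc2taxid`).
#' @param schema target [RankSchema-class]
#'   (default [defaultRankSchema]`("ncbi")`, kingdom through species).
#' @param propagate forward-fill missing ranks (default `TRUE`).
#' @param rankAliases named character vector mapping source rank names to
#'   schema rank names.
#' @param ambiguousVocab see [ambiguousLabelVocabulary()].
#' @return A [TaxonomyTable-class].
#' @export
buildNcbiTaxonomy <- function(tables, schema = defaultRankSchema("ncbi"),
                              propagate = TRUE,
                              rankAliases = c(superkingdom = "kingdom"),
                              ambiguousVocab = ambiguousLabelVocabulary()) {
  stopifnot(is.list(tables), all(c("nodes", "names", "acc2taxid") %in%
                                   names(tables)))
  nodes <- tables$nodes
  key <- as.character(nodes$taxid)
  parentOf <- setNames(nodes$parent, key)
  rankOf <- setNames(tolower(nodes$rank), key)
  nameOf <- setNames(tables$names$name, as.character(tables$names$taxid))
  if (length(rankAliases)) {
    hitAlias <- rankOf %in% tolower(names(rankAliases))
    rankOf[hitAlias] <- tolower(
      rankAliases[match(rankOf[hitAlias], tolower(names(rankAliases)))])
  }
  schemaRanks <- tolower(schema@ranks)
  R <- length(schema)
  acc <- tables$acc2taxid
  absent <- !(as.character(acc$taxid) %in% key)
  if (any(absent))
    stop("accessions mapped to taxids absent from the nodes table: ",
         paste(acc$accession[absent], collapse = ", "))
  if (anyDuplicated(acc$accession))
    stop("duplicate accessions: ",
         paste(unique(acc$accession[duplicated(acc$accession)]),
               collapse = ", "))
  n <- nrow(acc)
  labels <- matrix("", n, R)
  informative <- matrix(FALSE, n, R)
  for (i in seq_len(n)) {
    tid <- as.character(acc$taxid[i])
    chain <- character(0)
    cur <- tid
    repeat {
      if (cur %in% chain)
        stop("cycle in parent chain at taxid ", cur,
             " (accession ", acc$accession[i], ")")
      chain <- c(chain, cur)
      pa <- parentOf[[cur]]
      if (is.na(pa)) stop("taxid ", cur, " has no parent entry")
      pa <- as.character(pa)
      if (identical(pa, cur)) break  # root is its own parent
      if (!(pa %in% key))
        stop("parent taxid ", pa, " absent from nodes table")
      cur <- pa
    }
    chain <- rev(chain)  # root -> leaf
    vals <- rep("", R)
    idx <- match(rankOf[chain], schemaRanks)
    hit <- !is.na(idx)
    vals[idx[hit]] <- unname(nameOf[chain[hit]])
    vals[is.na(vals)] <- ""
    informative[i, ] <- .informativeLabels(vals, ambiguousVocab)
    if (propagate) vals <- .propagateMatrix(matrix(vals, nrow = 1L))[1L, ]
    labels[i, ] <- vals
  }
  taxonomyTable(acc$accession, labels = labels, informative = informative,
                schema = schema)
}
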