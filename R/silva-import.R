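#' Parse a taxonomy tree in Newick form into taxid paths
#'
#' The tree's node labels are taxonomy identifiers (taxids); every labeled
#' node is mapped to its ordered root-to-node chain of labeled taxids
#' (itself included). Singleton internal nodes, ubiquitous in taxonomy
#' trees, are preserved.
#'
#' @param newick Newick text, or a path to a Newick file (optionally `.gz`).
#' @return named list, taxid (character) -> integer vector of taxids from
#'   the root down to the node.
#' @examples
#' parseTaxTree("((3,4)2)1;")
#' @export
parseTaxTree <- function(newick) {
  txt <- if (length(newick) == 1L && !grepl("[();]", newick) &&
             file.exists(newick)) {
    paste(readLines(newick, warn = FALSE), collapse = "")
  } else if (length(newick) == 1L && grepl("[();]", newick)) {
    newick
  } else if (length(newick) == 1L && file.exists(newick)) {
    paste(readLines(newick, warn = FALSE), collapse = "")
  } else {
    stop("`newick` must be Newick text or an existing file path")
  }
  txt <- trimws(txt)
  nOpen <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  nClose <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (nOpen != nClose)
    stop("malformed Newick: unbalanced parentheses")
  if (!grepl(";\\s*$", txt))
    stop("malformed Newick: missing terminal ';'")
  body <- sub(";\\s*$", "", txt)
  if (!grepl("[(]", body)) {
    ## degenerate single-node tree
    lab <- trimws(sub(":.*$", "", body))
    if (!nzchar(lab)) stop("malformed Newick: unlabeled single node")
    out <- list(as.integer(lab))
    names(out) <- lab
    return(out)
  }
  ## wrap in an unlabeled super-root with a dummy sibling tip: taxonomy
  ## trees are chains of singleton nodes (often with a single tip), which
  ## phylo parsers otherwise collapse; the wrapper preserves every labeled
  ## node's ancestor chain and is dropped again below
  dummy <- "taxcurator.dummy.tip"
  tree <- ape::read.tree(text = paste0("(", body, ",", dummy, ");"))
  if (is.null(tree)) stop("malformed Newick: parse failure")
  nTip <- length(tree$tip.label)
  labels <- c(tree$tip.label, tree$node.label)
  labels[is.na(labels)] <- ""
  dup <- labels[nzchar(labels)][duplicated(labels[nzchar(labels)])]
  if (length(dup))
    stop("duplicate taxid labels in tree: ",
         paste(unique(dup), collapse = ", "))
  parent <- rep(NA_integer_, length(labels))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  paths <- vector("list", length(labels))
  names(paths) <- labels
  numbered <- grepl("^[0-9]+$", labels)
  pathOf <- function(node) {
    if (!is.null(paths[[node]])) return(paths[[node]])
    chain <- if (is.na(parent[node])) integer(0) else pathOf(parent[node])
    out <- if (numbered[node]) c(chain, as.integer(labels[node])) else chain
    paths[[node]] <<- out
    out
  }
  for (node in seq_along(labels)) pathOf(node)
  paths[numbered]
}

#' Read the SILVA-style taxonomy file triplet
#'
#' Three plain-text inputs, in the column layouts of SILVA 138 releases
#' (gzip accepted): the taxrank table (taxonomy path, taxid, rank), the
#' taxmap table (primaryAccession, start, stop, path, organism name, taxid)
#' and the Newick taxtree whose node labels are taxids. Columns are
#' addressed by position after a header check.
#'
#' @param taxrankPath,taxmapPath,taxtreePath file paths.
#' @return list with `taxrank` (data.frame: taxid, path, rank, name),
#'   `taxmap` (data.frame: accession pieces, organism name, taxid) and
#'   `taxtree` (the [parseTaxTree()] mapping).
#' @export
readSilvaTaxFiles <- function(taxrankPath, taxmapPath, taxtreePath) {
  tr <- utils::read.delim(taxrankPath, header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(tr) < 3L) stop("taxrank file must have >= 3 columns")
  if (nrow(tr) && is.na(suppressWarnings(as.integer(tr[1, 2])))) {
    tr <- tr[-1L, , drop = FALSE]  # header row
  }
  taxrank <- data.frame(
    taxid = as.integer(tr[[2]]),
    path = tr[[1]],
    rank = tolower(trimws(tr[[3]])),
    stringsAsFactors = FALSE)
  path0 <- sub(";$", "", taxrank$path)
  taxrank$name <- vapply(strsplit(path0, ";", fixed = TRUE), function(p)
    if (length(p)) p[length(p)] else "", character(1))
  tm <- utils::read.delim(taxmapPath, header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(tm) < 6L) stop("taxmap file must have >= 6 columns")
  if (nrow(tm) && tolower(tm[1, 1]) == "primaryaccession") {
    tm <- tm[-1L, , drop = FALSE]
  }
  taxmap <- data.frame(
    primaryAccession = tm[[1]],
    start = tm[[2]],
    stop = tm[[3]],
    path = tm[[4]],
    organismName = tm[[5]],
    taxid = as.integer(tm[[6]]),
    stringsAsFactors = FALSE)
  list(taxrank = taxrank, taxmap = taxmap,
       taxtree = parseTaxTree(taxtreePath))
}

#' Build a rank-standardized taxonomy table from SILVA-style files
#'
#' For each accession the taxid path is walked from the root to the leaf;
#' each node whose rank name matches a schema rank (exact, case-insensitive)
#' contributes its name at that rank. With `propagate = TRUE` the remaining
#' ranks are forward-filled with the last observed taxonomic value along
#' the path — which may come from an intermediate rank not in the schema
#' (e.g. a subphylum), the point of rank propagation. With
#' `includeSpecies = TRUE` a species rank is appended, derived from the
#' taxmap organism name via [deriveSpeciesLabel()].
#'
#' Propagated labels are flagged non-informative; directly annotated labels
#' are informative unless they match `ambiguousVocab`.
#'
#' @param files the [readSilvaTaxFiles()] list (taxrank/taxmap/taxtree).
#' @param schema target [RankSchema-class]
#'   (default [defaultRankSchema]`("silva")`, domain through genus).
#' @param propagate forward-fill unannotated ranks (default `TRUE`).
#' @param includeSpecies append an organism-name-derived species rank.
#' @param ambiguousVocab see [ambiguousLabelVocabulary()].
#' @param composeIds build record identifiers as
#'   `primaryAccession.start.stop` (the SILVA convention); otherwise the
#'   bare primary accession is used.
#' @return A [TaxonomyTable-class].
#' @export
buildSilvaTaxonomy <- function(files, schema = defaultRankSchema("silva"),
                               propagate = TRUE, includeSpecies = FALSE,
                               ambiguousVocab = ambiguousLabelVocabulary(),
                               composeIds = TRUE) {
  stopifnot(is.list(files), all(c("taxrank", "taxmap", "taxtree") %in%
                                  names(files)))
  taxrank <- files$taxrank
  taxmap <- files$taxmap
  taxtree <- files$taxtree
  nodeName <- setNames(taxrank$name, as.character(taxrank$taxid))
  nodeRank <- setNames(taxrank$rank, as.character(taxrank$taxid))
  schemaRanks <- tolower(schema@ranks)
  R <- length(schema)
  ids <- if (composeIds && all(nzchar(taxmap$start)) &&
             all(nzchar(taxmap$stop))) {
    paste(taxmap$primaryAccession, taxmap$start, taxmap$stop, sep = ".")
  } else {
    taxmap$primaryAccession
  }
  unresolved <- !(as.character(taxmap$taxid) %in% names(taxtree))
  if (any(unresolved))
    stop("accessions with taxids absent from the taxonomy tree: ",
         paste(ids[unresolved], collapse = ", "))
  n <- nrow(taxmap)
  labels <- matrix("", n, R)
  informative <- matrix(FALSE, n, R)
  for (i in seq_len(n)) {
    path <- taxtree[[as.character(taxmap$taxid[i])]]
    key <- as.character(path)
    known <- key %in% names(nodeName)
    pNames <- nodeName[key[known]]
    pRanks <- nodeRank[key[known]]
    assignIdx <- match(pRanks, schemaRanks)       # node -> schema rank
    vals <- rep("", R)
    hit <- !is.na(assignIdx)
    vals[assignIdx[hit]] <- pNames[hit]
    inf <- .informativeLabels(vals, ambiguousVocab)
    if (propagate) {
      nodePos <- seq_along(pNames)
      for (r in which(vals == "")) {
        deeper <- which(!is.na(assignIdx) & assignIdx > r)
        hi <- if (length(deeper)) min(nodePos[deeper]) else
          length(pNames) + 1L
        if (hi > 1L) vals[r] <- pNames[hi - 1L]
      }
    }
    labels[i, ] <- vals
    informative[i, ] <- inf
  }
  if (includeSpecies) {
    sp <- vapply(taxmap$organismName, deriveSpeciesLabel, character(1),
                 USE.NAMES = FALSE)
    labels <- cbind(labels, sp)
    informative <- cbind(informative, .informativeLabels(sp, ambiguousVocab))
    schema <- rankSchema(c(schema@handles, "s__"),
                         c(schema@ranks, "species"))
  }
  taxonomyTable(ids, labels = labels, informative = informative,
                schema = schema)
}

#' Derive a species label from an organism name
#'
#' Only the first two whitespace-delimited tokens are kept, stripping the
#' strain/subspecies qualifiers frequently embedded in source organism
#' names (which would otherwise inflate the species label vocabulary).
#' Infraspecific markers such as `"sp."` or `"cf."` in the second token are
#' kept verbatim.
#'
#' @param organismName free-text organism name.
#' @return species label (first two tokens joined by a single space;
#'   one-token names unchanged; empty input gives `""`).
#' @examples
#' deriveSpeciesLabel("Escherichia coli K-12 MG1655")
#' @export
deriveSpeciesLabel <- function(organismName) {
  toks <- strsplit(trimws(organismName), "\\s+")[[1]]
  if (length(toks) == 0L) return("")
  paste(utils::head(toks, 2L), collapse = " ")
}
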