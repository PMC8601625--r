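#' Default ambiguous-label vocabulary
#'
#' Labels containing one of these case-insensitive substrings designate
#' unidentified, uncultured or otherwise uninformative organisms and are
#' flagged non-informative when a lineage is parsed.
#'
#' @return character vector of patterns, matched as fixed, case-insensitive
#'   substrings.
#' @export
ambiguousLabelVocabulary <- function() {
  c("unidentified", "uncultured", "unknown", "unclassified", "metagenome",
    "environmental")
}

## case-insensitive fixed-substring match against a vocabulary
.matchesVocab <- function(labels, vocab) {
  if (length(vocab) == 0L) return(rep(FALSE, length(labels)))
  low <- tolower(labels)
  hit <- rep(FALSE, length(labels))
  for (v in tolower(vocab)) hit <- hit | grepl(v, low, fixed = TRUE)
  hit
}

## informative = non-empty and not matching the ambiguous vocabulary
.informativeLabels <- function(labels, vocab = ambiguousLabelVocabulary()) {
  labels != "" & !.matchesVocab(labels, vocab)
}

.newLineage <- function(labels, informative, schema) {
  new("Lineage", labels = unname(labels), informative = unname(informative),
      schema = schema)
}

#' Parse a semicolon-delimited lineage string
#'
#' Fields are matched to schema ranks by their rank prefix when prefixes are
#' present (`"g__Bacillus"`), positionally otherwise. Missing trailing ranks
#' are filled with empty labels. Empty labels and labels matching
#' `ambiguousVocab` are flagged non-informative.
#'
#' @param text lineage string, e.g. `"d__Bacteria; p__Firmicutes"`; `""`
#'   yields an all-empty lineage.
#' @param schema a [RankSchema-class].
#' @param ambiguousVocab character patterns marking ambiguous labels; see
#'   [ambiguousLabelVocabulary()].
#' @return A [Lineage-class].
#' @examples
#' sch <- defaultRankSchema("silva")
#' parseLineage("d__Bacteria; p__Firmicutes", sch)
#' @export
parseLineage <- function(text, schema,
                         ambiguousVocab = ambiguousLabelVocabulary()) {
  stopifnot(is(schema, "RankSchema"))
  n <- length(schema)
  fields <- if (is.na(text) || !nzchar(trimws(text))) character(0) else
    trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  labels <- rep("", n)
  hasPrefix <- grepl("^[A-Za-z0-9]+__", fields)
  if (length(fields) && any(hasPrefix) && any(schema@handles != "")) {
    ## prefix dialect: match fields to ranks by handle
    for (f in fields) {
      if (!nzchar(f)) next
      m <- regmatches(f, regexpr("^[A-Za-z0-9]+__", f))
      if (length(m) == 0L) {
        stop("field without rank prefix in prefixed lineage: '", f, "'")
      }
      i <- match(m, schema@handles)
      if (is.na(i)) {
        stop("rank prefix '", m, "' not present in schema")
      }
      labels[i] <- substring(f, nchar(m) + 1L)
    }
  } else {
    if (length(fields) > n) {
      stop("lineage has ", length(fields), " fields but schema has only ",
           n, " ranks")
    }
    ## positional dialect; strip handles if present anyway
    if (length(fields)) {
      vals <- sub("^[A-Za-z0-9]+__", "", fields)
      labels[seq_along(vals)] <- vals
    }
  }
  .newLineage(labels, .informativeLabels(labels, ambiguousVocab), schema)
}

#' Serialize a lineage to its string form
#'
#' @param lin a [Lineage-class].
#' @return character scalar, fields joined by `"; "` with rank handles
#'   prepended.
#' @export
formatLineage <- function(lin) {
  stopifnot(is(lin, "Lineage"))
  paste0(lin@schema@handles, lin@labels, collapse = "; ")
}

setMethod("show", "Lineage", function(object) {
  cat("Lineage:", formatLineage(object), "\n")
  cat("informative at:",
      paste(object@schema@ranks[object@informative], collapse = ", "), "\n")
})

## forward fill a label matrix: empty labels receive the nearest non-empty
## ancestor label. Labels that are present but non-informative (e.g.
## "uncultured") are observed values and propagate downward themselves.
.propagateMatrix <- function(labels) {
  if (ncol(labels) < 2L || nrow(labels) == 0L) return(labels)
  for (r in 2:ncol(labels)) {
    empty <- labels[, r] == ""
    labels[empty, r] <- labels[empty, r - 1L]
  }
  labels
}

#' Forward-fill empty ranks with the last observed ancestor label
#'
#' Rank propagation: every empty rank below an annotated ancestor receives
#' that ancestor's label (the "last observed taxonomic value"). The
#' informative mask is unchanged, so propagated labels remain flagged as
#' placeholders. Idempotent.
#'
#' @param x a [Lineage-class] or [TaxonomyTable-class].
#' @param decorate logical; if `TRUE`, propagated labels are suffixed with
#'   the source rank handle in brackets (off by default, plain forward fill).
#' @return object of the same class as `x`.
#' @export
setGeneric("propagateRanks", function(x, decorate = FALSE)
  standardGeneric("propagateRanks"))

#' @rdname propagateRanks
#' @export
setMethod("propagateRanks", "Lineage", function(x, decorate = FALSE) {
  m <- matrix(x@labels, nrow = 1L)
  filled <- .propagateMatrix(m)[1L, ]
  if (decorate) {
    prop <- filled != "" & x@labels == ""
    src <- .propagationSource(x@labels)
    filled[prop] <- paste0(filled[prop], " [",
                           sub("__$", "", x@schema@handles[src[prop]]), "]")
  }
  .newLineage(filled, x@informative, x@schema)
})

#' @rdname propagateRanks
#' @export
setMethod("propagateRanks", "TaxonomyTable", function(x, decorate = FALSE) {
  if (decorate) {
    lins <- lapply(seq_len(nrow(x@labels)), function(i)
      propagateRanks(.newLineage(x@labels[i, ], x@informative[i, ], x@schema),
                     decorate = TRUE))
    return(taxonomyTable(rownames(x@labels), lins, schema = x@schema))
  }
  initialize(x, labels = .propagateMatrix(x@labels))
})

## per-rank index of the rank a propagated value would come from
.propagationSource <- function(labels) {
  src <- integer(length(labels))
  last <- NA_integer_
  for (r in seq_along(labels)) {
    if (labels[r] != "") last <- r
    src[r] <- if (is.na(last)) r else last
  }
  src
}

#' Empty the ranks of a lineage beyond a given depth
#'
#' @param lin a [Lineage-class].
#' @param depth integer in `[0, length(schema)]`; `0` yields an all-empty
#'   lineage.
#' @return A [Lineage-class].
#' @export
truncateAtDepth <- function(lin, depth) {
  stopifnot(is(lin, "Lineage"))
  n <- length(lin@schema)
  if (depth < 0 || depth > n) stop("depth must lie in [0, ", n, "]")
  labels <- lin@labels
  info <- lin@informative
  if (depth < n) {
    drop <- (depth + 1L):n
    labels[drop] <- ""
    info[drop] <- FALSE
  }
  .newLineage(labels, info, lin@schema)
}

## coerce a list of Lineage / a TaxonomyTable into a label matrix + mask
.lineageMatrix <- function(x) {
  if (is(x, "TaxonomyTable")) {
    return(list(labels = x@labels, informative = x@informative,
                schema = x@schema))
  }
  if (is(x, "Lineage")) x <- list(x)
  stopifnot(length(x) >= 1L, all(vapply(x, is, logical(1), "Lineage")))
  schema <- x[[1]]@schema
  same <- vapply(x, function(l)
    identical(l@schema@handles, schema@handles) &&
      identical(l@schema@ranks, schema@ranks), logical(1))
  if (!all(same)) stop("lineages must share one schema")
  list(labels = do.call(rbind, lapply(x, slot, "labels")),
       informative = do.call(rbind, lapply(x, slot, "informative")),
       schema = schema)
}

#' Consensus lineage of a multiset of lineages
#'
#' Three consensus modes reconcile the taxonomies of records collapsed into
#' one cluster:
#' \describe{
#'   \item{`lca`}{last common ancestor: the longest rank-wise shared prefix
#'     of all lineages; deeper ranks are emptied.}
#'   \item{`majority`}{the single most frequent full lineage; ties resolve
#'     to the LCA of the tied lineages.}
#'   \item{`super`}{built rank by rank top-down, at each rank taking the most
#'     frequent label among lineages consistent with the prefix chosen so
#'     far, stopping at the first tie.}
#' }
#'
#' @param x list of [Lineage-class] objects or a [TaxonomyTable-class]
#'   (rows are the multiset).
#' @param mode `"lca"`, `"majority"` or `"super"`.
#' @return A [Lineage-class].
#' @export
consensusLineage <- function(x, mode = c("lca", "majority", "super")) {
  mode <- match.arg(mode)
  lm <- .lineageMatrix(x)
  if (nrow(lm$labels) == 0L) stop("consensus of an empty multiset")
  lab <- lm$labels
  info <- lm$informative
  n <- ncol(lab)
  result <- rep("", n)
  resInfo <- rep(FALSE, n)
  fill <- function(r, value, rows) {
    result[r] <<- value
    resInfo[r] <<- value != "" && any(info[rows, r][lab[rows, r] == value])
  }
  if (mode == "lca") {
    for (r in seq_len(n)) {
      u <- unique(lab[, r])
      if (length(u) != 1L) break
      fill(r, u, seq_len(nrow(lab)))
    }
  } else if (mode == "majority") {
    key <- apply(lab, 1L, paste, collapse = "\x1f")
    tab <- table(key)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) {
      i <- match(winners, key)
      result <- lab[i, ]
      resInfo <- info[i, ]
    } else {
      tied <- match(winners, key)
      return(consensusLineage(
        taxonomyTable(as.character(seq_along(tied)),
                      labels = lab[tied, , drop = FALSE],
                      informative = info[tied, , drop = FALSE],
                      schema = lm$schema),
        mode = "lca"))
    }
  } else { # super
    active <- rep(TRUE, nrow(lab))
    for (r in seq_len(n)) {
      tab <- table(lab[active, r])
      winners <- names(tab)[tab == max(tab)]
      if (length(winners) != 1L) break
      fill(r, winners, which(active))
      active <- active & lab[, r] == winners
    }
  }
  .newLineage(result, resInfo, lm$schema)
}

#' Collapse labels related by string prefix
#'
#' Labels standing in a proper-prefix relation (subclade suffixes such as
#' `"Lactobacillus_A"` vs `"Lactobacillus"`) are grouped and each group is
#' represented by its shortest member, so that cross-database label
#' comparisons do not undercount shared taxa.
#'
#' @param labels character vector (treated as a set).
#' @return character vector of unique representatives; never contains two
#'   labels in a prefix relation.
#' @examples
#' collapsePrefixLabels(c("Lactobacillus", "Lactobacillus_A"))
#' @export
collapsePrefixLabels <- function(labels) {
  unique(unname(prefixCollapseMap(labels)))
}

#' @describeIn collapsePrefixLabels the full mapping label -> representative
#'   (named character vector), useful when canonicalizing several label sets
#'   against a common union.
#' @export
prefixCollapseMap <- function(labels) {
  labels <- unique(as.character(labels))
  n <- length(labels)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1L) {
    ord <- order(nchar(labels))
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        i <- ord[a]; j <- ord[b]
        if (nchar(labels[i]) < nchar(labels[j]) &&
            startsWith(labels[j], labels[i])) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  rep_of <- vapply(split(seq_len(n), root), function(ix)
    labels[ix][which.min(nchar(labels[ix]))], character(1))
  setNames(rep_of[as.character(root)], labels)
}
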