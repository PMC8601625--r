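#' Dereplicate identical sequences with consensus taxonomy
#'
#' Identical sequence strings are collapsed to a single record. In `"uniq"`
#' mode one record is kept per distinct (sequence, lineage) pair, preserving
#' identical sequences that carry different taxonomic labels. The other
#' modes keep one record per distinct sequence and reconcile the members'
#' lineages with [consensusLineage()]. The retained identifier is always the
#' first-seen member's.
#'
#' @param seqs a [Biostrings::DNAStringSet].
#' @param tax a [TaxonomyTable-class] covering every sequence.
#' @param mode `"uniq"`, `"lca"`, `"majority"` or `"super"`.
#' @return list with `seqs` (dereplicated [Biostrings::DNAStringSet]) and
#'   `tax` (matching [TaxonomyTable-class]).
#' @export
dereplicateSeqs <- function(seqs, tax, mode = c("uniq", "lca", "majority",
                                                "super")) {
  mode <- match.arg(mode)
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  ids <- names(seqs)
  missing <- setdiff(ids, taxIds(tax))
  if (length(missing))
    stop("sequences without taxonomy entry: ",
         paste(missing, collapse = ", "))
  x <- as.character(seqs)
  tax <- tax[ids]
  keys <- if (mode == "uniq") {
    paste(x, lineageStrings(tax), sep = "\x1f")
  } else {
    x
  }
  firstIdx <- which(!duplicated(keys))
  groups <- split(seq_along(keys), factor(keys, levels = keys[firstIdx]))
  repIds <- ids[firstIdx]
  if (mode == "uniq") {
    outTax <- tax[repIds]
  } else {
    lins <- lapply(groups, function(ix) consensusLineage(tax[ix], mode = mode))
    outTax <- taxonomyTable(repIds, unname(lins), schema = tax@schema)
  }
  list(seqs = seqs[firstIdx], tax = outTax)
}

.defaultAlignParams <- function() {
  list(match = 1, mismatch = -1, gapOpening = 5, gapExtension = 2)
}

## identity of one query against several subjects: global alignment,
## matches / alignment columns excluding terminal gap columns
.identityToSubjects <- function(query, subjects,
                                params = .defaultAlignParams()) {
  if (length(subjects) == 0L) return(numeric(0))
  mat <- nucleotideSubstitutionMatrix(match = params$match,
                                      mismatch = params$mismatch,
                                      baseOnly = FALSE)
  aln <- pairwiseAlignment(pattern = DNAStringSet(subjects),
                           subject = query, type = "global",
                           substitutionMatrix = mat,
                           gapOpening = params$gapOpening,
                           gapExtension = params$gapExtension)
  ## PID1: matching columns over aligned + internal-gap columns, i.e. all
  ## alignment columns excluding terminal gaps
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Pairwise percent identity of two sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap opening -5,
#' gap extension -2 by default); identity is the fraction of matching
#' columns over all alignment columns, excluding terminal gap columns
#' (overhangs), mirroring the identity notion of common greedy clustering
#' tools.
#'
#' @param a,b nucleotide sequences (character or
#'   [Biostrings::DNAString]-like), both non-empty.
#' @param match,mismatch,gapOpening,gapExtension alignment scoring
#'   parameters.
#' @return identity fraction in `[0, 1]`; symmetric in its arguments.
#' @examples
#' pairwiseIdentity("ACGTACGT", "ACGTACGA")  # 0.875
#' @export
pairwiseIdentity <- function(a, b, match = 1, mismatch = -1, gapOpening = 5,
                             gapExtension = 2) {
  a <- as.character(a)
  b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  .identityToSubjects(DNAStringSet(b)[[1]], DNAStringSet(a),
                      params = list(match = match, mismatch = mismatch,
                                    gapOpening = gapOpening,
                                    gapExtension = gapExtension))
}

#' Greedy percent-identity clustering into OTUs
#'
#' Records are processed in order of decreasing length (ties broken by
#' identifier); each record joins the first existing centroid (in centroid
#' creation order) whose [pairwiseIdentity()] to it meets `percIdentity`,
#' otherwise it founds a new centroid. When several centroids qualify, the
#' earliest-created one wins. Each cluster receives a consensus lineage via
#' [consensusLineage()]. At `percIdentity = 1` the procedure reduces to
#' dereplication of identical equal-length sequences.
#'
#' @param seqs a [Biostrings::DNAStringSet].
#' @param tax a [TaxonomyTable-class] covering every sequence.
#' @param percIdentity identity threshold in (0, 1].
#' @param mode consensus mode (`"lca"`, `"majority"` or `"super"`).
#' @return A [ClusterResult-class].
#' @export
clusterGreedy <- function(seqs, tax, percIdentity, mode = c("lca", "majority",
                                                            "super")) {
  mode <- match.arg(mode)
  stopifnot(percIdentity > 0, percIdentity <= 1)
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  ids <- names(seqs)
  missing <- setdiff(ids, taxIds(tax))
  if (length(missing))
    stop("sequences without taxonomy entry: ",
         paste(missing, collapse = ", "))
  ord <- order(-width(seqs), ids)
  seqs <- seqs[ord]
  ids <- ids[ord]
  centroidSeqs <- DNAStringSet()
  centroidIds <- character(0)
  members <- list()
  identities <- list()
  for (i in seq_along(seqs)) {
    idn <- .identityToSubjects(seqs[[i]], centroidSeqs)
    hit <- which(idn >= percIdentity)
    if (length(hit)) {
      j <- hit[1]
      members[[j]] <- c(members[[j]], ids[i])
      identities[[j]] <- c(identities[[j]], idn[j])
    } else {
      centroidSeqs <- c(centroidSeqs, seqs[i])
      centroidIds <- c(centroidIds, ids[i])
      members[[length(members) + 1L]] <- ids[i]
      identities[[length(identities) + 1L]] <- 1
    }
  }
  consensus <- taxonomyTable(
    centroidIds,
    lapply(members, function(mem) consensusLineage(tax[mem], mode = mode)),
    schema = tax@schema)
  new("ClusterResult", centroids = centroidIds, members = members,
      identities = identities, percIdentity = percIdentity,
      consensus = consensus)
}

#' @describeIn ClusterResult-class number of clusters.
#' @param x a [ClusterResult-class].
#' @export
clusterCount <- function(x) length(x@centroids)

#' @describeIn ClusterResult-class centroid identifiers.
#' @export
clusterCentroids <- function(x) x@centroids

#' @describeIn ClusterResult-class member identifiers per cluster (named
#'   list keyed by centroid).
#' @export
clusterMembers <- function(x) setNames(x@members, x@centroids)

#' @describeIn ClusterResult-class consensus [TaxonomyTable-class] keyed by
#'   centroid.
#' @export
clusterConsensus <- function(x) x@consensus

setMethod("show", "ClusterResult", function(object) {
  sizes <- vapply(object@members, length, integer(1))
  cat("ClusterResult:", length(object@centroids), "clusters over",
      sum(sizes), "records at identity >=", object@percIdentity, "\n")
  cat("  cluster sizes:", paste(utils::head(sort(sizes, decreasing = TRUE),
                                            10L), collapse = ", "),
      if (length(sizes) > 10L) "...\n" else "\n")
})

#' Reduce a clustering to representative sequences + consensus taxonomy
#'
#' @param clusters a [ClusterResult-class].
#' @param seqs the original [Biostrings::DNAStringSet].
#' @return list with `seqs` (centroid sequences) and `tax` (consensus
#'   [TaxonomyTable-class]).
#' @export
clusterRepresentatives <- function(clusters, seqs) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  list(seqs = seqs[clusters@centroids], tax = clusters@consensus)
}
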