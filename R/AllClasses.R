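#' @import methods
#' @importFrom stats setNames
NULL

#' Rank schema for hierarchical taxonomy
#'
#' A `RankSchema` fixes the ordered set of taxonomic ranks a database uses,
#' together with the textual handle ("rank prefix") that marks each rank in a
#' serialized lineage string (e.g. `"g__"` for genus). All lineages and
#' taxonomy tables in the package are interpreted relative to a schema.
#'
#' @slot handles character vector of rank prefixes, e.g. `c("d__", "p__", ...)`.
#'   Handles must be unique; an all-empty vector selects the prefix-free
#'   positional dialect.
#' @slot ranks character vector of rank names (`"domain"`, `"phylum"`, ...),
#'   parallel to `handles`.
#'
#' @seealso [rankSchema()], [defaultRankSchema()]
#' @export
setClass("RankSchema",
  representation(handles = "character", ranks = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@handles) < 1L)
      msg <- c(msg, "schema must contain at least one rank")
    if (length(object@handles) != length(object@ranks))
      msg <- c(msg, "handles and ranks must have equal length")
    if (anyDuplicated(object@handles))
      msg <- c(msg, "rank handles must be unique")
    if (anyDuplicated(object@ranks))
      msg <- c(msg, "rank names must be unique")
    ok <- grepl("__$", object@handles) | object@handles == ""
    if (!all(ok))
      msg <- c(msg, "each handle must end in '__' or be empty")
    if (is.null(msg)) TRUE else msg
  })

#' Ranked taxonomic lineage
#'
#' A `Lineage` holds one label per schema rank plus a per-rank informative
#' mask. The mask distinguishes real annotations from placeholders: empty
#' labels, labels matching the ambiguous-label vocabulary (e.g. "uncultured")
#' and labels filled in by rank propagation are all flagged non-informative.
#'
#' @slot labels character vector, one label per schema rank (may be `""`).
#' @slot informative logical vector parallel to `labels`.
#' @slot schema the [RankSchema-class] the lineage is expressed in.
#'
#' @seealso [parseLineage()], [propagateRanks()], [formatLineage()]
#' @export
setClass("Lineage",
  representation(labels = "character", informative = "logical",
                 schema = "RankSchema"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@schema@handles)
    if (length(object@labels) != n)
      msg <- c(msg, "labels length must equal schema length")
    if (length(object@informative) != n)
      msg <- c(msg, "informative mask length must equal schema length")
    if (any(is.na(object@labels)))
      msg <- c(msg, "labels must not be NA")
    if (any(object@informative & object@labels == ""))
      msg <- c(msg, "empty labels cannot be informative")
    if (is.null(msg)) TRUE else msg
  })

#' Table of taxonomic lineages
#'
#' Maps record identifiers (sequence accessions / feature ids) to lineages
#' under a shared [RankSchema-class]. Backed by a character matrix of labels
#' and a parallel logical informative mask; rows are records, columns ranks.
#'
#' @slot schema shared [RankSchema-class].
#' @slot labels character matrix (records x ranks) with identifier rownames.
#' @slot informative logical matrix parallel to `labels`.
#'
#' @seealso [taxonomyTable()], [readTaxonomyTsv()], [lineageStrings()]
#' @export
setClass("TaxonomyTable",
  representation(schema = "RankSchema", labels = "matrix",
                 informative = "matrix"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@schema@handles)
    if (!is.character(object@labels))
      msg <- c(msg, "labels must be a character matrix")
    if (ncol(object@labels) != n)
      msg <- c(msg, "label matrix must have one column per schema rank")
    if (!identical(dim(object@labels), dim(object@informative)))
      msg <- c(msg, "labels and informative mask must have identical shape")
    ids <- rownames(object@labels)
    if (nrow(object@labels) > 0L && is.null(ids))
      msg <- c(msg, "label matrix must carry identifier rownames")
    if (!is.null(ids) && anyDuplicated(ids))
      msg <- c(msg, "identifiers must be unique")
    if (is.null(msg)) TRUE else msg
  })

#' Record of a sequence/taxonomy filtering step
#'
#' Every filter returns, alongside the surviving records, a `CurationReport`
#' stating which identifiers were removed and for which (single) reason.
#' The first failing rule wins, so each identifier appears under at most one
#' reason and `kept + removed = input`.
#'
#' @slot keptIds identifiers surviving the filter, in input order.
#' @slot removed named list, reason -> character vector of identifiers.
#' @export
setClass("CurationReport",
  representation(keptIds = "character", removed = "list"),
  validity = function(object) {
    rem <- unlist(object@removed, use.names = FALSE)
    if (length(rem) && anyDuplicated(c(object@keptIds, rem)))
      return("an identifier may appear only once across kept and removed")
    TRUE
  })

#' Result of dereplication/greedy clustering
#'
#' Clusters partition the input records; each cluster is anchored at a
#' centroid (which is a member of its own cluster) and carries a consensus
#' lineage computed from its members' taxonomies.
#'
#' @slot centroids centroid identifiers, in creation order.
#' @slot members list parallel to `centroids`; member identifiers per cluster
#'   (the centroid included).
#' @slot identities list parallel to `members`; member-to-centroid identity
#'   fractions.
#' @slot percIdentity the identity threshold used, in (0, 1].
#' @slot consensus [TaxonomyTable-class] keyed by centroid identifier.
#' @export
setClass("ClusterResult",
  representation(centroids = "character", members = "list",
                 identities = "list", percIdentity = "numeric",
                 consensus = "TaxonomyTable"),
  validity = function(object) {
    msg <- NULL
    if (length(object@members) != length(object@centroids))
      msg <- c(msg, "one member vector per centroid required")
    if (length(object@percIdentity) != 1L ||
        object@percIdentity <= 0 || object@percIdentity > 1)
      msg <- c(msg, "percIdentity must be a single value in (0, 1]")
    own <- mapply(function(ctr, mem) ctr %in% mem,
                  object@centroids, object@members)
    if (length(own) && !all(own))
      msg <- c(msg, "each centroid must be a member of its own cluster")
    if (anyDuplicated(unlist(object@members, use.names = FALSE)))
      msg <- c(msg, "clusters must partition the input (no duplicates)")
    if (is.null(msg)) TRUE else msg
  })

#' Kmer naive Bayes classifier model
#'
#' Multinomial naive Bayes over forward-strand kmer counts. One class per
#' distinct full training lineage; per-class kmer probabilities are
#' additively smoothed; priors are uniform over classes.
#'
#' @slot k kmer length.
#' @slot alpha additive smoothing weight.
#' @slot schema [RankSchema-class] of the training taxonomy.
#' @slot classLabels character matrix (classes x ranks) of class lineages.
#' @slot classInformative logical matrix parallel to `classLabels`.
#' @slot logLik numeric matrix (classes x 4^k) of log kmer probabilities,
#'   columns named by kmer.
#' @slot logPrior numeric vector of per-class log priors.
#' @seealso [fitClassifier()], [classifySeqs()]
#' @export
setClass("ClassifierModel",
  representation(k = "integer", alpha = "numeric", schema = "RankSchema",
                 classLabels = "matrix", classInformative = "matrix",
                 logLik = "matrix", logPrior = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@k < 1L) msg <- c(msg, "k must be >= 1")
    if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
    if (nrow(object@logLik) != nrow(object@classLabels))
      msg <- c(msg, "one likelihood row per class required")
    if (length(object@logPrior) != nrow(object@classLabels))
      msg <- c(msg, "one prior per class required")
    sums <- rowSums(exp(object@logLik))
    if (length(sums) && any(abs(sums - 1) > 1e-6))
      msg <- c(msg, "per-class kmer probabilities must sum to 1")
    if (is.null(msg)) TRUE else msg
  })
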