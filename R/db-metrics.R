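#' Shannon entropy of a count vector
#'
#' \eqn{H = -\sum_i p_i \ln p_i} with \eqn{p_i = c_i / \sum c}; zero counts
#' are ignored. Entropy captures both richness (number of categories) and
#' evenness of the distribution; a uniform distribution over `n` categories
#' attains the maximum, \eqn{\ln n}.
#'
#' @param counts non-negative counts (a frequency multiset), total > 0.
#' @param base logarithm base; the default `exp(1)` reports nats, use `2`
#'   for bits.
#' @return entropy (>= 0).
#' @examples
#' shannonEntropy(c(1, 1))        # ln 2
#' shannonEntropy(c(3, 1))        # 0.5623...
#' @export
shannonEntropy <- function(counts, base = exp(1)) {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("counts must sum to a positive total")
  p <- counts[counts > 0] / total
  -sum(p * log(p)) / log(base)
}

#' Per-rank information metrics of a taxonomy table
#'
#' For every rank the report gives: the number of unique labels (distinct
#' full lineage prefixes to that depth, among records informative there),
#' the Shannon entropy (nats) of those prefix frequencies, the number of
#' records unclassified at the rank, and the number of records whose
#' annotation terminates exactly at the rank. Records carrying no
#' informative rank at all are reported in the `"unannotated"` attribute, so
#' that `sum(terminal) + unannotated == length(tax)`.
#'
#' Propagated labels are flagged non-informative by the parsers, so they
#' count as unclassified here (the mask, not the label text, decides).
#'
#' @param tax a non-empty [TaxonomyTable-class].
#' @param base entropy logarithm base (default: nats).
#' @return data.frame with columns `rank`, `unique_labels`, `entropy`,
#'   `unclassified`, `terminal`.
#' @export
evaluateTaxonomy <- function(tax, base = exp(1)) {
  stopifnot(is(tax, "TaxonomyTable"))
  if (length(tax) == 0L) stop("empty taxonomy table")
  n <- length(tax@schema)
  depth <- terminalDepths(tax)
  out <- data.frame(rank = tax@schema@ranks,
                    unique_labels = integer(n), entropy = numeric(n),
                    unclassified = integer(n), terminal = integer(n),
                    stringsAsFactors = FALSE)
  for (r in seq_len(n)) {
    inf <- tax@informative[, r]
    prefixes <- apply(tax@labels[inf, seq_len(r), drop = FALSE], 1L,
                      paste, collapse = "\x1f")
    tab <- table(prefixes)
    out$unique_labels[r] <- length(tab)
    out$entropy[r] <- if (length(tab)) shannonEntropy(tab, base) else 0
    out$unclassified[r] <- sum(!inf)
    out$terminal[r] <- sum(depth == r)
  }
  attr(out, "unannotated") <- sum(depth == 0L)
  out
}

## pooled forward-strand kmer counts over a sequence set; kmers containing
## ambiguous characters are skipped
.pooledKmerCounts <- function(seqs, k) {
  stopifnot(k >= 1L)
  if (k <= 8L) {
    counts <- colSums(oligonucleotideFrequency(seqs, width = k))
    return(counts[counts > 0])
  }
  x <- as.character(seqs)
  kmers <- unlist(lapply(x, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    km <- substring(s, 1:(L - k + 1L), k:L)
    km[!grepl("[^ACGT]", km)]
  }), use.names = FALSE)
  if (length(kmers) == 0L) return(setNames(numeric(0), character(0)))
  tab <- table(kmers)
  setNames(as.numeric(tab), names(tab))
}

#' Sequence-level information metrics of a database
#'
#' Reports the number of distinct sequences, the length distribution, the
#' Shannon entropy (nats) of sequence occurrence frequencies, and the
#' entropy of the pooled forward-strand kmer distribution at each requested
#' kmer length (records shorter than `k` contribute no kmers; kmers
#' containing ambiguous characters are skipped).
#'
#' @param seqs a non-empty [Biostrings::DNAStringSet].
#' @param kmerLengths integer kmer lengths (default `c(2, 4, 8, 16)`).
#' @param deduplicate compute sequence entropy on the deduplicated set
#'   (richness-only) instead of occurrence frequencies (default `FALSE`).
#' @param base entropy logarithm base (default: nats).
#' @return list with `uniqueSequences`, `totalSequences`, `lengthSummary`
#'   (min/q1/median/mean/q3/max), `sequenceEntropy` and `kmerEntropy` (a
#'   data.frame with columns `k`, `entropy`).
#' @export
evaluateSeqs <- function(seqs, kmerLengths = c(2L, 4L, 8L, 16L),
                         deduplicate = FALSE, base = exp(1)) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  if (length(seqs) == 0L) stop("empty sequence set")
  stopifnot(all(kmerLengths >= 1L))
  x <- as.character(seqs)
  seqTab <- table(x)
  if (deduplicate) seqTab[] <- 1
  w <- width(seqs)
  q <- stats::quantile(w, c(0.25, 0.5, 0.75), names = FALSE)
  kent <- vapply(kmerLengths, function(k) {
    counts <- .pooledKmerCounts(seqs, as.integer(k))
    if (length(counts) == 0L) return(NA_real_)
    shannonEntropy(counts, base)
  }, numeric(1))
  list(uniqueSequences = length(seqTab),
       totalSequences = length(seqs),
       lengthSummary = c(min = min(w), q1 = q[1], median = q[2],
                         mean = mean(w), q3 = q[3], max = max(w)),
       sequenceEntropy = shannonEntropy(seqTab, base),
       kmerEntropy = data.frame(k = as.integer(kmerLengths),
                                entropy = kent))
}

#' Genus / species label consistency
#'
#' Among records informative at both the genus and species ranks, a record
#' is inconsistent when the first whitespace token of its species label
#' differs from its genus label (a frequent artifact of species labels
#' lifted verbatim from source organism names).
#'
#' @param tax a [TaxonomyTable-class] whose schema contains `genus` and
#'   `species` ranks.
#' @return list with `fraction` (inconsistent / evaluable; 0 when no record
#'   is evaluable), `offenders` (identifiers), `n` (evaluable records) and
#'   `emptyDenominator` flag.
#' @export
genusSpeciesConsistency <- function(tax) {
  stopifnot(is(tax, "TaxonomyTable"))
  g <- rankIndex(tax@schema, "genus")
  s <- rankIndex(tax@schema, "species")
  both <- tax@informative[, g] & tax@informative[, s]
  if (!any(both)) {
    return(list(fraction = 0, offenders = character(0), n = 0L,
                emptyDenominator = TRUE))
  }
  genus <- tax@labels[both, g]
  firstTok <- vapply(strsplit(tax@labels[both, s], "\\s+"), `[`, character(1),
                     1L)
  bad <- firstTok != genus
  list(fraction = mean(bad), offenders = taxIds(tax)[both][bad],
       n = sum(both), emptyDenominator = FALSE)
}

#' Cross-database taxonomy label overlap
#'
#' For each reference database and rank, reports the proportion of the
#' reference's rank labels that are shared with every other database, pair
#' and trio of databases, and with all databases jointly. Labels are the
#' bare rank-name tokens of informative entries; before comparison, labels
#' standing in a prefix relation across the union of all databases are
#' collapsed with [collapsePrefixLabels()] so subclade suffixes do not
#' cause undercounting. The reference compared with itself is 1 by
#' construction and is included for clarity.
#'
#' @param tables named list of 2-4 [TaxonomyTable-class] objects; ranks are
#'   compared up to the shallowest common depth.
#' @param collapse apply the prefix collapse (default `TRUE`).
#' @return data.frame with columns `reference`, `rank`, `comparison`
#'   (other database names joined by `"+"`, or the reference name itself for
#'   the self row), `order` (number of databases intersected with the
#'   reference) and `proportion`.
#' @export
taxonomyOverlap <- function(tables, collapse = TRUE) {
  stopifnot(is.list(tables), length(tables) >= 2L, length(tables) <= 4L,
            !is.null(names(tables)))
  depth <- min(vapply(tables, function(t) length(t@schema), integer(1)))
  ranks <- tables[[1]]@schema@ranks[seq_len(depth)]
  nms <- names(tables)
  rows <- list()
  for (r in seq_len(depth)) {
    sets <- lapply(tables, function(t)
      unique(t@labels[t@informative[, r], r]))
    if (collapse) {
      cmap <- prefixCollapseMap(unlist(sets, use.names = FALSE))
      sets <- lapply(sets, function(s) unique(unname(cmap[s])))
    }
    for (ref in nms) {
      refSet <- sets[[ref]]
      denom <- length(refSet)
      rows[[length(rows) + 1L]] <- data.frame(
        reference = ref, rank = ranks[r], comparison = ref, order = 0L,
        proportion = 1, stringsAsFactors = FALSE)
      others <- setdiff(nms, ref)
      for (m in seq_along(others)) {
        combos <- utils::combn(others, m, simplify = FALSE)
        for (cmb in combos) {
          shared <- Reduce(intersect, sets[cmb], refSet)
          rows[[length(rows) + 1L]] <- data.frame(
            reference = ref, rank = ranks[r],
            comparison = paste(cmb, collapse = "+"), order = m,
            proportion = if (denom == 0L) 0 else length(shared) / denom,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
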