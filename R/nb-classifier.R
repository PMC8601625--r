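#' Forward-strand kmer count profile of one sequence
#'
#' All overlapping kmers are counted; kmers containing ambiguous characters
#' are skipped; a sequence shorter than `k` yields an empty profile.
#'
#' @param seq a nucleotide sequence (character or
#'   [Biostrings::DNAString]-like).
#' @param k kmer length (>= 1).
#' @return named integer vector of counts (zero-count kmers omitted).
#' @examples
#' kmerProfile("ACGN", 2)  # AC = 1, CG = 1; GN skipped
#' @export
kmerProfile <- function(seq, k) {
  stopifnot(k >= 1L)
  counts <- .pooledKmerCounts(DNAStringSet(as.character(seq)), as.integer(k))
  v <- as.integer(counts)
  names(v) <- names(counts)
  v
}

#' Fit a kmer naive Bayes taxonomy classifier
#'
#' One class per distinct full training lineage. Per-class kmer
#' probabilities are the additively smoothed pooled member counts,
#' \eqn{(c + \alpha) / (\sum c + \alpha 4^k)}; priors are uniform over
#' classes. Defaults (`k = 7`, `alpha = 0.001`, uniform priors) follow the
#' conventions of widely used amplicon naive Bayes classifiers.
#'
#' @param seqs reference [Biostrings::DNAStringSet]; every sequence must
#'   have a taxonomy entry.
#' @param tax a [TaxonomyTable-class].
#' @param k kmer length (1-8).
#' @param alpha additive smoothing weight (> 0).
#' @return A [ClassifierModel-class].
#' @export
fitClassifier <- function(seqs, tax, k = 7L, alpha = 0.001) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  if (length(seqs) == 0L) stop("empty reference set")
  k <- as.integer(k)
  if (k < 1L || k > 8L) stop("k must lie in 1..8")
  ids <- names(seqs)
  missing <- setdiff(ids, taxIds(tax))
  if (length(missing))
    stop("reference sequences without taxonomy: ",
         paste(missing, collapse = ", "))
  tax <- tax[ids]
  keys <- .lineageKeys(tax)
  classes <- unique(keys)
  counts <- oligonucleotideFrequency(seqs, width = k)
  classCounts <- rowsum(counts, group = factor(keys, levels = classes))
  tot <- rowSums(classCounts)
  prob <- (classCounts + alpha) / (tot + alpha * 4^k)
  firstIdx <- match(classes, keys)
  new("ClassifierModel", k = k, alpha = alpha, schema = tax@schema,
      classLabels = tax@labels[firstIdx, , drop = FALSE],
      classInformative = tax@informative[firstIdx, , drop = FALSE],
      logLik = log(prob),
      logPrior = rep(-log(length(classes)), length(classes)))
}

## queries x classes posterior matrix (rows sum to 1), log-sum-exp normalized
.classPosteriors <- function(model, seqs) {
  Q <- oligonucleotideFrequency(seqs, width = model@k)
  if (ncol(Q) != ncol(model@logLik))
    stop("kmer length mismatch between model and query profiles")
  scores <- Q %*% t(model@logLik) +
    matrix(model@logPrior, nrow = nrow(Q), ncol = length(model@logPrior),
           byrow = TRUE)
  m <- apply(scores, 1L, max)
  post <- exp(scores - m)
  post / rowSums(post)
}

#' Classify query sequences with confidence-based depth truncation
#'
#' Per query, class posteriors are computed in log space (log prior plus the
#' profile-weighted log likelihoods, log-sum-exp normalized). Posteriors are
#' then aggregated bottom-up over classes sharing each lineage prefix of the
#' best class, and the deepest prefix whose aggregated posterior reaches
#' `confidence` is reported. Queries confident at no rank are reported as
#' unassigned (all-empty lineage, serialized as `"Unassigned"`).
#'
#' @param model a [ClassifierModel-class].
#' @param queries a [Biostrings::DNAStringSet].
#' @param confidence posterior mass required to report a rank, in `[0, 1]`
#'   (default 0.7; 0 always reports the best class's full lineage).
#' @return list with `tax` (a [TaxonomyTable-class] of reported lineages)
#'   and `confidence` (named numeric vector, aggregated posterior at the
#'   reported depth; 1 for unassigned queries).
#' @export
classifySeqs <- function(model, queries, confidence = 0.7) {
  stopifnot(is(model, "ClassifierModel"), confidence >= 0, confidence <= 1)
  if (is.character(queries)) queries <- DNAStringSet(queries)
  post <- .classPosteriors(model, queries)
  n <- length(model@schema)
  ## per-depth prefix keys of the classes
  prefKeys <- vapply(seq_len(n), function(r)
    apply(model@classLabels[, seq_len(r), drop = FALSE], 1L, paste,
          collapse = "\x1f"), character(nrow(model@classLabels)))
  if (nrow(model@classLabels) == 1L) prefKeys <- matrix(prefKeys, nrow = 1L)
  labels <- matrix("", nrow(post), n)
  info <- matrix(FALSE, nrow(post), n)
  conf <- numeric(nrow(post))
  for (q in seq_len(nrow(post))) {
    p <- post[q, ]
    best <- which.max(p)
    depth <- 0L
    agg <- 1
    for (d in n:1) {
      a <- sum(p[prefKeys[, d] == prefKeys[best, d]])
      if (a >= confidence) {
        depth <- d
        agg <- a
        break
      }
    }
    if (depth > 0L) {
      labels[q, seq_len(depth)] <- model@classLabels[best, seq_len(depth)]
      info[q, seq_len(depth)] <-
        model@classInformative[best, seq_len(depth)]
    }
    conf[q] <- agg
  }
  tax <- taxonomyTable(names(queries), labels = labels, informative = info,
                       schema = model@schema)
  list(tax = tax, confidence = setNames(conf, names(queries)))
}

#' Posterior class probabilities for query sequences
#'
#' @param model a [ClassifierModel-class].
#' @param queries a [Biostrings::DNAStringSet].
#' @return numeric matrix (queries x classes), rows summing to 1; columns
#'   named by serialized class lineage.
#' @export
classPosteriors <- function(model, queries) {
  if (is.character(queries)) queries <- DNAStringSet(queries)
  post <- .classPosteriors(model, queries)
  sch <- model@schema
  colnames(post) <- apply(model@classLabels, 1L, function(lab)
    paste0(sch@handles, lab, collapse = "; "))
  rownames(post) <- names(queries)
  post
}

#' Write classifications as taxonomy TSV with a Confidence column
#'
#' Unassigned queries (no rank reported) are written as `"Unassigned"`.
#'
#' @param classified result of [classifySeqs()].
#' @param path output path.
#' @export
writeClassificationTsv <- function(classified, path) {
  s <- lineageStrings(classified$tax)
  empty <- apply(taxLabels(classified$tax) == "", 1L, all)
  s[empty] <- "Unassigned"
  df <- data.frame("Feature ID" = names(s), Taxon = unname(s),
                   Confidence = unname(classified$confidence[names(s)]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

setMethod("show", "ClassifierModel", function(object) {
  cat("Kmer naive Bayes ClassifierModel: k =", object@k,
      ", alpha =", object@alpha, "\n")
  cat("  ", nrow(object@classLabels), " classes over ",
      length(object@schema), " ranks\n", sep = "")
})
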