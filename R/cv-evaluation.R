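#' Stratified k-fold assignment by full lineage
#'
#' Records are grouped by full lineage; within each group the members are
#' shuffled (seeded) and dealt round-robin over the folds, with the starting
#' fold rotating across groups so fold sizes stay balanced. Groups smaller
#' than `k` consequently appear in fewer folds, and singletons in exactly
#' one test fold. Deterministic given the seed.
#'
#' @param tax a non-empty [TaxonomyTable-class].
#' @param k fold count (>= 2, <= number of records).
#' @param seed integer RNG seed.
#' @return named integer vector (identifier -> fold index in `1..k`), with
#'   attributes `k` and `seed`.
#' @export
stratifiedKFold <- function(tax, k = 3L, seed = 1L) {
  stopifnot(is(tax, "TaxonomyTable"), length(tax) > 0L)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > length(tax)) stop("k exceeds the number of records")
  keys <- .lineageKeys(tax)
  ids <- taxIds(tax)
  groups <- split(ids, factor(keys, levels = unique(keys)))
  fold <- integer(0)
  withr::with_seed(as.integer(seed), {
    start <- 0L
    for (g in groups) {
      g <- sample(g)
      f <- ((start + seq_along(g) - 1L) %% k) + 1L
      fold <- c(fold, setNames(f, g))
      start <- (start + length(g)) %% k
    }
  })
  fold <- fold[ids]
  attr(fold, "k") <- k
  attr(fold, "seed") <- as.integer(seed)
  fold
}

#' Expected taxonomy under LCA truncation of taxonomic singletons
#'
#' A test record whose full lineage also occurs in the training set keeps
#' its lineage. A taxonomic singleton (lineage absent from training) cannot
#' be classified to full depth even in principle; its expected lineage is
#' truncated to the LCA with its nearest training taxon, i.e. the longest
#' rank-wise prefix it shares with any training lineage (remaining ranks
#' emptied).
#'
#' @param testTax,trainTax [TaxonomyTable-class] objects sharing a schema.
#' @return A [TaxonomyTable-class] parallel to `testTax`.
#' @export
expectedWithLcaTruncation <- function(testTax, trainTax) {
  stopifnot(is(testTax, "TaxonomyTable"), is(trainTax, "TaxonomyTable"),
            identical(testTax@schema@handles, trainTax@schema@handles))
  if (length(trainTax) == 0L) stop("empty training set")
  n <- length(testTax@schema)
  trainKeys <- unique(.lineageKeys(trainTax))
  testKeys <- .lineageKeys(testTax)
  trainLab <- trainTax@labels[match(trainKeys, .lineageKeys(trainTax)), ,
                              drop = FALSE]
  labels <- testTax@labels
  info <- testTax@informative
  for (i in seq_len(nrow(labels))) {
    if (testKeys[i] %in% trainKeys) next
    eq <- trainLab == matrix(labels[i, ], nrow = nrow(trainLab), ncol = n,
                             byrow = TRUE)
    ## depth of the longest all-equal prefix against each training lineage
    depths <- apply(eq, 1L, function(v) {
      bad <- which(!v)
      if (length(bad)) bad[1] - 1L else n
    })
    d <- max(depths)
    if (d < n) {
      labels[i, (d + 1L):n] <- ""
      info[i, (d + 1L):n] <- FALSE
    }
  }
  taxonomyTable(taxIds(testTax), labels = labels, informative = info,
                schema = testTax@schema)
}

#' Per-rank precision / recall / F-measure of classifications
#'
#' At each rank, a query is a true positive when expected and observed are
#' both informative there and their lineage prefixes to that rank match; a
#' false positive when the observed label is informative but wrong or
#' unexpected (over-classification); a false negative when an informative
#' expected label is not recovered (misclassification or
#' under-classification). Over-classification therefore counts only against
#' precision, under-classification only against recall, and
#' misclassification against both. Scores are micro-averaged over the
#' pooled queries.
#'
#' @param expected,observed [TaxonomyTable-class] objects over the same
#'   identifiers and schema.
#' @return data.frame with columns `rank`, `TP`, `FP`, `FN`, `precision`,
#'   `recall`, `F`, and logical `empty_denominator` (set when a rank has no
#'   positives at all and its rates default to 0).
#' @export
evaluateClassifications <- function(expected, observed) {
  stopifnot(is(expected, "TaxonomyTable"), is(observed, "TaxonomyTable"),
            identical(expected@schema@handles, observed@schema@handles))
  if (!setequal(taxIds(expected), taxIds(observed)))
    stop("expected and observed tables must cover the same identifiers")
  observed <- observed[taxIds(expected)]
  n <- length(expected@schema)
  out <- data.frame(rank = expected@schema@ranks,
                    TP = integer(n), FP = integer(n), FN = integer(n),
                    precision = numeric(n), recall = numeric(n),
                    F = numeric(n), empty_denominator = logical(n),
                    stringsAsFactors = FALSE)
  expKey <- matrix("", length(expected), n)
  obsKey <- matrix("", length(expected), n)
  for (r in seq_len(n)) {
    expKey[, r] <- apply(expected@labels[, seq_len(r), drop = FALSE], 1L,
                         paste, collapse = "\x1f")
    obsKey[, r] <- apply(observed@labels[, seq_len(r), drop = FALSE], 1L,
                         paste, collapse = "\x1f")
  }
  for (r in seq_len(n)) {
    expInf <- expected@informative[, r]
    obsInf <- observed@informative[, r]
    tp <- expInf & obsInf & expKey[, r] == obsKey[, r]
    fp <- obsInf & !tp
    fn <- expInf & !tp
    TP <- sum(tp); FP <- sum(fp); FN <- sum(fn)
    P <- if (TP + FP > 0) TP / (TP + FP) else 0
    R <- if (TP + FN > 0) TP / (TP + FN) else 0
    F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
    out[r, 2:8] <- list(TP, FP, FN, P, R, F1,
                        (TP + FP == 0) || (TP + FN == 0))
  }
  out
}

#' Best-case classification accuracy (train = test)
#'
#' Trains the naive Bayes classifier on the full database and classifies
#' the very same sequences, scoring against the untruncated taxonomy. The
#' data leakage is intentional: every query has an exact match in the
#' reference, so the result is the upper bound of classification accuracy
#' for the database.
#'
#' @param seqs a [Biostrings::DNAStringSet].
#' @param tax a matching [TaxonomyTable-class].
#' @param kmerLength,alpha classifier parameters; see [fitClassifier()].
#' @param confidence reporting threshold; see [classifySeqs()].
#' @return the [evaluateClassifications()] data.frame.
#' @export
evaluateFitClassifier <- function(seqs, tax, kmerLength = 7L, alpha = 0.001,
                                  confidence = 0.7) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  model <- fitClassifier(seqs, tax, k = kmerLength, alpha = alpha)
  observed <- classifySeqs(model, seqs, confidence = confidence)$tax
  evaluateClassifications(tax[names(seqs)], observed)
}

#' Cross-validated classification accuracy
#'
#' Stratified k-fold evaluation: per fold, the classifier is trained on the
#' complement, the expected taxonomy of the test fold is derived with
#' [expectedWithLcaTruncation()] against the training taxonomy (so
#' taxonomic singletons are only expected to reach their LCA with the
#' training set), and the fold is classified. All per-query
#' (expected, observed) pairs are pooled across folds and scored once.
#'
#' @param seqs a [Biostrings::DNAStringSet].
#' @param tax a matching [TaxonomyTable-class].
#' @param kFolds fold count (default 3).
#' @param seed RNG seed for the stratified split.
#' @param kmerLength,alpha,confidence classifier parameters.
#' @return the [evaluateClassifications()] data.frame.
#' @export
evaluateCrossValidate <- function(seqs, tax, kFolds = 3L, seed = 1L,
                                  kmerLength = 7L, alpha = 0.001,
                                  confidence = 0.7) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  tax <- tax[names(seqs)]
  folds <- stratifiedKFold(tax, k = kFolds, seed = seed)
  expectedAll <- NULL
  observedAll <- NULL
  for (f in seq_len(attr(folds, "k"))) {
    testIds <- names(folds)[folds == f]
    trainIds <- names(folds)[folds != f]
    if (length(testIds) == 0L) next
    model <- fitClassifier(seqs[trainIds], tax[trainIds], k = kmerLength,
                           alpha = alpha)
    expected <- expectedWithLcaTruncation(tax[testIds], tax[trainIds])
    observed <- classifySeqs(model, seqs[testIds],
                             confidence = confidence)$tax
    expectedAll <- if (is.null(expectedAll)) expected else
      rbind2(expectedAll, expected)
    observedAll <- if (is.null(observedAll)) observed else
      rbind2(observedAll, observed)
  }
  evaluateClassifications(expectedAll, observedAll)
}

#' Write a per-rank precision/recall/F report as TSV
#'
#' @param report the [evaluateClassifications()] data.frame.
#' @param path output path.
#' @export
writePrfTsv <- function(report, path) {
  utils::write.table(
    report[, c("rank", "precision", "recall", "F", "TP", "FP", "FN")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
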