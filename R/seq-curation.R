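## longest single-base run per sequence (character vector input)
.maxHomopolymerRun <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return(0L)
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    max(r$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

## count of IUPAC codes outside A/C/G/T
.ambiguousCount <- function(seqs) {
  acgt <- rowSums(letterFrequency(seqs, c("A", "C", "G", "T")))
  as.integer(width(seqs) - acgt)
}

#' Remove low-quality sequences (homopolymers, ambiguous bases)
#'
#' After optional gap removal a record is culled when its longest single-base
#' run exceeds `maxHomopolymer` \emph{or} it contains more than
#' `maxAmbiguous` IUPAC characters outside A/C/G/T. Comparisons are strict
#' (`>`), so a run of exactly `maxHomopolymer` or exactly `maxAmbiguous`
#' ambiguous bases is kept. Homopolymer runs are measured after degapping;
#' the homopolymer rule is checked first for reason attribution.
#'
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector).
#' @param maxHomopolymer maximum tolerated homopolymer run length
#'   (default 8; a common choice for COI barcode data is 12).
#' @param maxAmbiguous maximum tolerated count of ambiguous bases (default 5).
#' @param degap remove `-`/`.` characters before filtering (default `TRUE`).
#' @return list with elements `seqs` (surviving [Biostrings::DNAStringSet],
#'   input order, degapped when `degap`) and `report`
#'   ([CurationReport-class]).
#' @export
cullSeqs <- function(seqs, maxHomopolymer = 8L, maxAmbiguous = 5L,
                     degap = TRUE) {
  stopifnot(maxHomopolymer >= 1L, maxAmbiguous >= 1L)
  ids <- names(seqs)
  if (is.null(ids)) stop("sequences must be named")
  x <- setNames(as.character(seqs), ids)
  .checkAlphabet(x, ids, allowGaps = TRUE)
  if (degap) x <- gsub("[-.]", "", x)
  xs <- DNAStringSet(setNames(x, ids))
  runs <- .maxHomopolymerRun(x)
  ambig <- .ambiguousCount(xs)
  byRun <- runs > maxHomopolymer
  byAmb <- !byRun & ambig > maxAmbiguous
  keep <- !byRun & !byAmb
  list(seqs = xs[keep],
       report = .curationReport(ids[keep],
                                list(homopolymer = ids[byRun],
                                     ambiguous = ids[byAmb])))
}

#' Filter sequences by length
#'
#' A record is kept iff `minLen <= length <= maxLen` (inclusive bounds; an
#' absent bound is unbounded).
#'
#' @param seqs a [Biostrings::DNAStringSet].
#' @param minLen,maxLen integer bounds or `NULL`.
#' @return list with `seqs` and `report` as in [cullSeqs()].
#' @export
filterSeqsLength <- function(seqs, minLen = NULL, maxLen = NULL) {
  if (is.null(minLen) && is.null(maxLen)) {
    warning("no length bounds given; filter is a no-op")
  }
  if (!is.null(minLen) && !is.null(maxLen) && minLen > maxLen)
    stop("minLen must not exceed maxLen")
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  w <- width(seqs)
  ids <- names(seqs)
  tooShort <- if (is.null(minLen)) rep(FALSE, length(w)) else w < minLen
  tooLong <- if (is.null(maxLen)) rep(FALSE, length(w)) else
    (!tooShort & w > maxLen)
  keep <- !tooShort & !tooLong
  list(seqs = seqs[keep],
       report = .curationReport(ids[keep],
                                list(too_short = ids[tooShort],
                                     too_long = ids[tooLong])))
}

#' Filter sequences by taxon-specific length bounds
#'
#' Length windows are attached to taxonomy labels (e.g. Archaea >= 900 nt
#' and Bacteria >= 1200 nt, the bounds applied to SSU rRNA reference
#' releases). A record matching a constrained label anywhere in its lineage
#' must satisfy that constraint; a record matching several constraints must
#' satisfy all of them (the most restrictive window wins). Unmatched records
#' pass.
#'
#' @param seqs a [Biostrings::DNAStringSet].
#' @param tax a [TaxonomyTable-class] covering the sequences.
#' @param constraints named list, label -> `c(min, max)` (use `NA` for an
#'   unbounded side).
#' @param rank optional rank name restricting where labels are matched
#'   (default: anywhere in the lineage).
#' @param missing what to do with records lacking a taxonomy entry:
#'   `"error"` (default) or `"pass"`.
#' @return list with `seqs` and `report` as in [cullSeqs()].
#' @export
filterSeqsLengthByTaxon <- function(seqs, tax, constraints, rank = NULL,
                                    missing = c("error", "pass")) {
  missing <- match.arg(missing)
  stopifnot(is(tax, "TaxonomyTable"), is.list(constraints),
            !is.null(names(constraints)))
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  ids <- names(seqs)
  absent <- setdiff(ids, taxIds(tax))
  if (length(absent) && missing == "error")
    stop("records without taxonomy: ", paste(absent, collapse = ", "))
  lab <- tax@labels
  cols <- if (is.null(rank)) seq_len(ncol(lab)) else rankIndex(tax@schema, rank)
  w <- width(seqs)
  violated <- vapply(seq_along(ids), function(i) {
    if (ids[i] %in% absent) return(FALSE)
    row <- lab[ids[i], cols]
    lo <- -Inf; hi <- Inf
    for (labName in names(constraints)) {
      if (labName %in% row) {
        b <- constraints[[labName]]
        if (!is.na(b[1])) lo <- max(lo, b[1])
        if (length(b) > 1L && !is.na(b[2])) hi <- min(hi, b[2])
      }
    }
    w[i] < lo || w[i] > hi
  }, logical(1))
  keep <- !violated
  list(seqs = seqs[keep],
       report = .curationReport(ids[keep],
                                list(taxon_length = ids[violated])))
}

#' Filter taxonomy records by annotation depth
#'
#' Keeps entries whose deepest informative rank is at or below
#' `requiredRank` — e.g. `requiredRank = "order"` retains records annotated
#' at the order level or below, a useful strictness filter for databases
#' with many shallow annotations.
#'
#' @param tax a [TaxonomyTable-class].
#' @param requiredRank rank name in the table's schema.
#' @return list with `tax` (filtered [TaxonomyTable-class]) and `report`
#'   ([CurationReport-class]).
#' @export
filterByAnnotationDepth <- function(tax, requiredRank) {
  stopifnot(is(tax, "TaxonomyTable"))
  need <- rankIndex(tax@schema, requiredRank)
  depth <- terminalDepths(tax)
  keep <- depth >= need
  ids <- taxIds(tax)
  list(tax = tax[keep],
       report = .curationReport(ids[keep],
                                list(shallow_annotation = ids[!keep])))
}
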