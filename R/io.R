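#' @importFrom Biostrings DNAStringSet readBStringSet writeXStringSet
#'   oligonucleotideFrequency letterFrequency pairwiseAlignment
#'   nucleotideSubstitutionMatrix pid width
NULL

.IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D",
                "H", "V", "N")
.GAP_CHARS <- c("-", ".")

## uppercase, RNA U -> T; returns character vector
.normalizeSeqChars <- function(x) {
  chartr("uU", "tT", x)
}

## validate an IUPAC DNA alphabet (+ optional gaps); error names the first
## offending character and its position
.checkAlphabet <- function(x, ids = names(x), allowGaps = TRUE) {
  ## '.' is literal inside a bracket expression; '-' is literal when last
  pat <- paste0("[^", paste(.IUPAC_DNA, collapse = ""),
                if (allowGaps) ".-", "]")
  bad <- regexpr(pat, x)
  hit <- which(bad > 0L)
  if (length(hit)) {
    i <- hit[1]
    stop("non-IUPAC character '", substring(x[i], bad[i], bad[i]),
         "' at position ", bad[i], " of record '",
         if (!is.null(ids)) ids[i] else i, "'")
  }
  invisible(TRUE)
}

#' Read nucleotide sequences from FASTA
#'
#' Sequences are normalized on read: uppercased, RNA `U` converted to `T`,
#' and validated against the IUPAC DNA alphabet (gap characters `-` and `.`
#' are tolerated and may be removed later by [cullSeqs()]). Gzipped files are
#' read transparently. The full header line is kept as the record identifier.
#'
#' @param path FASTA file (optionally `.gz`).
#' @return A [Biostrings::DNAStringSet] (gap-containing records are returned
#'   as such, encoded with `-`/`.`).
#' @export
readFasta <- function(path) {
  raw <- readBStringSet(path)
  if (length(raw) == 0L) {
    warning("empty FASTA file: ", path)
    return(DNAStringSet())
  }
  x <- toupper(as.character(raw))
  x <- .normalizeSeqChars(x)
  x <- toupper(x)
  names(x) <- names(raw)
  if (anyDuplicated(names(x)))
    stop("duplicate FASTA identifiers: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  .checkAlphabet(x)
  DNAStringSet(x)
}

#' Write sequences as wrapped FASTA
#'
#' Deterministic output: 80-column wrapping, records in input order; `.gz`
#' paths are compressed.
#'
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, path, width = 80L,
                  compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a two-column taxonomy table (Feature ID, Taxon)
#'
#' The canonical dialect is tab-separated with header
#' `"Feature ID<TAB>Taxon"` and lineage fields joined by `"; "`. A headerless
#' file is accepted with a warning when `lenient = TRUE`.
#'
#' @param path TSV file (optionally `.gz`).
#' @param schema a [RankSchema-class]; when `NULL` the schema is inferred
#'   from the rank prefixes present in the file.
#' @param lenient accept a missing header with a warning.
#' @param ambiguousVocab see [ambiguousLabelVocabulary()].
#' @return A [TaxonomyTable-class].
#' @export
readTaxonomyTsv <- function(path, schema = NULL, lenient = FALSE,
                            ambiguousVocab = ambiguousLabelVocabulary()) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) != 2L)
    stop("taxonomy TSV must have exactly 2 columns, found ", ncol(df))
  if (nrow(df) && identical(tolower(df[1, 1]), "feature id")) {
    df <- df[-1L, , drop = FALSE]
  } else if (lenient) {
    warning("taxonomy TSV lacks a 'Feature ID\tTaxon' header; ",
            "assuming headerless data")
  } else {
    stop("taxonomy TSV must start with a 'Feature ID\tTaxon' header ",
         "(use lenient = TRUE to accept headerless files)")
  }
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate Feature ID: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(schema)) schema <- .inferSchema(df[[2]])
  lins <- lapply(df[[2]], parseLineage, schema = schema,
                 ambiguousVocab = ambiguousVocab)
  taxonomyTable(ids, lins, schema = schema)
}

.RANK_BY_LETTER <- c(d = "domain", k = "kingdom", p = "phylum", c = "class",
                     o = "order", f = "family", g = "genus", s = "species")

## infer a schema from the rank prefixes observed across lineage strings
.inferSchema <- function(texts) {
  fields <- trimws(unlist(strsplit(texts, ";", fixed = TRUE)))
  pref <- regmatches(fields, regexpr("^[A-Za-z0-9]+__", fields))
  handles <- unique(pref)
  if (length(handles) == 0L)
    stop("cannot infer a schema from prefix-free lineages; pass `schema`")
  ## order handles by their first co-occurrence position within a record
  first <- vapply(handles, function(h) {
    for (tx in texts) {
      fs <- trimws(strsplit(tx, ";", fixed = TRUE)[[1]])
      i <- which(startsWith(fs, h))
      if (length(i)) return(i[1])
    }
    NA_integer_
  }, integer(1))
  handles <- handles[order(first)]
  letters1 <- substring(handles, 1L, 1L)
  ranks <- ifelse(letters1 %in% names(.RANK_BY_LETTER),
                  .RANK_BY_LETTER[letters1], sub("__$", "", handles))
  rankSchema(handles, unname(ranks))
}

#' Write a taxonomy table as canonical two-column TSV
#'
#' Bit-exact dialect: header `"Feature ID<TAB>Taxon"`, lineage fields joined
#' by `"; "`, one record per line in table order.
#'
#' @param tax a [TaxonomyTable-class].
#' @param path output path.
#' @export
writeTaxonomyTsv <- function(tax, path) {
  s <- lineageStrings(tax)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("Feature ID\tTaxon", con)
  if (length(s)) writeLines(paste(names(s), s, sep = "\t"), con)
  invisible(path)
}

#' Write cluster membership as TSV (centroid, member, identity)
#'
#' @param clusters a [ClusterResult-class].
#' @param path output path.
#' @export
writeClusterTsv <- function(clusters, path) {
  df <- data.frame(
    centroid = rep(clusters@centroids,
                   vapply(clusters@members, length, integer(1))),
    member = unlist(clusters@members, use.names = FALSE),
    identity = unlist(clusters@identities, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a provenance sidecar log
#'
#' Records the effective parameters of a run as JSON next to its outputs so
#' any result file can be traced back to the exact configuration that
#' produced it.
#'
#' @param path output `.json` path.
#' @param action name of the action run.
#' @param params named list of effective parameters.
#' @export
writeProvenance <- function(path, action, params) {
  rec <- list(action = action,
              package = "taxcurator",
              version = as.character(utils::packageVersion("taxcurator")),
              parameters = params[order(names(params))])
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Serialize / restore a classifier model
#'
#' The model is stored as a single versioned archive; reloading restores a
#' bit-identical model.
#'
#' @param model a [ClassifierModel-class].
#' @param path archive path.
#' @export
writeClassifier <- function(model, path) {
  stopifnot(is(model, "ClassifierModel"))
  payload <- list(format = "taxcurator-nb-classifier", formatVersion = 1L,
                  model = model)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname writeClassifier
#' @return `readClassifier`: a [ClassifierModel-class].
#' @export
readClassifier <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "taxcurator-nb-classifier"))
    stop("not a classifier archive: ", path)
  if (payload$formatVersion > 1L)
    stop("classifier archive version ", payload$formatVersion,
         " is newer than this package supports")
  validObject(payload$model)
  payload$model
}
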