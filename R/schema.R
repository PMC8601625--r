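#' Construct a rank schema
#'
#' @param handles character vector of rank prefixes (each ending in `"__"`),
#'   or all-empty strings for the prefix-free positional dialect.
#' @param ranks character vector of rank names, parallel to `handles`.
#' @return A [RankSchema-class].
#' @examples
#' rankSchema(c("d__", "p__", "g__"), c("domain", "phylum", "genus"))
#' @export
rankSchema <- function(handles, ranks) {
  new("RankSchema", handles = as.character(handles), ranks = as.character(ranks))
}

#' Built-in rank schemas
#'
#' `"silva"` is the six-rank domain-to-genus schema used by SILVA-style
#' curation (`d__` ... `g__`); with `species = TRUE` an `s__` species rank is
#' appended (populated from the source organism name). `"ncbi"` is the
#' seven-rank kingdom-to-species schema (`k__` ... `s__`) used when
#' standardizing NCBI taxonomies. `"greengenes"` is an alias for `"ncbi"`.
#'
#' @param style one of `"silva"`, `"ncbi"`, `"greengenes"`.
#' @param species logical; append a species rank (only meaningful for
#'   `"silva"`, the others already end at species).
#' @return A [RankSchema-class].
#' @export
defaultRankSchema <- function(style = c("silva", "ncbi", "greengenes"),
                              species = FALSE) {
  style <- match.arg(style)
  if (style == "silva") {
    h <- c("d__", "p__", "c__", "o__", "f__", "g__")
    r <- c("domain", "phylum", "class", "order", "family", "genus")
    if (species) {
      h <- c(h, "s__")
      r <- c(r, "species")
    }
    rankSchema(h, r)
  } else {
    rankSchema(c("k__", "p__", "c__", "o__", "f__", "g__", "s__"),
               c("kingdom", "phylum", "class", "order", "family", "genus",
                 "species"))
  }
}

#' Number of ranks in a schema
#' @param x a [RankSchema-class].
#' @return integer rank count.
#' @export
setMethod("length", "RankSchema", function(x) length(x@handles))

#' @describeIn rankSchema rank handles accessor.
#' @param x a [RankSchema-class].
#' @export
rankHandles <- function(x) x@handles

#' @describeIn rankSchema rank names accessor.
#' @export
rankNames <- function(x) x@ranks

#' Index of a rank name within a schema
#'
#' Matching is exact but case-insensitive.
#'
#' @param x a [RankSchema-class].
#' @param rank rank name (e.g. `"genus"`).
#' @return integer index.
#' @export
rankIndex <- function(x, rank) {
  i <- match(tolower(rank), tolower(x@ranks))
  if (is.na(i)) stop("unknown rank name: ", rank)
  i
}

setMethod("show", "RankSchema", function(object) {
  cat("RankSchema with", length(object@handles), "ranks:",
      paste0(object@handles, object@ranks, collapse = ", "), "\n")
})
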