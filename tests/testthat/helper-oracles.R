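# shared fixtures and independent brute-force oracles

schema3 <- rankSchema(c("d__", "p__", "g__"), c("domain", "phylum", "genus"))
schema7 <- defaultRankSchema("silva", species = TRUE)

lin3 <- function(d = "", p = "", g = "") {
  parseLineage(paste0("d__", d, "; p__", p, "; g__", g), schema3)
}

## all multisets (as index vectors, non-decreasing) of sizes 1..maxSize
## drawn from 1..n
multisetIndices <- function(n, maxSize) {
  out <- list()
  grow <- function(prefix, lo) {
    for (i in lo:n) {
      tup <- c(prefix, i)
      out[[length(out) + 1L]] <<- tup
      if (length(tup) < maxSize) grow(tup, i)
    }
  }
  grow(integer(0), 1L)
  out
}

## --- consensus oracles: direct definitions over label matrices -----------

lcaOracle <- function(lab) {
  res <- rep("", ncol(lab))
  for (r in seq_len(ncol(lab))) {
    if (length(unique(lab[, r])) > 1L) break
    res[r] <- lab[1L, r]
  }
  res
}

majorityOracle <- function(lab) {
  key <- apply(lab, 1L, paste, collapse = "|")
  tab <- table(key)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) {
    lab[match(winners, key), ]
  } else {
    lcaOracle(lab[match(winners, key), , drop = FALSE])
  }
}

superOracle <- function(lab) {
  res <- rep("", ncol(lab))
  keep <- rep(TRUE, nrow(lab))
  for (r in seq_len(ncol(lab))) {
    tab <- table(lab[keep, r])
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) != 1L) break
    res[r] <- winners
    keep <- keep & lab[, r] == winners
  }
  res
}

## --- per-rank confusion-count oracle over (expected, observed) pairs -----

## expLab/obsLab: character matrices (queries x ranks); "" = unclassified.
## Direct per-query application of the TP/FP/FN rules, independent of the
## package's vectorized implementation.
confusionOracle <- function(expLab, obsLab) {
  n <- ncol(expLab)
  out <- data.frame(rank = seq_len(n), TP = 0L, FP = 0L, FN = 0L)
  for (q in seq_len(nrow(expLab))) {
    for (r in seq_len(n)) {
      expInf <- expLab[q, r] != ""
      obsInf <- obsLab[q, r] != ""
      match_ <- identical(expLab[q, 1:r], obsLab[q, 1:r])
      if (expInf && obsInf && match_) {
        out$TP[r] <- out$TP[r] + 1L
      } else {
        if (obsInf) out$FP[r] <- out$FP[r] + 1L
        if (expInf) out$FN[r] <- out$FN[r] + 1L
      }
    }
  }
  out$precision <- ifelse(out$TP + out$FP > 0, out$TP / (out$TP + out$FP), 0)
  out$recall <- ifelse(out$TP + out$FN > 0, out$TP / (out$TP + out$FN), 0)
  out$F <- ifelse(out$precision + out$recall > 0,
                  2 * out$precision * out$recall /
                    (out$precision + out$recall), 0)
  out
}

## build a 2-rank TaxonomyTable from a label matrix (all labels informative)
tab2 <- function(lab, ids = paste0("q", seq_len(nrow(lab)))) {
  taxonomyTable(ids, labels = lab,
                schema = rankSchema(c("g__", "s__"), c("genus", "species")))
}

## --- worked-example SILVA fixture ----------------------------------------

writeSubphylumSilvaFixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(
    "Eukaryota;\t2\tdomain",
    "Eukaryota;Fungi;\t3\tkingdom",
    "Eukaryota;Fungi;Ascomycota;\t4\tphylum",
    "Eukaryota;Fungi;Ascomycota;Taphrinomycotina;\t5\tsubphylum",
    "Eukaryota;Fungi;Ascomycota;Pezizomycotina;\t6\tsubphylum"),
    file.path(dir, "taxrank.tsv"))
  writeLines(c(
    "primaryAccession\tstart\tstop\tpath\torganism_name\ttaxid",
    paste0("Z27393\t1\t1722\tEukaryota;Fungi;Ascomycota;Taphrinomycotina;",
           "\tSaitoella complicata\t5"),
    paste0("AB671439\t1\t2071\tEukaryota;Fungi;Ascomycota;Pezizomycotina;",
           "\tPyronema omphalodes\t6")),
    file.path(dir, "taxmap.tsv"))
  writeLines("(((5,6)4)3)2;", file.path(dir, "taxtree.tre"))
  c(taxrank = file.path(dir, "taxrank.tsv"),
    taxmap = file.path(dir, "taxmap.tsv"),
    taxtree = file.path(dir, "taxtree.tre"))
}

kingdomSchema <- rankSchema(
  c("d__", "k__", "p__", "c__", "o__", "f__", "g__"),
  c("domain", "kingdom", "phylum", "class", "order", "family", "genus"))

## random lineage over schema3 with a seeded generator; may contain empty
## tails and ambiguous labels
randomLineage3 <- function() {
  depth <- sample(0:3, 1L)
  labs <- c(sample(c("A", "B", "C", "uncultured"), depth, replace = TRUE),
            rep("", 3L - depth))
  parseLineage(paste0(c("d__", "p__", "g__"), labs, collapse = "; "), schema3)
}
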