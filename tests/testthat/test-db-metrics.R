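library(Biostrings)

test_that("shannonEntropy evaluates the formula directly", {
  expect_identical(shannonEntropy(5), 0)
  expect_equal(shannonEntropy(c(1, 1)), log(2))
  expect_equal(shannonEntropy(c(3, 1)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)))
  expect_equal(shannonEntropy(c(2, 0, 2)), log(2))  # zero counts ignored
  expect_equal(shannonEntropy(c(1, 1, 1, 1), base = 2), 2)
  expect_error(shannonEntropy(c(0, 0)), "positive")
  expect_error(shannonEntropy(c(-1, 2)), "non-negative")

  ## maximal at the uniform distribution
  set.seed(31)
  for (i in 1:50) {
    n <- sample(2:10, 1)
    counts <- sample(1:20, n, replace = TRUE)
    expect_lte(shannonEntropy(counts), log(n) + 1e-12)
  }
})

test_that("evaluateTaxonomy reports per-rank uniqueness, entropy and terminal ranks", {
  sch <- schema3
  same <- taxonomyTable(
    c("a", "b", "c"),
    rep(list(lin3("A", "B", "X")), 3), schema = sch)
  repSame <- evaluateTaxonomy(same)
  expect_identical(repSame$unique_labels, rep(1L, 3))
  expect_identical(repSame$entropy, rep(0, 3))

  ## two entries differing only at the deepest rank
  two <- taxonomyTable(c("a", "b"),
                       list(lin3("A", "B", "X"), lin3("A", "B", "Y")),
                       schema = sch)
  repTwo <- evaluateTaxonomy(two)
  expect_identical(repTwo$unique_labels, c(1L, 1L, 2L))
  expect_equal(repTwo$entropy[3], log(2))
  expect_equal(repTwo$entropy[2], 0)

  ## terminal and unclassified counting
  mix <- taxonomyTable(c("a", "b"),
                       list(lin3("A", "B", "X"), lin3("A", "B")),
                       schema = sch)
  repMix <- evaluateTaxonomy(mix)
  expect_identical(repMix$terminal, c(0L, 1L, 1L))
  expect_identical(repMix$unclassified, c(0L, 0L, 1L))
  expect_identical(sum(repMix$terminal) + attr(repMix, "unannotated"),
                   length(mix))

  ## unclassified + informative = table size at every rank
  expect_true(all(repMix$unclassified +
                    colSums(taxInformative(mix)) == length(mix)))
})

test_that("evaluateSeqs measures sequence and pooled kmer entropy", {
  dup <- DNAStringSet(setNames(rep("ACGTACGT", 4), paste0("s", 1:4)))
  repDup <- evaluateSeqs(dup, kmerLengths = 2)
  expect_identical(repDup$uniqueSequences, 1L)
  expect_equal(repDup$sequenceEntropy, 0)

  one <- DNAStringSet(c(x = "ACGT"))
  expect_equal(evaluateSeqs(one, kmerLengths = 1)$kmerEntropy$entropy,
               log(4))

  pair <- DNAStringSet(c(a = "AAAA", b = "AAAT"))
  repPair <- evaluateSeqs(pair, kmerLengths = 2)
  expect_equal(repPair$kmerEntropy$entropy, shannonEntropy(c(5, 1)))
  expect_equal(repPair$sequenceEntropy, log(2))

  ## the string-extraction path (k > 8) agrees with the tabulation path
  set.seed(12)
  seqs <- DNAStringSet(setNames(vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = ""),
    character(1)), paste0("s", 1:5)))
  viaTable <- taxcurator:::.pooledKmerCounts(seqs, 8L)
  viaStrings <- local({
    x <- as.character(seqs)
    km <- unlist(lapply(x, function(s)
      substring(s, 1:(nchar(s) - 7L), 8:nchar(s))))
    table(km)
  })
  expect_identical(sort(names(viaTable)), sort(names(viaStrings)))
  expect_equal(unname(viaTable[names(viaStrings)]),
               unname(as.numeric(viaStrings)))
  expect_true(is.finite(
    evaluateSeqs(seqs, kmerLengths = 9)$kmerEntropy$entropy))

  ## records shorter than k contribute no kmers
  expect_true(is.na(
    evaluateSeqs(one, kmerLengths = 16)$kmerEntropy$entropy))
})

test_that("genusSpeciesConsistency flags species whose first token mismatches the genus", {
  sch <- defaultRankSchema("silva", species = TRUE)
  tax <- taxonomyTable(
    c("ok", "bad", "nospecies"),
    list(parseLineage(paste0("d__B; p__P; c__C; o__O; f__F; ",
                             "g__Escherichia; s__Escherichia coli"), sch),
         parseLineage(paste0("d__B; p__P; c__C; o__O; f__F; ",
                             "g__Shigella; s__Escherichia coli"), sch),
         parseLineage("d__B; p__P; c__C; o__O; f__F; g__Bacillus", sch)),
    schema = sch)
  out <- genusSpeciesConsistency(tax)
  expect_equal(out$fraction, 0.5)
  expect_identical(out$offenders, "bad")
  expect_identical(out$n, 2L)

  none <- genusSpeciesConsistency(tax[c("nospecies")])
  expect_true(none$emptyDenominator)
  expect_equal(none$fraction, 0)
})

test_that("taxonomyOverlap reports shared-label proportions after prefix collapse", {
  mk <- function(ids, gl) {
    taxonomyTable(ids, labels = cbind("Bacteria", gl),
                  schema = rankSchema(c("d__", "g__"), c("domain", "genus")))
  }
  ref <- mk(c("r1", "r2", "r3"), c("X", "X_A", "Y"))
  other <- mk(c("o1", "o2"), c("X", "Z"))
  out <- taxonomyOverlap(list(ref = ref, other = other))
  g <- out[out$rank == "genus", ]
  ## ref genus labels collapse to {X, Y}; shared with other = {X} -> 1/2
  expect_equal(g$proportion[g$reference == "ref" & g$comparison == "other"],
               0.5)
  expect_equal(g$proportion[g$reference == "ref" & g$comparison == "ref"], 1)

  ## identical tables share everything; disjoint genera share nothing
  same <- taxonomyOverlap(list(a = ref, b = ref))
  expect_true(all(same$proportion == 1))
  disj <- taxonomyOverlap(list(a = mk("a1", "G1"), b = mk("b1", "G2")))
  gd <- disj[disj$rank == "genus" & disj$order > 0, ]
  expect_true(all(gd$proportion == 0))

  expect_error(taxonomyOverlap(list(only = ref)))
})

test_that("overlap proportions are nested: pairs >= trios >= all-shared", {
  mk <- function(ids, gl) {
    taxonomyTable(ids, labels = cbind("Bacteria", gl),
                  schema = rankSchema(c("d__", "g__"), c("domain", "genus")))
  }
  set.seed(77)
  pool <- paste0("G", 1:12)
  tabs <- lapply(1:3, function(i) {
    g <- sample(pool, 7)
    mk(paste0("t", i, "_", seq_along(g)), g)
  })
  names(tabs) <- c("a", "b", "c")
  out <- taxonomyOverlap(tabs)
  g <- out[out$rank == "genus" & out$reference == "a", ]
  expect_true(all(g$proportion >= 0 & g$proportion <= 1))
  trio <- g$proportion[g$order == 2]
  for (pairCmp in g[g$order == 1, "comparison"]) {
    p <- g$proportion[g$comparison == pairCmp]
    expect_true(all(trio <= p + 1e-12))
  }
})
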