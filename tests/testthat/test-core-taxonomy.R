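test_that("parseLineage matches fields by prefix, fills trailing ranks, and flags ambiguity", {
  lin <- parseLineage("d__Eukaryota; k__Fungi; p__Ascomycota; c__; o__; f__; g__",
                      kingdomSchema)
  expect_identical(lin@labels,
                   c("Eukaryota", "Fungi", "Ascomycota", "", "", "", ""))
  expect_identical(lin@informative,
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))

  empty <- parseLineage("", kingdomSchema)
  expect_true(all(empty@labels == ""))
  expect_false(any(empty@informative))

  amb <- parseLineage("d__Bacteria; p__Firmicutes; g__uncultured", schema3)
  expect_identical(amb@labels[3], "uncultured")
  expect_identical(amb@informative, c(TRUE, TRUE, FALSE))

  ## serialization round-trips exactly
  s <- "d__Bacteria; p__Firmicutes; g__"
  expect_identical(formatLineage(parseLineage(s, schema3)), s)
})

test_that("parseLineage rejects unknown prefixes and too many fields", {
  expect_error(parseLineage("x__Whatever", schema3), "not present in schema")
  expect_error(parseLineage("A; B; C; D", schema3), "fields")
})

test_that("positional (prefix-free) lineages are accepted and normalized", {
  lin <- parseLineage("Bacteria; Firmicutes", schema3)
  expect_identical(lin@labels, c("Bacteria", "Firmicutes", ""))
  expect_identical(formatLineage(lin), "d__Bacteria; p__Firmicutes; g__")
})

test_that("propagateRanks forward-fills empty ranks and is idempotent", {
  expect_identical(
    formatLineage(propagateRanks(parseLineage("d__Bacteria", schema3))),
    "d__Bacteria; p__Bacteria; g__Bacteria")

  full <- parseLineage("d__A; p__B; g__C", schema3)
  expect_identical(formatLineage(propagateRanks(full)), formatLineage(full))

  ## informative mask is untouched by propagation
  prop <- propagateRanks(parseLineage("d__Bacteria", schema3))
  expect_identical(prop@informative, c(TRUE, FALSE, FALSE))

  set.seed(41)
  for (i in 1:50) {
    l <- randomLineage3()
    once <- propagateRanks(l)
    expect_identical(formatLineage(propagateRanks(once)),
                     formatLineage(once))
    ## propagated labels equal their nearest non-empty ancestor
    filled <- once@labels
    raw <- l@labels
    for (r in which(raw == "" & filled != "")) {
      above <- raw[seq_len(r - 1L)]
      expect_identical(filled[r], above[max(which(above != ""))])
    }
  }
})

test_that("truncateAtDepth empties ranks beyond the depth", {
  l <- parseLineage("d__A; p__B; g__C", schema3)
  expect_identical(formatLineage(truncateAtDepth(l, 3)), formatLineage(l))
  expect_identical(formatLineage(truncateAtDepth(l, 2)), "d__A; p__B; g__")
  t0 <- truncateAtDepth(l, 0)
  expect_true(all(t0@labels == ""))
  expect_error(truncateAtDepth(l, 4), "depth")
})

test_that("consensusLineage implements lca, majority and super modes", {
  a <- lin3("A", "B", "X")
  b <- lin3("A", "B", "Y")
  expect_identical(formatLineage(consensusLineage(list(a, b), "lca")),
                   "d__A; p__B; g__")

  l1 <- lin3("A", "B", "X")
  l2 <- lin3("A", "C", "Z")
  expect_identical(formatLineage(consensusLineage(list(l1, l1, l2),
                                                  "majority")),
                   formatLineage(l1))

  s1 <- lin3("A", "B", "")
  s2 <- lin3("A", "C", "")
  expect_identical(formatLineage(consensusLineage(list(s1, s2, s1), "super")),
                   "d__A; p__B; g__")

  expect_identical(formatLineage(consensusLineage(list(a), "lca")),
                   formatLineage(a))
  expect_error(consensusLineage(list(), "lca"))
})

test_that("consensus modes agree with brute-force oracles on random multisets", {
  labels <- c("A", "B", "C")
  pool <- expand.grid(d = labels, p = labels, g = labels,
                      stringsAsFactors = FALSE)
  lineages <- lapply(seq_len(nrow(pool)), function(i)
    lin3(pool$d[i], pool$p[i], pool$g[i]))
  set.seed(99)
  for (i in 1:200) {
    idx <- sort(sample(length(lineages), sample(1:4, 1L), replace = TRUE))
    lab <- as.matrix(pool[idx, , drop = FALSE])
    dimnames(lab) <- NULL
    ms <- lineages[idx]
    expect_identical(consensusLineage(ms, "lca")@labels, lcaOracle(lab))
    expect_identical(consensusLineage(ms, "majority")@labels,
                     unname(majorityOracle(lab)))
    expect_identical(consensusLineage(ms, "super")@labels,
                     unname(superOracle(lab)))
  }
})

test_that("collapsePrefixLabels groups prefix-related labels under the shortest member", {
  expect_setequal(collapsePrefixLabels(c("Lactobacillus", "Lactobacillus_A")),
                  "Lactobacillus")
  expect_setequal(collapsePrefixLabels(c("Bacillus", "Clostridium")),
                  c("Bacillus", "Clostridium"))
  expect_setequal(collapsePrefixLabels(c("X", "X_A", "X_B", "Y")),
                  c("X", "Y"))
  ## chains collapse transitively
  expect_setequal(collapsePrefixLabels(c("X", "X_A", "X_AB")), "X")

  ## no two output labels ever stand in a prefix relation
  set.seed(5)
  alphabet <- c("Lacto", "Lactobacillus", "Lactobacillus_A", "Bac",
                "Bacillus", "BacillusX", "Clostridium", "C")
  for (i in 1:50) {
    out <- collapsePrefixLabels(sample(alphabet, sample(2:8, 1L)))
    for (a in out) for (b in out) {
      if (a != b) expect_false(startsWith(b, a))
    }
  }
})
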