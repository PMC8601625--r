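# hand-built taxdump fixture: superkingdom -> phylum -> genus -> species,
# with no class/order/family nodes at all
.writeTaxdumpFixture <- function(dir, dialect = "pipe") {
  nodes <- data.frame(
    taxid = c(1L, 2L, 3L, 4L, 5L),
    parent = c(1L, 1L, 2L, 3L, 4L),
    rank = c("no rank", "superkingdom", "phylum", "genus", "species"))
  names_ <- data.frame(
    taxid = 1:5,
    name = c("root", "Bacteria", "Firmicutes", "Bacillus",
             "Bacillus subtilis"))
  fmt <- function(df) {
    if (dialect == "pipe") {
      apply(df, 1L, function(r) paste0(paste(trimws(r),
                                             collapse = "\t|\t"), "\t|"))
    } else {
      apply(df, 1L, function(r) paste(trimws(r), collapse = "\t"))
    }
  }
  writeLines(fmt(nodes), file.path(dir, "nodes.dmp"))
  writeLines(fmt(cbind(names_, unique_name = "",
                       class = "scientific name")),
             file.path(dir, "names.dmp"))
  writeLines(c("accession\ttaxid", "ACC001\t5"),
             file.path(dir, "acc2taxid.tsv"))
  c(nodes = file.path(dir, "nodes.dmp"),
    names = file.path(dir, "names.dmp"),
    acc2taxid = file.path(dir, "acc2taxid.tsv"))
}

test_that("missing ranks are propagated down from the nearest higher rank", {
  for (dialect in c("pipe", "tsv")) {
    dir <- withr::local_tempdir()
    f <- .writeTaxdumpFixture(dir, dialect)
    tb <- readTaxdumpFiles(f["nodes"], f["names"], f["acc2taxid"])
    on <- buildNcbiTaxonomy(tb, propagate = TRUE)
    expect_identical(
      unname(lineageStrings(on)),
      paste0("k__Bacteria; p__Firmicutes; c__Firmicutes; o__Firmicutes; ",
             "f__Firmicutes; g__Bacillus; s__Bacillus subtilis"))
    off <- buildNcbiTaxonomy(tb, propagate = FALSE)
    expect_identical(
      unname(lineageStrings(off)),
      paste0("k__Bacteria; p__Firmicutes; c__; o__; f__; ",
             "g__Bacillus; s__Bacillus subtilis"))
    ## propagation changes only non-informative ranks
    diff <- taxLabels(on) != taxLabels(off)
    expect_true(all(!taxInformative(on)[diff]))
    expect_identical(taxInformative(on), taxInformative(off))
  }
})

test_that("a chain carrying all schema ranks projects verbatim", {
  dir <- withr::local_tempdir()
  ranks <- c("no rank", "superkingdom", "phylum", "class", "order",
             "family", "genus", "species")
  nms <- c("root", "K", "P", "C", "O", "F", "G", "G sp")
  writeLines(paste(1:8, c(1L, 1:7), ranks, sep = "\t"),
             file.path(dir, "nodes.tsv"))
  writeLines(paste(1:8, nms, sep = "\t"), file.path(dir, "names.tsv"))
  writeLines(c("accession\ttaxid", "A1\t8"), file.path(dir, "acc.tsv"))
  tb <- readTaxdumpFiles(file.path(dir, "nodes.tsv"),
                         file.path(dir, "names.tsv"),
                         file.path(dir, "acc.tsv"))
  tt <- buildNcbiTaxonomy(tb, propagate = FALSE)
  expect_identical(unname(lineageStrings(tt)),
                   "k__K; p__P; c__C; o__O; f__F; g__G; s__G sp")
})

test_that("unresolvable accessions and parent-chain cycles are reported", {
  dir <- withr::local_tempdir()
  f <- .writeTaxdumpFixture(dir)
  tb <- readTaxdumpFiles(f["nodes"], f["names"], f["acc2taxid"])
  tb$acc2taxid$taxid <- 77L
  expect_error(buildNcbiTaxonomy(tb), "ACC001")

  tb2 <- readTaxdumpFiles(f["nodes"], f["names"], f["acc2taxid"])
  tb2$nodes$parent[tb2$nodes$taxid == 2L] <- 3L  # 2 -> 3 -> 2 cycle
  expect_error(buildNcbiTaxonomy(tb2), "cycle")
})

test_that("emitted taxdump tables round-trip a generated taxonomy exactly", {
  db <- generateReferenceDb(fixtureSpec(seed = 11, nPhyla = 2,
                                        nGeneraPerPhylum = 2,
                                        nSpeciesPerGenus = 2,
                                        seqsPerSpecies = 2))
  for (dialect in c("pipe", "tsv")) {
    dir <- withr::local_tempdir()
    f <- emitTaxdumpFiles(db$tax, dir, dialect = dialect)
    tb <- readTaxdumpFiles(f["nodes"], f["names"], f["acc2taxid"])
    back <- buildNcbiTaxonomy(tb, schema = taxSchema(db$tax),
                              rankAliases = c())
    expect_identical(lineageStrings(back), lineageStrings(db$tax))
  }
})

test_that("the superkingdom alias feeds the kingdom rank", {
  schemaK <- defaultRankSchema("ncbi")
  lin <- parseLineage(
    "k__Bacteria; p__P1; c__C1; o__O1; f__F1; g__G1; s__G1 spx", schemaK)
  tax <- taxonomyTable("X1", list(lin), schema = schemaK)
  dir <- withr::local_tempdir()
  f <- emitTaxdumpFiles(tax, dir, useSuperkingdom = TRUE)
  tb <- readTaxdumpFiles(f["nodes"], f["names"], f["acc2taxid"])
  expect_true("superkingdom" %in% tb$nodes$rank)
  back <- buildNcbiTaxonomy(tb)  # default alias superkingdom -> kingdom
  expect_identical(lineageStrings(back), lineageStrings(tax))
})
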