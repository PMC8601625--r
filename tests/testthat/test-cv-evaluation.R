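library(Biostrings)

test_that("stratifiedKFold distributes taxonomic groups across folds", {
  sch <- schema3
  ids <- paste0("r", 1:9)
  tax <- taxonomyTable(ids, lapply(rep(1:3, each = 3), function(i)
    lin3("D", "P", paste0("G", i))), schema = sch)
  folds <- stratifiedKFold(tax, k = 3, seed = 5)
  ## each fold holds exactly one member of each of the 3 classes
  for (f in 1:3) {
    inFold <- names(folds)[folds == f]
    expect_identical(length(inFold), 3L)
    expect_setequal(substr(taxLabels(tax)[inFold, "genus"], 2, 2),
                    as.character(1:3))
  }

  ## singleton classes appear in exactly one fold
  tax2 <- taxonomyTable(c(ids, "solo"),
                        c(lapply(rep(1:3, each = 3), function(i)
                          lin3("D", "P", paste0("G", i))),
                          list(lin3("D", "P", "Gsolo"))), schema = sch)
  folds2 <- stratifiedKFold(tax2, k = 3, seed = 5)
  expect_identical(sum(names(folds2) == "solo"), 1L)

  ## determinism and the partition property for k in 2..5
  set.seed(61)
  big <- taxonomyTable(paste0("x", 1:23), lapply(1:23, function(i)
    lin3("D", "P", paste0("G", sample(5, 1)))), schema = sch)
  for (k in 2:5) {
    f1 <- stratifiedKFold(big, k = k, seed = 99)
    f2 <- stratifiedKFold(big, k = k, seed = 99)
    expect_identical(f1, f2)
    expect_setequal(names(f1), taxIds(big))
    expect_true(all(f1 %in% seq_len(k)))
    expect_lte(max(table(f1)) - min(table(factor(f1, levels = 1:k))), 5)
  }
  expect_error(stratifiedKFold(tax, k = 100, seed = 1), "exceeds")
})

test_that("expected taxonomy truncates singletons to their LCA with training", {
  sch <- schema3
  train <- taxonomyTable(c("t1", "t2"),
                         list(lin3("D", "P", "G1"), lin3("D", "P", "G2")),
                         schema = sch)
  test_ <- taxonomyTable(c("present", "genusNew", "alien"),
                         list(lin3("D", "P", "G1"), lin3("D", "P", "G9"),
                              lin3("E", "Q", "Z")), schema = sch)
  exp_ <- expectedWithLcaTruncation(test_, train)
  s <- lineageStrings(exp_)
  expect_identical(unname(s["present"]), "d__D; p__P; g__G1")
  expect_identical(unname(s["genusNew"]), "d__D; p__P; g__")
  expect_identical(unname(s["alien"]), "d__; p__; g__")
  expect_error(expectedWithLcaTruncation(test_, train[integer(0)]), "empty")
})

test_that("evaluateClassifications reproduces the hand-counted confusion set", {
  ## 4 queries at the deepest rank: 2 correct, 1 wrong label,
  ## 1 expected-informative but unclassified
  expLab <- rbind(c("G", "s1"), c("G", "s2"), c("G", "s3"), c("G", "s4"))
  obsLab <- rbind(c("G", "s1"), c("G", "s2"), c("G", "sX"), c("G", ""))
  out <- evaluateClassifications(tab2(expLab), tab2(obsLab))
  sp <- out[out$rank == "species", ]
  expect_identical(c(sp$TP, sp$FP, sp$FN), c(2L, 1L, 2L))
  expect_equal(sp$precision, 2 / 3)
  expect_equal(sp$recall, 1 / 2)
  expect_equal(sp$F, 4 / 7)

  ## over-classification: FP at the rank, never FN
  expLab2 <- rbind(c("G", ""))
  obsLab2 <- rbind(c("G", "s1"))
  out2 <- evaluateClassifications(tab2(expLab2), tab2(obsLab2))
  sp2 <- out2[out2$rank == "species", ]
  expect_identical(c(sp2$TP, sp2$FP, sp2$FN), c(0L, 1L, 0L))

  ## perfect agreement scores 1 everywhere
  out3 <- evaluateClassifications(tab2(expLab), tab2(expLab))
  expect_true(all(out3$F == 1))
})

test_that("evaluateClassifications matches the brute-force confusion oracle exhaustively", {
  ## all (expected, observed) single-query configurations over a 2-rank
  ## schema with labels {A, B, unclassified}
  cells <- expand.grid(r1 = c("A", "B", ""), r2 = c("A", "B", ""),
                       stringsAsFactors = FALSE)
  cells <- cells[!(cells$r1 == "" & cells$r2 != ""), ]  # no rank gaps
  cfgs <- seq_len(nrow(cells))
  for (e in cfgs) {
    for (o in cfgs) {
      expLab <- matrix(unlist(cells[e, ]), 1)
      obsLab <- matrix(unlist(cells[o, ]), 1)
      got <- evaluateClassifications(tab2(expLab), tab2(obsLab))
      want <- confusionOracle(expLab, obsLab)
      expect_identical(got$TP, want$TP)
      expect_identical(got$FP, want$FP)
      expect_identical(got$FN, want$FN)
      expect_equal(got$F, want$F)
    }
  }
})

test_that("pooled multi-query scoring matches the oracle on random configurations", {
  set.seed(44)
  vals <- c("A", "B", "")
  randLab <- function(n) {
    m <- cbind(sample(vals, n, TRUE), sample(vals, n, TRUE))
    m[m[, 1] == "", 2] <- ""
    m
  }
  for (i in 1:100) {
    n <- sample(1:3, 1)
    expLab <- randLab(n)
    obsLab <- randLab(n)
    got <- evaluateClassifications(tab2(expLab), tab2(obsLab))
    want <- confusionOracle(expLab, obsLab)
    expect_identical(got$TP, want$TP)
    expect_identical(got$FP, want$FP)
    expect_identical(got$FN, want$FN)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
  }
})

test_that("fit-classifier accuracy bounds cross-validated accuracy", {
  for (seed in c(2, 13)) {
    db <- generateReferenceDb(fixtureSpec(seed = seed, nPhyla = 1L,
                                          nGeneraPerPhylum = 2L,
                                          nSpeciesPerGenus = 2L,
                                          seqsPerSpecies = 4L,
                                          seqLength = 150L))
    fit <- evaluateFitClassifier(db$seqs, db$tax)
    cv <- evaluateCrossValidate(db$seqs, db$tax, kFolds = 3, seed = seed)
    expect_gte(fit[fit$rank == "species", "F"],
               cv[cv$rank == "species", "F"])
    ## determinism of the whole regime
    cv2 <- evaluateCrossValidate(db$seqs, db$tax, kFolds = 3, seed = seed)
    expect_identical(cv, cv2)
  }
})

test_that("singleton species under shared genera contribute zero species recall", {
  sch <- schema3
  set.seed(3)
  bases <- c("A", "C", "G", "T")
  n <- 6L
  ids <- paste0("r", 1:n)
  seqs <- DNAStringSet(setNames(vapply(1:n, function(i)
    paste(sample(bases, 80, TRUE), collapse = ""), character(1)), ids))
  ## every species is a singleton, all under one genus
  tax <- taxonomyTable(ids, lapply(1:n, function(i)
    lin3("D", "P", paste0("G", i))), schema = sch)
  cv <- evaluateCrossValidate(seqs, tax, kFolds = 3, seed = 1,
                              kmerLength = 4)
  g <- cv[cv$rank == "genus", ]
  expect_identical(g$TP, 0L)
  expect_identical(g$FN, 0L)  # expectations truncated above genus
})
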