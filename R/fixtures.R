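#' Specification for a synthetic reference database
#'
#' Describes the planted taxonomy shape, the sequence divergence structure
#' and the quality defects to inject. All randomness flows from the single
#' `seed`. Divergences are planted with disjoint substitution position
#' blocks so that realized pairwise identities match the specification
#' exactly under gap-free comparison: genus ancestors differ pairwise by
#' `betweenGenusDivergence`, species ancestors within a genus by
#' `2 * betweenSpeciesDivergence`, and each member differs from its species
#' ancestor by `1 - withinSpeciesIdentity`.
#'
#' @param seed integer RNG seed.
#' @param nPhyla,nGeneraPerPhylum,nSpeciesPerGenus,seqsPerSpecies taxonomy
#'   shape and family sizes.
#' @param seqLength sequence length (nt).
#' @param withinSpeciesIdentity member-to-species-ancestor identity in
#'   (0, 1].
#' @param betweenSpeciesDivergence per-species divergence from the genus
#'   ancestor (pairwise species divergence is twice this).
#' @param betweenGenusDivergence pairwise divergence between genus
#'   ancestors.
#' @param ambiguousLabelFraction fraction of records whose species label is
#'   replaced by an ambiguous-vocabulary label.
#' @param homopolymerInjection numeric `c(length, fraction)`: fraction of
#'   records receiving an injected single-base run of the given length.
#' @param ambiguousBaseInjection numeric `c(count, fraction)`: fraction of
#'   records receiving the given number of injected `N` bases.
#' @return a `FixtureSpec` list.
#' @export
fixtureSpec <- function(seed = 1L, nPhyla = 2L, nGeneraPerPhylum = 3L,
                        nSpeciesPerGenus = 4L, seqsPerSpecies = 5L,
                        seqLength = 300L, withinSpeciesIdentity = 0.99,
                        betweenSpeciesDivergence = 0.05,
                        betweenGenusDivergence = 0.20,
                        ambiguousLabelFraction = 0,
                        homopolymerInjection = c(length = 9, fraction = 0),
                        ambiguousBaseInjection = c(count = 6, fraction = 0)) {
  spec <- list(seed = as.integer(seed), nPhyla = as.integer(nPhyla),
               nGeneraPerPhylum = as.integer(nGeneraPerPhylum),
               nSpeciesPerGenus = as.integer(nSpeciesPerGenus),
               seqsPerSpecies = as.integer(seqsPerSpecies),
               seqLength = as.integer(seqLength),
               withinSpeciesIdentity = withinSpeciesIdentity,
               betweenSpeciesDivergence = betweenSpeciesDivergence,
               betweenGenusDivergence = betweenGenusDivergence,
               ambiguousLabelFraction = ambiguousLabelFraction,
               homopolymerInjection = unname(homopolymerInjection),
               ambiguousBaseInjection = unname(ambiguousBaseInjection))
  stopifnot(spec$withinSpeciesIdentity > 0, spec$withinSpeciesIdentity <= 1,
            spec$betweenGenusDivergence > 0,
            spec$betweenGenusDivergence <= 1,
            spec$betweenSpeciesDivergence >= 0,
            spec$betweenSpeciesDivergence <= 1,
            spec$ambiguousLabelFraction >= 0,
            spec$ambiguousLabelFraction <= 1,
            spec$homopolymerInjection[2] >= 0,
            spec$homopolymerInjection[2] <= 1,
            spec$ambiguousBaseInjection[2] >= 0,
            spec$ambiguousBaseInjection[2] <= 1)
  class(spec) <- "FixtureSpec"
  spec
}

.BASES <- c("A", "C", "G", "T")

## substitute the given positions with a uniformly chosen *different* base
.mutateAt <- function(chars, pos) {
  if (length(pos) == 0L) return(chars)
  cur <- chars[pos]
  pick <- vapply(cur, function(b) sample(setdiff(.BASES, b), 1L),
                 character(1), USE.NAMES = FALSE)
  chars[pos] <- pick
  chars
}

## break any single-base run longer than maxRun by substituting every
## (maxRun+1)-th position of the run with a different base
.breakLongRuns <- function(chars, maxRun = 5L) {
  r <- rle(chars)
  long <- which(r$lengths > maxRun)
  if (length(long) == 0L) return(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in long) {
    at <- seq(starts[i] + maxRun, ends[i], by = maxRun + 1L)
    chars <- .mutateAt(chars, at)
  }
  chars
}

#' Generate a seeded synthetic reference database with planted truth
#'
#' Builds a taxonomy honoring the requested shape (one class/order per
#' phylum, one family per genus, species labels of the form
#' `"<genus> sp<i>"` so genus-species consistency holds by construction)
#' and a sequence family per species at the planted divergences (see
#' [fixtureSpec()]; substitution-only, so identities are exact). Quality
#' defects — over-threshold homopolymer runs, ambiguous bases, ambiguous
#' species labels — are injected into disjoint record subsets at the
#' requested fractions, and clean sequences are guaranteed free of runs
#' over 5 nt and of ambiguous bases, so the planted defect lists are the
#' exact filter truth. Fully deterministic given the seed.
#'
#' @param spec a [fixtureSpec()].
#' @return list with `seqs` ([Biostrings::DNAStringSet]), `tax`
#'   ([TaxonomyTable-class], ambiguous-label injections applied) and
#'   `truth`, a list with the planted ground truth: `tax` (true lineages),
#'   `species` (named species assignment = true cluster membership),
#'   `homopolymerIds`, `ambiguousBaseIds`, `ambiguousLabelIds`.
#' @export
generateReferenceDb <- function(spec = fixtureSpec()) {
  stopifnot(inherits(spec, "FixtureSpec"))
  L <- spec$seqLength
  nGenera <- spec$nPhyla * spec$nGeneraPerPhylum
  gBlock <- round(spec$betweenGenusDivergence / 2 * L)
  sBlock <- round(spec$betweenSpeciesDivergence * L)
  if (nGenera * gBlock > L)
    stop("infeasible spec: genus divergence blocks exceed sequence length")
  if (spec$nSpeciesPerGenus * sBlock > L - nGenera * gBlock)
    stop("infeasible spec: species divergence blocks exceed sequence length")
  mMut <- round((1 - spec$withinSpeciesIdentity) * L)
  withr::with_seed(spec$seed, {
    root <- sample(.BASES, L, replace = TRUE)
    genusPos <- if (gBlock > 0L) {
      split(sample(L, nGenera * gBlock),
            rep(seq_len(nGenera), each = gBlock))
    } else {
      rep(list(integer(0)), nGenera)
    }
    freePos <- setdiff(seq_len(L), unlist(genusPos))
    ids <- character(0)
    seqChars <- list()
    rows <- list()
    speciesOf <- character(0)
    gIdx <- 0L
    recIdx <- 0L
    for (p in seq_len(spec$nPhyla)) {
      for (gg in seq_len(spec$nGeneraPerPhylum)) {
        gIdx <- gIdx + 1L
        genusAnc <- .mutateAt(root, genusPos[[gIdx]])
        spPos <- if (sBlock > 0L) {
          split(sample(freePos, spec$nSpeciesPerGenus * sBlock),
                rep(seq_len(spec$nSpeciesPerGenus), each = sBlock))
        } else {
          rep(list(integer(0)), spec$nSpeciesPerGenus)
        }
        for (s in seq_len(spec$nSpeciesPerGenus)) {
          spAnc <- .mutateAt(genusAnc, spPos[[s]])
          genus <- sprintf("Genus%02d", gIdx)
          lineage <- c("Bacteria", sprintf("Phylum%02d", p),
                       sprintf("Class%02d", p), sprintf("Order%02d", p),
                       sprintf("Family%02d", gIdx), genus,
                       sprintf("%s sp%d", genus, s))
          for (m in seq_len(spec$seqsPerSpecies)) {
            recIdx <- recIdx + 1L
            chars <- .mutateAt(spAnc, sample(L, mMut))
            chars <- .breakLongRuns(chars)
            id <- sprintf("A%05d.1.%d", recIdx, L)
            ids <- c(ids, id)
            seqChars[[id]] <- chars
            rows[[id]] <- lineage
            speciesOf[id] <- paste(genus, sprintf("sp%d", s))
          }
        }
      }
    }
    n <- length(ids)
    labels <- do.call(rbind, rows)
    ## disjoint defect subsets
    nHomo <- round(spec$homopolymerInjection[2] * n)
    nAmb <- round(spec$ambiguousBaseInjection[2] * n)
    nLab <- round(spec$ambiguousLabelFraction * n)
    pool <- sample(ids)
    homoIds <- utils::head(pool, nHomo)
    ambIds <- utils::head(setdiff(pool, homoIds), nAmb)
    labIds <- utils::head(setdiff(pool, c(homoIds, ambIds)), nLab)
    runLen <- as.integer(spec$homopolymerInjection[1])
    for (id in homoIds) {
      start <- sample(L - runLen + 1L, 1L)
      base <- sample(.BASES, 1L)
      seqChars[[id]][start:(start + runLen - 1L)] <- base
    }
    ambCount <- as.integer(spec$ambiguousBaseInjection[1])
    for (id in ambIds) {
      seqChars[[id]][sample(L, ambCount)] <- "N"
    }
    ambLabels <- c("uncultured bacterium", "unidentified",
                   "unknown organism", "environmental sample")
    obsLabels <- labels
    for (id in labIds) {
      obsLabels[match(id, ids), 7L] <- sample(ambLabels, 1L)
    }
  })
  schema <- defaultRankSchema("silva", species = TRUE)
  seqs <- DNAStringSet(vapply(seqChars, paste, character(1), collapse = ""))
  truthTax <- taxonomyTable(ids, labels = labels, schema = schema)
  obsTax <- taxonomyTable(ids, labels = obsLabels, schema = schema)
  list(seqs = seqs, tax = obsTax,
       truth = list(tax = truthTax, species = speciesOf,
                    homopolymerIds = homoIds, ambiguousBaseIds = ambIds,
                    ambiguousLabelIds = labIds))
}

## paths (root -> node label vectors) of the distinct non-empty prefixes of
## a taxonomy table, with taxids assigned in first-seen order (root = 1)
.prefixForest <- function(tax, rootName = "Root") {
  lab <- tax@labels
  n <- length(tax@schema)
  pathKey <- c(Root = 1L)
  nodes <- data.frame(taxid = 1L, name = rootName, rank = "no rank",
                      parent = 1L, depth = 0L, stringsAsFactors = FALSE)
  leafTaxid <- integer(nrow(lab))
  for (i in seq_len(nrow(lab))) {
    depth <- max(c(0L, which(lab[i, ] != "")))
    parent <- 1L
    key <- "Root"
    for (r in seq_len(depth)) {
      if (lab[i, r] == "")
        stop("taxonomy contains an empty internal rank; cannot emit a tree")
      key <- paste(key, lab[i, r], sep = "\x1f")
      if (is.na(pathKey[key])) {
        taxid <- max(nodes$taxid) + 1L
        pathKey[key] <- taxid
        nodes <- rbind(nodes, data.frame(
          taxid = taxid, name = lab[i, r], rank = tax@schema@ranks[r],
          parent = parent, depth = r, stringsAsFactors = FALSE))
      }
      parent <- pathKey[[key]]
    }
    leafTaxid[i] <- parent
  }
  list(nodes = nodes, leafTaxid = leafTaxid)
}

## serialize a parent table to Newick with taxid node labels
.forestToNewick <- function(nodes) {
  children <- split(nodes$taxid[-1L], nodes$parent[-1L])
  rec <- function(taxid) {
    kids <- children[[as.character(taxid)]]
    if (is.null(kids)) return(as.character(taxid))
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
           ")", taxid)
  }
  paste0(rec(nodes$taxid[1]), ";")
}

#' Emit a taxonomy table as SILVA-style taxrank/taxmap/taxtree files
#'
#' Writes the three-file SILVA dialect encoding the table, so that
#' [buildSilvaTaxonomy()] on the output recovers the input (the round-trip
#' oracle for the SILVA importer). Identifiers of the form
#' `acc.start.stop` are decomposed into the taxmap accession columns. When
#' the table carries a species rank, the species labels become the taxmap
#' organism names and the tree covers ranks above species only (the SILVA
#' convention). Optionally an intermediate node of an unmapped rank (e.g. a
#' subphylum) is inserted below a named label to exercise rank propagation.
#'
#' @param tax a [TaxonomyTable-class] (internal ranks must be non-empty
#'   down to each record's terminal label).
#' @param dir output directory (created if needed).
#' @param intermediates optional data.frame with columns `below` (parent
#'   label), `name` and `rank`: inserts a singleton node of that unmapped
#'   rank beneath every tree node carrying the `below` label.
#' @return invisible named character vector of the three file paths
#'   (`taxrank`, `taxmap`, `taxtree`).
#' @export
emitSilvaFiles <- function(tax, dir, intermediates = NULL) {
  stopifnot(is(tax, "TaxonomyTable"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hasSpecies <- "species" %in% tolower(tax@schema@ranks)
  treeRanks <- if (hasSpecies) {
    seq_len(rankIndex(tax@schema, "species") - 1L)
  } else {
    seq_len(length(tax@schema))
  }
  treeTax <- taxonomyTable(
    taxIds(tax), labels = tax@labels[, treeRanks, drop = FALSE],
    informative = tax@informative[, treeRanks, drop = FALSE],
    schema = rankSchema(tax@schema@handles[treeRanks],
                        tax@schema@ranks[treeRanks]))
  forest <- .prefixForest(treeTax)
  nodes <- forest$nodes
  leafTaxid <- forest$leafTaxid
  if (!is.null(intermediates)) {
    for (i in seq_len(nrow(intermediates))) {
      at <- which(nodes$name == intermediates$below[i])
      for (pa in nodes$taxid[at]) {
        taxid <- max(nodes$taxid) + 1L
        depth <- nodes$depth[nodes$taxid == pa] + 1L
        kids <- nodes$parent == pa & nodes$taxid != pa
        nodes$parent[kids] <- taxid
        moved <- leafTaxid == pa
        nodes <- rbind(nodes, data.frame(
          taxid = taxid, name = intermediates$name[i],
          rank = intermediates$rank[i], parent = pa, depth = depth,
          stringsAsFactors = FALSE))
        leafTaxid[moved] <- taxid
      }
    }
  }
  ## full path text per node (SILVA style, trailing semicolon)
  pathOf <- setNames(character(nrow(nodes)), as.character(nodes$taxid))
  ord <- order(nodes$depth)
  for (i in ord) {
    pa <- as.character(nodes$parent[i])
    tid <- as.character(nodes$taxid[i])
    pathOf[tid] <- if (nodes$taxid[i] == nodes$parent[i]) "" else
      paste0(pathOf[pa], nodes$name[i], ";")
  }
  taxrankPath <- file.path(dir, "taxrank.tsv")
  keep <- nodes$taxid != nodes$parent | nodes$taxid == 1L
  utils::write.table(
    data.frame(path = ifelse(pathOf[as.character(nodes$taxid)] == "",
                             "Root;", pathOf[as.character(nodes$taxid)]),
               taxid = nodes$taxid, rank = nodes$rank)[keep, ],
    taxrankPath, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  ids <- taxIds(tax)
  m <- regmatches(ids, regexec("^(.*)\\.(\\d+)\\.(\\d+)$", ids))
  pacc <- vapply(seq_along(ids), function(i)
    if (length(m[[i]])) m[[i]][2] else ids[i], character(1))
  start <- vapply(seq_along(ids), function(i)
    if (length(m[[i]])) m[[i]][3] else "1", character(1))
  stop_ <- vapply(seq_along(ids), function(i)
    if (length(m[[i]])) m[[i]][4] else "1", character(1))
  organism <- if (hasSpecies) {
    tax@labels[, rankIndex(tax@schema, "species")]
  } else {
    nodes$name[match(leafTaxid, nodes$taxid)]
  }
  taxmapPath <- file.path(dir, "taxmap.tsv")
  utils::write.table(
    data.frame(primaryAccession = pacc, start = start, stop = stop_,
               path = pathOf[as.character(leafTaxid)],
               organism_name = organism, taxid = leafTaxid),
    taxmapPath, sep = "\t", quote = FALSE, row.names = FALSE)
  taxtreePath <- file.path(dir, "taxtree.tre")
  writeLines(.forestToNewick(nodes), taxtreePath)
  invisible(c(taxrank = taxrankPath, taxmap = taxmapPath,
              taxtree = taxtreePath))
}

#' Emit a taxonomy table as NCBI taxdump-style tables
#'
#' Writes nodes/names tables (classic `|`-delimited taxdump dialect or
#' plain TSV) plus a two-column accession-to-taxid TSV encoding the table,
#' so that [buildNcbiTaxonomy()] on the output recovers the input. With
#' `useSuperkingdom = TRUE` the schema's kingdom rank is written as
#' `"superkingdom"` (the NCBI convention), exercising the importer's rank
#' alias map.
#'
#' @param tax a [TaxonomyTable-class].
#' @param dir output directory.
#' @param dialect `"pipe"` (taxdump) or `"tsv"`.
#' @param useSuperkingdom write the kingdom rank as `superkingdom`.
#' @return invisible named character vector of the three file paths
#'   (`nodes`, `names`, `acc2taxid`).
#' @export
emitTaxdumpFiles <- function(tax, dir, dialect = c("pipe", "tsv"),
                             useSuperkingdom = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(is(tax, "TaxonomyTable"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  forest <- .prefixForest(tax)
  nodes <- forest$nodes
  if (useSuperkingdom) {
    nodes$rank[nodes$rank == "kingdom"] <- "superkingdom"
  }
  fmt <- function(df) {
    if (dialect == "pipe") {
      apply(df, 1L, function(row)
        paste0(paste(trimws(row), collapse = "\t|\t"), "\t|"))
    } else {
      apply(df, 1L, function(row) paste(trimws(row), collapse = "\t"))
    }
  }
  nodesPath <- file.path(dir, if (dialect == "pipe") "nodes.dmp" else
    "nodes.tsv")
  writeLines(fmt(data.frame(nodes$taxid, nodes$parent, nodes$rank)),
             nodesPath)
  namesPath <- file.path(dir, if (dialect == "pipe") "names.dmp" else
    "names.tsv")
  writeLines(fmt(data.frame(nodes$taxid, nodes$name, "",
                            "scientific name")), namesPath)
  accPath <- file.path(dir, "acc2taxid.tsv")
  utils::write.table(
    data.frame(accession = taxIds(tax), taxid = forest$leafTaxid),
    accPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nodes = nodesPath, names = namesPath, acc2taxid = accPath))
}
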