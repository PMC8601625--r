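---
title: "Curating and evaluating marker-gene reference databases with taxcurator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and evaluating marker-gene reference databases with taxcurator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

Amplicon-based surveys of microbial (and other) communities assign taxonomy
to reads by comparing them against a reference database: a set of marker-gene
sequences, each annotated with a ranked lineage. The quality of those
assignments is bounded by the quality of the reference — its sequence
quality, the consistency and depth of its taxonomic labels, and how much of
the relevant clade space it covers. taxcurator implements the computational
steps of building such a reference from common taxonomy distribution
formats, curating it, quantifying its information content, and estimating
the classification accuracy it can support.

The central objects are a `RankSchema` (an ordered list of ranks with their
textual handles, `d__` ... `s__`), a `Lineage` (one label per rank plus an
informative mask) and a `TaxonomyTable` (identifier to lineage). The mask is
the package's representation of annotation quality: a rank is informative
only if it carries a real annotation — empty labels, labels matching the
ambiguous vocabulary (`"uncultured"`, `"unidentified"`, `"unknown"`,
`"unclassified"`, `"metagenome"`, `"environmental"`; configurable) and
labels filled in by rank propagation are all non-informative. All
"unclassified" metrics and the per-rank scorer consult the mask, not the
label text, so a propagated or ambiguous label never masquerades as an
annotation. This is a deliberate design choice where the alternatives
(counting propagated labels as classified) would make propagated databases
look spuriously complete.

# Taxonomy imports and rank propagation

`buildSilvaTaxonomy()` consumes the three-file SILVA dialect: a taxrank
table (taxonomy path, taxid, rank), a taxmap table (accession, start, stop,
path, organism name, taxid) and a Newick taxtree whose node labels are
taxids. For each accession the taxid path is walked root-to-leaf and each
node whose rank matches a schema rank (exact, case-insensitive) contributes
its name. Rank propagation then forward-fills unannotated ranks with the
*last observed* taxonomic value along the path — crucially, that value may
come from an intermediate rank that is not part of the schema at all (a
subphylum, say), which is what lets propagation disambiguate two records
that agree on every schema rank but diverge at an intermediate clade. The
cost, documented rather than hidden, is rank conflation: a class column may
carry a subphylum name. Species labels, when requested, are derived from
the free-text organism name by keeping its first two whitespace tokens
(`deriveSpeciesLabel()`), which strips strain qualifiers; infraspecific
markers in the second token ("sp.", "cf.") are kept verbatim, a caveat for
databases that use them heavily.

`buildNcbiTaxonomy()` ascends taxdump parent chains instead. Here
propagation fills a missing rank from the nearest *schema-assigned* higher
rank; unranked clades do not participate. The asymmetry with the SILVA
importer is intentional: SILVA paths are curated rank sequences where
intermediate names are meaningful fill values, whereas NCBI chains are
dense with `"no rank"` nodes (strains, clades) whose names would pollute
standard ranks. NCBI's `superkingdom` feeds the schema's `kingdom` via a
configurable alias map.

`parseTaxTree()` is built on `ape::read.tree()`. Taxonomy trees are chains
of singleton internal nodes, sometimes with a single tip, which phylo
parsers collapse or mis-root; the wrapper therefore parses the tree inside
an unlabeled super-root with a dummy sibling tip, which preserves every
labeled node's ancestor chain for any tree shape, and validates parenthesis
balance and the terminal semicolon up front.

# Sequence curation

`cullSeqs()` removes records whose longest homopolymer run exceeds 8 nt or
that carry more than 5 ambiguous (non-ACGT IUPAC) bases — both strict
inequalities, both measured after degapping. The defaults suit SSU rRNA
data; COI barcode data is commonly culled at a more permissive run length
of 12. `filterSeqsLength()` applies a global inclusive length window
(e.g. 250–1600 nt for COI); `filterSeqsLengthByTaxon()` attaches windows to
taxonomy labels, as in the SSU convention of dropping Archaea under 900 nt
and Bacteria under 1200 nt, with the most restrictive window winning when
several labels match. Labels match anywhere in the lineage by default
because the constrained names (Archaea, Bacteria) are unambiguous; a
rank-restricted option exists for label vocabularies that repeat across
ranks. `filterByAnnotationDepth()` keeps records informative at or below a
required rank, the standard strictness filter for databases with shallow
annotations. Every filter returns a `CurationReport` whose removal reasons
partition the removed set (first failing rule wins, homopolymer before
ambiguity) and which always satisfies kept + removed = input.

# Dereplication, clustering, consensus taxonomy

`dereplicateSeqs()` collapses identical sequences. Mode `uniq` preserves
identical sequences that carry different labels (one record per distinct
sequence/lineage pair); `lca`, `majority` and `super` keep one record per
distinct sequence and reconcile the member lineages with
`consensusLineage()`: the rank-wise longest common prefix; the most
frequent full lineage (ties resolved conservatively to the LCA of the tied
candidates); or a rank-by-rank top-down majority that stops at the first
tie. `clusterGreedy()` extends this to OTU clustering: records in
decreasing length order (ties by identifier) join the first centroid, in
centroid-creation order, whose global-alignment identity meets the
threshold, else found a new centroid. First-created-centroid tie-breaking
and the length-sorted processing order make the procedure deterministic.
Identity is matches over alignment columns excluding terminal gaps,
computed from a Needleman–Wunsch alignment at match +1, mismatch −1, gap
open −5, gap extend −2 — the conventions of the greedy clustering tools
this emulates; the scoring is exposed as parameters. The implementation is
all-pairs-to-centroids and O(n²); it is intended for database curation at
desk scale, not for clustering read sets.

# Information metrics

`shannonEntropy()` is the plain H = −Σ pᵢ ln pᵢ, reported in nats (a bits
option exists for display). `evaluateTaxonomy()` applies it per rank to
full lineage-prefix frequencies, so two identical genus names under
different families count as distinct labels; the cross-database comparison
`taxonomyOverlap()` deliberately uses the opposite convention — bare
rank-name tokens — because databases disagree on higher-rank placements,
and additionally collapses labels standing in a string-prefix relation
(`"Lactobacillus_A"` to `"Lactobacillus"`) across the union of the
compared databases before intersecting, so subclade suffixes do not
undercount shared taxa. Both conventions are documented and selectable.
`evaluateSeqs()` reports unique sequences, the length distribution,
sequence entropy over occurrence frequencies (a deduplicated richness-only
switch exists) and pooled forward-strand kmer entropy at k = 2, 4, 8, 16
by default; kmers containing ambiguous bases are skipped, and no
canonicalization is applied (forward strand only) since reference releases
are consistently oriented. `genusSpeciesConsistency()` counts records
whose species label's first token contradicts the genus label, a frequent
artifact of species labels lifted from source organism names.

# The classifier and the two evaluation regimes

The built-in classifier is a multinomial naive Bayes over kmer counts:
classes are the distinct full training lineages, per-class kmer
probabilities are additively smoothed pooled member counts
((c + α)/(Σc + α·4ᵏ)), priors are uniform. Defaults k = 7, α = 0.001,
confidence 0.7 mirror the conventions of the widely used amplicon naive
Bayes classifiers; all are parameters. Arithmetic is in log space with
log-sum-exp normalization. At reporting time the posteriors are aggregated
over the best class's lineage prefixes and the deepest prefix reaching the
confidence threshold is returned (the aggregated posterior is monotone
non-increasing in depth, so the reported depth is well defined); a query
confident at no rank is Unassigned.

Two regimes estimate the classification accuracy a database supports.
`evaluateFitClassifier()` trains and tests on the same records — the data
leakage is intentional and gives the best-case bound, since every query has
an exact reference match. `evaluateCrossValidate()` is the realistic
counterpart: records are split into k stratified folds (grouped by full
lineage, shuffled within groups under the seed, dealt round-robin with a
rotating starting fold so fold sizes stay balanced; groups smaller than k
simply appear in fewer folds). Within each fold the expected taxonomy is
truncated for taxonomic singletons: a test lineage absent from the training
fold cannot be recovered even in principle, so its expectation is the LCA
with its nearest training taxon, operationalized as the longest rank-wise
prefix shared with any training lineage — a pure taxonomy distance, the
minimal reading of "nearest"; no sequence distance is consulted. Truncation
applies whenever the full lineage is absent from a fold's training split,
which generalizes the singleton case to unlucky splits of small groups.

`evaluateClassifications()` scores expected versus observed per rank:
a true positive needs both sides informative with matching prefixes;
over-classification (observed deeper than expected) costs precision only,
under-classification recall only, misclassification both. Scores are
micro-averaged over the queries pooled across folds — a single confusion
tally, deterministic, rather than per-fold averages. No per-taxon (macro)
breakdown is attempted.

# The synthetic-data generator

`generateReferenceDb()` plants a database with known structure so every
stage is testable offline. Defaults: 2 phyla × 3 genera per phylum × 4
species per genus × 5 sequences per species, 300 nt — small enough that the
full pipeline (including O(n²) clustering and cross-validation) runs in
seconds, large enough that species, genus and phylum structure are all
present. Divergences are planted with disjoint substitution-position
blocks, and a substituted base always differs from the parent base, so
realized identities are exact rather than approximate: genus ancestors
differ pairwise by 0.20, species within a genus by 2 × 0.05, members from
their species ancestor by 1 − 0.99. Under these conditions the planted
species partition is exactly the clustering truth at 97% identity
(within-species pairwise identity ≥ 0.98, between-species ≤ ~0.93). Clean
sequences are post-processed to break any chance homopolymer run over
5 nt — a 300 nt i.i.d. sequence has a ~0.5% chance of a natural run over
8, which across a database would corrupt the planted filter truth — so the
injected defect lists (run of 9 at a chosen fraction of records, 6 N bases
at another fraction, ambiguous species labels at a third) are exact.
Injection fractions default to 0: the default database is clean, and tests
switch defects on explicitly. All randomness flows from one seed through
one RNG stream; outputs are byte-identical across reruns.

What the generator does *not* emulate: indels (substitution-only by
default, so gap-free identities are exact; an indel-free model also means
the aligner is exercised only lightly), chimeras, rate heterogeneity along
the sequence, and realistic phylogenetic branch-length distributions.
Passing tests therefore demonstrate the correctness of the machinery on
planted structure, not classifier performance on real SSU/ITS/COI data —
real databases are messier in exactly the ways the curation functions
exist to measure.

# Numerical and interface choices

- Entropy uses natural logarithms end to end; uniform n categories give
  ln n to floating-point accuracy (bitwise exactness is not attainable for
  all n).
- Greedy clustering recomputes identities against centroids only; an
  optional kmer prescreen was considered and rejected for the default path
  because it must provably not change results to be admissible.
- The taxonomy TSV dialect is fixed (header `Feature ID<TAB>Taxon`,
  fields joined by `"; "`) and written bit-exactly; a headerless lenient
  read exists. FASTA is wrapped at 80 columns; gzip is transparent on
  read and write. Reads normalize case and RNA `U` to `T` and validate
  the IUPAC alphabet, naming the first offending character and position.
- Classifier models serialize to a single versioned archive
  (`writeClassifier()`/`readClassifier()`); reloading is bit-stable.
- Every CLI subcommand writes a provenance JSON sidecar with the
  effective parameters, so any output can be traced to its configuration.

# Known limitations

Clustering is quadratic and single-threaded; imports hold the whole
taxonomy in memory; the classifier supports k ≤ 8 (the dense 4ᵏ count
matrix is the simple, fast representation at that size). Live retrieval
from SILVA/NCBI is out of scope: the importers consume local files in the
documented dialects. Nomenclatural validation of names against the
formal codes is not attempted.
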