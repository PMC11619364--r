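---
title: "Host prediction from CRISPR spacers: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host prediction from CRISPR spacers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacerhost)
```

## The inference

A CRISPR spacer is a 26–72 bp fragment of foreign DNA that a bacterium has
stored in its genome after an encounter with a plasmid, phage or other
mobile element. If a spacer from strain *S* matches a plasmid *P* exactly,
the lineage of *S* has met *P* (or a close relative carrying the same
protospacer), which makes *S* a *potential host* of *P*. Aggregating all
matching spacers per plasmid gives a predicted host set; the taxonomic
spread of that set estimates host range. The method deliberately keeps
*all* predicted hosts rather than picking a most-likely one — breadth is the
signal of interest, and alternative hosts are predictions, not noise.

Two artifacts must be handled before the inference is sound:

* **Self-hits.** A spacer whose source accession *is* the plasmid records a
  plasmid-borne CRISPR array, not an immunity event; such hits are removed
  (and counted) before any host is predicted.
* **IS elements.** Insertion sequences shared across unrelated replicons
  could let a spacer acquired from one element match a plasmid its host
  never met. The target-annotation module measures this risk by locating
  each hit within annotated features and classifying target genes;
  hits inside `mobile_element` features are flagged explicitly.

## Matching model

Matching is ungapped and full-spacer-length: a hit is a contiguous window of
the plasmid, on either strand, whose Hamming identity to the entire spacer
is at least the configured threshold (default 1.0, i.e. exact). We chose
full-length semantics deliberately — at "100% identity, no gaps" a
full-length exact match is the biologically meaningful protospacer event,
whereas partial high-scoring-pair semantics vary between alignment-tool
versions. `min_match_length` is accordingly a spacer-length floor (shorter
spacers are not searched), not a partial-match window. Sub-100% thresholds
(used in the 90/95/100% sensitivity sweep) allow `floor(w·(1−t))`
mismatches over the full width `w`.

Implementation: exact mode concatenates all plasmids with `N` runs (an `N`
never matches an `A/C/G/T` pattern) and runs one trusted-band Aho–Corasick
dictionary over all oriented spacers; mismatch mode scans each oriented
spacer with a fixed-length Hamming window. Both report 0-based half-open
coordinates on the forward strand, sorted by (plasmid, start, spacer,
strand) so outputs are byte-reproducible. Palindromic spacers would match
identically in both orientations; they are reported once, on `+`.
Ambiguity codes never match: spacers containing them are skipped at load
(with a counted warning), and `N` runs in plasmids cannot be hit.

Plasmids are scanned as deposited, i.e. linearly. Most plasmids are
circular molecules, so an optional `circular` mode appends the first
`w−1` bases to catch origin-spanning protospacers; it is off by default to
mirror how deposited FASTA is conventionally scanned.

### E-values

The hit filter needs a defined expectation model; we use the ungapped
Karlin–Altschul form

$$E = K \cdot m \cdot n \cdot e^{-\lambda S}, \qquad
  S = s_{\mathrm{match}}(w - d) - s_{\mathrm{mismatch}} d$$

with `m` the total plasmid-database length, `n` the spacer length, `d` the
mismatch count, and the published ungapped parameters for +1/−2 scoring
(`λ = 1.33`, `K = 0.621`) as defaults. The default cutoff is `1e-5`. All
parameters are configurable via `evalue_params()`; an empty database
(`m = 0`) yields `E = 0` by convention. For realistic database sizes any
full-length 26+ bp match passes easily — the filter matters for short
spacers and permissive identity thresholds, where it suppresses windows
whose score a practitioner would not trust.

## Concordance and host range

The seven-rank ladder `species < genus < family < order < class < phylum <
superkingdom` drives everything. Species names are normalized to their
first two whitespace-separated tokens, so strain suffixes collapse
("Escherichia coli K-12 MG1655" → "Escherichia coli"). Single-token names
pass through unchanged and "Candidatus X y" normalizes to "Candidatus X";
both are flagged low-confidence rather than rejected — passthrough is
non-destructive and the flag preserves auditability. A missing rank never
matches anything, including another missing rank: sparse lineages must not
fabricate concordance. A load-time validator reports taxonomies in which a
taxon sits under two parents.

Per plasmid, the *best-match rank* is the lowest rank at which the reported
host agrees with at least one predicted host; the concordance table
accumulates these counts up the ladder and expresses them against two
denominators (matched plasmids, all plasmids). Plasmids whose reported host
is "uncultured" can never be concordant; they are flagged so the
non-concordant tail can be decomposed into genuine mismatches versus
predictions for unknown hosts.

Host-range grades follow the six-grade scale of Redondo-Salvo et al.:
grade I when all predicted hosts differ at most at species level (including
singleton host sets), II when they span two or more genera within one
family, up to VI for two or more phyla. Two policies are worth stating:

* A host set that needs a rank missing from some lineage is *excluded with a
  logged reason* rather than graded — guessing would systematically inflate
  broad grades.
* Grading is monotone by construction: adding a host can never lower a
  grade, and duplicated hits change nothing because grading happens after
  consolidation to unique (plasmid, host) pairs.

Mobility stratification splits grade distributions by MOB+/MOB− labels
(supplied externally, e.g. from a relaxase typer). Over/under-representation
of a mobility class within a grade is tested with a two-sided Fisher exact
test; the choice is ours — an exact test is assumption-free at the small
cell counts the broad grades produce.

### Reporting conventions

Percentages are reported to one decimal, means to two. Quartiles use linear
interpolation between closest ranks (R's default type 7) and standard
deviations the population convention; both are fixed so that fixture tests
can assert exact equality.

## Target annotation

A hit is annotated with the feature that *fully contains* it — a hit
straddling a boundary is unannotated (the rule can be relaxed to
any-overlap). Nested features resolve to the shortest container, ties to
the lowest start. Feature tables use 1-based inclusive coordinates (GenBank
convention; GFF3 is also accepted) and are converted internally to 0-based
half-open with `start0 = start1 − 1`, `end0 = end1`.

Target genes are classified into five categories (function-unknown,
plasmid-backbone, potential-backbone, general-functional,
transposon-associated) by a keyword lexicon applied to product names,
replacing per-gene manual curation so the classification is deterministic
and reproducible. The default lexicon (shipped as
`inst/extdata/target_lexicon.tsv`, editable configuration rather than code)
covers conjugation/`tra`/`mob`, replication control/`rep`/`cop`,
partitioning/`par`, toxin–antitoxin, methylation/restriction,
transposase/integrase/IS and DUF/hypothetical/`nan` terms. Priority order
puts unknown-function first and transposon terms before backbone terms, so
"transposase" in an otherwise plasmid-flavored product string is never
misfiled; names matching nothing fall back to general-functional with a
`lexicon_miss` flag. `repeat` features with missing IDs are `nan`
placeholders and classify as unknown. A lexicon approximates manual
curation; the miss flag is the audit trail for names it does not know.

## Networks

The bipartite network has plasmid (or PTU) and family nodes, one edge per
predicted (plasmid, family) association, family nodes annotated with their
phylum. The pruning rule removes a family only when *both* conditions hold:
fewer than `min_plasmids` (default 10) connected plasmids *and* no plasmid
shared with another family. Pruning is applied in a single pass over the
initial graph — the rule describes a one-shot display filter — and the test
suite verifies it is idempotent. Plasmid nodes left without any family are
dropped from the rendered graph; whether to keep such orphans was an open
choice, and removal matches the filter's for-clarity intent. PTU collapsing
unions host families across the member plasmids of each PTU; plasmids
without a PTU assignment are simply absent from the PTU-level network.
Layout is out of scope: exports carry topology and node attributes only
(GraphML with `node_class`/`phylum` attributes, SIF with relation `hosts`,
plain edge TSV), with deterministic node and edge ordering.

## The synthetic fixture generator

The generator emulates the *structure* of a plasmid database with reported
hosts plus a strain-linked spacer database: a balanced taxonomy; strains
carrying 26–72 bp spacers; plasmid sequences containing exact planted
protospacer copies from designated host strains (on both strands, at
recorded coordinates); plasmid-borne self-spacers; decoy IS segments copied
verbatim across plasmids and annotated as `mobile_element` but never used
as spacer sources; feature products drawn from the categorization lexicon
so category recovery is exact by construction; MOB labels and a partial PTU
map. Everything is a pure function of the seed.

Design choices worth recording:

* **Background sequence is i.i.d. uniform over ACGT** and planted segments
  never overlap. This keeps the chance-collision probability of a ≥26 bp
  pattern analytically negligible (≈ `L·4^-26` per oriented pattern), so
  "predicted host set = planted host set" is a sharp expectation, not a
  statistical one.
* **Grade targets are realized at minimal taxonomic distance** (grade II =
  two genera in one family, III = two families in one order, ...), which
  makes the planted grade provably what `assign_grade()` computes from the
  planted lineages. Because grades IV and V need two orders within a class
  and two classes within a phylum, the taxonomy configuration carries
  explicit class and order multiplicities alongside the other rank counts.
* **Default scale**: 5 phyla × 2 classes × 2 orders × 5 families × 2 genera
  with one species and strain each = 200 strains × 10 spacers = 2,000
  spacers, targeted by 200 plasmids of 5–9 kb. The planted grade mix
  (119 I, 52 II, 12 III, 12 IV, 2 V, 3 VI) follows the narrow-skewed
  distribution reported for real plasmid collections, ~5% of plasmids carry
  a self-spacer, and five decoy IS segments each appear on three plasmids.
* **`mutation_rate`** applies per-base substitutions to planted protospacer
  copies (recording the realized mismatch count per copy) to drive the
  90/95/100% identity-threshold sweep, whose hit counts must fall
  monotonically as the threshold rises.

What the fixtures deliberately do *not* model: CRISPR array genetics
(repeats, PAMs, acquisition bias — the method never uses them), database
taxon bias, shared backbone homology between unrelated plasmids, and
sequencing error. Passing the recovery suites therefore demonstrates that
the machinery is correct — matching, consolidation, concordance, grading,
categorization, pruning — not that real-data accuracy will be 100%; on real
databases accuracy is bounded by CRISPR–Cas prevalence (reported in roughly
40% of bacteria) and by database bias toward well-studied taxa.

## Numerical and degenerate-input policy

* Empty plasmid sequences error; spacers with non-ACGT characters are
  skipped with a counted warning; an empty predicted host set is a caller
  error for `best_match_rank()`/`assign_grade()` (unmatched plasmids are
  simply absent).
* Windows extending past a sequence end are never hits (no partial
  windows); in circular mode the wrap is made explicit by sequence
  extension instead.
* A zero margin in the mobility enrichment table makes the test undefined;
  `p = 1` is returned with a warning rather than an error so batch
  summaries do not abort.
* All randomness (fixtures, tests) flows through explicit seeds; identical
  inputs give byte-identical hit tables and exports.

## Problem sizes used by the test suite

Unit tests run on 12–20 plasmid bundles (~2.5–4 kb plasmids, ~150 spacers)
and on hand-built sequences with planted matches; the oracle-equivalence
suites compare the matcher against a brute-force all-offset Hamming scan on
~40 kb of sequence; the end-to-end recovery and acceptance checks use the
full default bundle (200 plasmids, ~2,000 spacers) and a smaller mutated
bundle for the identity sweep. These sizes keep a complete run fast while
still exercising every code path at the default configuration.

## Known limitations

* Name-string taxonomy: lineages are compared as given; synonymous or
  renamed taxa are not resolved, and dirty taxonomies are reported, not
  repaired.
* The lexicon approximates manual curation of target-gene categories;
  `lexicon_miss` flags its blind spots.
* No probabilistic host scoring or most-likely-host ranking — every
  predicted host is reported with equal standing; scoring is a natural
  extension but out of scope here.
* The E-value model is a stand-in for whatever expectation model produced a
  given external hit list; when reproducing someone else's filtering,
  match their parameters via `evalue_params()`.
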