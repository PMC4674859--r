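---
title: "Building gene-pathway interaction networks from text-mined events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building gene-pathway interaction networks from text-mined events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathevents)
```

## The problem

Biomedical event extractors of the GENIA tradition recognise typed events
(gene expression, transcription, protein catabolism, phosphorylation,
localization, binding, and the three regulation types) whose arguments are
gene/protein mentions — or, recursively, other events. Pathways, however,
are also named in text as actors: a pathway can activate a gene, a gene
product can inhibit a pathway, two pathways can regulate one another. A
gene-only extractor either ignores such statements or degrades them into
spurious gene–gene relations by picking up the gene name embedded in the
pathway name.

`pathevents` treats pathway mentions as first-class event participants
without retraining the extractor. The trick is entirely at the annotation
level: pathway mentions are *disguised* with the `Protein` entity type the
extractor expects, events are extracted as usual, and a sidecar then
*undisguises* the pathway participants. Downstream, every event becomes
zero or more undirected interaction pairs, and the pairs plus curated
pathway membership yield a gene–pathway multigraph.

## Pathway recognition

Production pathway NER systems combine soft dictionary matching with
hand-written rules. The package provides a transparent, tunable stand-in
with two detectors:

* **Soft matching** (`soft_match()`): every token window of the document is
  normalized — lowercased, split on all punctuation including `/` and `-`,
  with *head terms* removed — and scored against every dictionary synonym by
  token-set Jaccard similarity. Windows scoring at or above
  `similarity_threshold` become candidates; overlaps resolve longest-first,
  ties to the smaller start offset, so pathway mentions never overlap.
* **Rule detection** (`rule_detect()`): every occurrence of a head term
  (*pathway*, *signaling*, *signalling*, *cascade*, *signal transduction* by
  default) is extended leftwards over up to `max_entity_tokens` contiguous
  entity-like tokens — tokens carrying capitals, digits, Greek letters, or
  hyphen/slash compounds (`Wnt/β-catenin`). A head term with no entity-like
  context is dropped, which keeps generic phrases like "a signaling event"
  out.

Parameters and defaults:

| parameter | default | meaning |
|---|---|---|
| `similarity_threshold` | 0.8 | minimum Jaccard between normalized token sets; 1.0 degenerates to exact normalized matching |
| `head_terms` | pathway(s), signaling, signalling, cascade, signal transduction | generic tokens stripped before scoring and used as rule anchors |
| `max_entity_tokens` | 5 | longest specific (non-head) token run in a candidate |

The 0.8 default accepts one token of disagreement on most multi-token
dictionary names while rejecting unrelated spans; it is deliberately
conservative because downstream normalization re-scores surfaces anyway.
At threshold 1.0 the matcher provably coincides with exact
normalized-string matching, which is how the test suite pins its
behaviour to a brute-force oracle.

## Overlap merging

Gene names nest inside pathway names, so gene and pathway annotations over
the same text frequently overlap. Any set of mentions connected by
pairwise overlap (sharing at least one character — touching boundaries do
not count) collapses transitively into a single mention spanning the
interval union; the merged mention is a pathway if any member was. The
specification for this step only addresses gene-inside-pathway absorption,
but the output must be overlap-free, so the package also collapses
all-gene overlap components into one gene mention — without this the
disguise step, which requires disjoint spans, could not accept arbitrary
recognizer output. Merging is idempotent and insensitive to input order,
and no text position covered by an input mention is ever lost.

## Normalization and event filtering

* Gene mentions normalize by **exact case-folded lookup** in the gene
  lexicon. No fuzzy gene matching is attempted: surfaces absent from the
  lexicon are treated as recognizer false positives, and fuzzy matching
  would convert those false positives into wrong identifiers rather than
  removing them.
* Pathway mentions normalize against the pathway dictionary with the same
  token-set similarity used for recognition; the best-scoring synonym at or
  above the threshold wins. Records sharing a canonical id (the same
  pathway curated by several source databases) are unioned — synonyms and
  member genes alike — at load time. Score ties break to the
  lexicographically smallest canonical id, purely for determinism.
* An event is **discarded whole** if any mention in its recursive argument
  closure fails to normalize; there is no partial salvage, because a pair
  emitted from a half-normalized event would assert an interaction the text
  does not support. The discard log records each dropped event with its
  first offending surface.
* Pathways are only admissible in regulation-typed events. The validity
  check is recursive: every event node whose subtree contains a pathway —
  the event itself and any nested sub-event — must be one of
  `Regulation`, `Positive_regulation`, `Negative_regulation`. A binding
  over a pathway nested under a regulation is therefore still invalid.

## From events to pairs

Nested arguments expand recursively: a mention is itself; an event is the
union of the expansions of its themes and cause. Then:

* regulation with a cause: all cross-product pairs of cause-side and
  theme-side participants, self-pairs removed, category from the event
  type. The cross product is the maximal faithful reading when a side
  expands to several entities; in the common one-theme/one-cause case it
  reduces to the single ⟨Cause, Theme⟩ pair.
* regulation without a cause: nothing (there is no interaction partner).
* binding with *n* ≥ 2 distinct themes: all *n*(*n* − 1)/2 theme pairs;
  duplicate themes are collapsed first, so a degenerate self-binding emits
  nothing.
* all other event types: nothing — they matter only as nested arguments.

Pairs are undirected (event directionality is deliberately ignored) and
deduplicate corpus-wide on the unordered node pair **plus category**;
whether the published uniqueness convention included the category is
unstated, so the package includes it — collapsing across categories would
conflate a positive and a negative regulation of the same pair — and the
key is explicit in `extract_unique_pairs()` so the alternative is one
`dplyr::distinct()` away. Provenance (`doc_id`, `event_id` sets) merges
across duplicates.

Node keys live in two namespaces that cannot collide: genes are bare
Entrez integers, pathways carry a `PW:` prefix. The same labels appear in
SIF exports.

## Network and topology

The network is a **multigraph**: a text-mined edge and a curated
`member_of` edge between the same endpoints coexist, which is exactly what
makes "multi-edge node pairs" a meaningful statistic. Conventions, chosen
to match Cytoscape's NetworkAnalyzer since those are the conventions the
field reports under:

* path-based statistics (components, diameter, characteristic path length,
  clustering) use the simplified projection with parallel edges collapsed;
* the mean clustering coefficient averages `2e/(k(k−1))` over **all**
  nodes, with nodes of fewer than two neighbours contributing 0;
* diameter and characteristic path length are taken over connected
  unordered pairs, ignoring disconnected pairs rather than treating them
  as infinite — finite values remain defined on multi-component networks;
* density is the mean distinct-neighbour count divided by *n* − 1;
* on an edgeless network the path statistics are `NA` rather than 0 — they
  are undefined, not zero.

Hubs rank by degree **with multiplicity** (a curated membership adds to a
pathway's hub score, as it should: the pathway really is attached to that
gene). Bottlenecks rank by unnormalized shortest-path betweenness with
fractional credit for tied geodesics, computed on the simplified graph.
Published bottleneck scores in this domain often come from plugin-specific
variants of the metric; this package implements the textbook definition
the prose of those reports states, and promises ranking semantics, not
score parity with any particular plugin. All tie-breaks are by node key,
ascending.

igraph supplies the graph algorithms; the test suite checks every
statistic and the betweenness scores against independent brute-force
oracles (Floyd–Warshall distances, geodesic counting by adjacency powers,
direct triangle counts) on hundreds of random graphs of up to 8 nodes.

## Evaluation

`precision()` is `TP/(TP+FP)` over a sample of reported pathway events.
Genuine recall over the space of all possible events is unattainable —
true pathway events are far too sparse for random sampling — so the
package implements **pseudo-recall**, `TP/(TP+FN)` over a candidate set of
same-document ⟨pathway, gene⟩ mention pairs lying within a character
distance threshold (default 100, an empirically motivated figure).
Conventions the original description leaves open, fixed here once:

* distance is the number of characters strictly between the nearer span
  boundaries — 0 for adjacent or overlapping spans — and the threshold is
  strict (`< 100`);
* sampling enumerates all qualifying pairs deterministically, then draws
  without replacement under a caller-supplied seed, leaving the global RNG
  state untouched; if fewer pairs qualify than requested, all are returned
  with a warning;
* event equivalence for scoring requires the same document, the same event
  type, and identical normalized participant sets per role after nested
  expansion;
* F1 is computed from unrounded precision and recall; only display
  rounding produces whole percentages.

## The synthetic corpus generator

`generate_corpus()` emulates a literature corpus at the annotation level:
templated sentences ("X activates Y", "Downregulation of X inhibits Y",
"X interacts with Y and Z", "X is phosphorylated") with exactly controlled
character offsets, standoff annotations, a gene lexicon, and a multi-source
pathway dictionary. The default study conditions, chosen once as a
plausible miniature of an abstract corpus and used throughout the
package's own validation: 100 documents, Poisson(3) event sentences per
document, 40 genes, 8 pathways (each with two source-database synonym
variants and 3–8 member genes), 30% of regulation events nested, 20%
binding events (2 or 3 themes), a 35% chance per regulation endpoint of
being a pathway, and 10% phosphorylation noise sentences that exercise the
event-type filter without producing pairs.

Unmappability is planted per event tree: with probability
`unmappable_fraction` one participant's surface is swapped for an
out-of-lexicon form. In nested sentences the swap targets the sub-event
theme, so the whole tree (sub-event and parent) becomes unmappable and the
expected fraction of discarded event rows equals `unmappable_fraction`
exactly — this is the analytic expectation the stochastic acceptance check
compares against, at a ±0.05 tolerance over ten seeds.

What the generator does **not** emulate: realistic English syntax,
recognizer error profiles (boundary errors, wrong argument attachment,
trigger confusion), discontinuous or abbreviated mentions, species
ambiguity, or document-level redundancy of the same assertion. Passing the
recovery tests therefore demonstrates that the pipeline's mechanics —
parsing, merging, disguise round-trip, normalization, expansion,
deduplication, network assembly — are faithful; it says nothing about NER
or extractor quality on real text, which the package intentionally
consumes as given.

`expected_network()` re-derives the network from the planted truth with
deliberately naive nested loops and serves as the second implementation in
dual-route tests of the network builder.

## Numerical and engineering choices

* Offsets are 0-based, half-open, in characters (not bytes) throughout, so
  multi-byte symbols like β count as one position.
* Standoff, SIF and table writers are deterministic (sorted output);
  identical inputs give byte-identical files, and `read ∘ write` is the
  identity on the in-memory model for all formats — properties the suite
  checks on hundreds of random instances.
* The `.a1` reader accepts `Protein` (extractor-facing) and `Pathway`
  (internal) entity types; unknown types are preserved but flagged with a
  warning. Span/surface mismatches are always an error naming the line,
  never silently repaired.
* Duplicate gene lexicon rows are tolerated; conflicting mappings for the
  same case-folded surface are a hard load error. Silent last-wins would
  make network content depend on file row order.
* Per-document processing is independent; with `workers > 1` documents are
  processed in parallel and results are combined in sorted `doc_id` order,
  so outputs are identical for any worker count.
* The event extractor is pluggable (`extractor` hook or pre-existing `.a2`
  files); the package never bundles one. The GENIA GE 2011 argument
  inventory is assumed for `.a2` parsing, with site/location arguments
  preserved but excluded from pairing.
* Problem sizes in the validation suite — 100-document corpora, ten-seed
  replicates, 200 random graphs of ≤ 8 nodes for the topology oracles, 500
  random round-trip instances — were chosen so the oracle checks stay
  exhaustive at small scale while the whole suite runs in about a minute
  and a half.

## Known limitations

* Pathway matching quality is bounded by the dictionary: no learned NER,
  no reproduction of published F1 figures for dedicated pathway NER
  systems, whose corpora and exact algorithms are external to this
  package.
* Gene normalization is lookup-only: no species disambiguation, no
  gene-family resolution, no fuzzy rescue of near-miss surfaces.
* Event polarity, speculation and negation are ignored; a "does not
  activate" statement still yields a positive-regulation pair if the
  extractor reports one.
* Directionality is discarded by design, so the network cannot distinguish
  regulator from regulated.
* Betweenness scores follow the standard definition and need not equal
  plugin-specific bottleneck scores; rankings are comparable, magnitudes
  may not be.
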