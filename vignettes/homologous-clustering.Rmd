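---
title: "Homologous clustering by similarity graphs, Louvain communities, and sub-cluster merging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homologous clustering by similarity graphs, Louvain communities, and sub-cluster merging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homoclust)
```

## The problem

Protein annotations in public repositories are mostly transferred
computationally rather than verified experimentally, so errors propagate:
a mislabelled sequence becomes the template for the next hundred
annotations. One practical aid is to group large protein collections into
*homologous clusters* — sets of sequences inferred to share ancestry — so
that a scientist annotating a new sequence can inspect the whole cluster
it matches, see which members carry experimentally validated annotations,
and judge the consensus rather than trusting a single best BLAST hit.

`homoclust` implements that clustering engine at desk scale: pairwise
semi-global alignment statistics define a similarity graph over the
sequences, Louvain modularity optimization partitions the graph into
communities, an iterative batch scheme keeps the memory footprint of very
large inputs bounded, and a merging pass resolves the batched results into
final clusters. Around the engine sit a flat-file membership store with
best-match queries, k-mer-distance sequence similarity networks (SSNs) for
fine-grained annotation decisions, and a synthetic-data generator with
planted families so that every stage is testable without any download.

## The similarity graph

Every candidate pair of sequences is aligned **semi-globally**: a global
alignment in which gaps at either end of either sequence are free. This
suits pairs whose lengths differ substantially (a domain against a
multi-domain protein) and overlapping fragments, since terminal overhangs
are not penalized. Internal gaps are affine: a gap of length $L$ costs
$g_o + L \cdot g_e$.

Three statistics summarize each alignment:

1. **length ratio** — alignment length over the length of the longer
   sequence, where "alignment length" counts the columns between the
   first and last column pairing two residues (overhangs excluded,
   internal gaps included);
2. **match ratio** — exact matches over alignment length;
3. **score ratio** — alignment score over the smaller self score
   (the self score of a sequence is the sum of diagonal substitution
   matrix entries over its residues).

The graph has the sequences as vertices and an edge wherever statistic 1
strictly exceeds a threshold, 0.8 by default; statistic 1 is also the edge
weight. Statistics 2 and 3 are retained on the edge table but play no role
downstream.

```{r}
stats <- align_stats("ACDEFG", "CDEF")
stats
```

The contained sequence aligns over 4 of the 6 columns of the longer one
(`len_ratio` 2/3) with every column identical and a score equal to its
self score.

### Numerical choices

* **Substitution matrix and gap penalties.** BLOSUM62 (bundled in NCBI
  text format) with gap open 11 and gap extend 2, all configurable. The
  extension penalty deliberately sits above the common BLAST default of 1:
  because the package aligns arbitrary candidate pairs rather than only
  pre-screened high-identity pairs, a cheap extension lets two *unrelated*
  sequences chain short lucky segments with long gaps into an alignment of
  barely positive score spanning most of their length. Such mosaic
  alignments inflate the length ratio past the 0.8 threshold (and can push
  it beyond 1, since internal gap columns count toward the span) while
  meaning nothing biologically. With $g_e = 2$ the mosaic costs more than
  the short terminal-overlap optimum and the statistic stays
  discriminative; genuine homolog alignments, whose internal gaps are
  short, are essentially unchanged.
* **Candidate pairs.** By default a pair is aligned only if the two
  sequences share at least one exact 6-mer (`prefilter_k = 6`), the
  word-based candidate generation that large-scale alignment engines use.
  Homologous pairs above any plausible identity level share many exact
  6-mers, so the rule costs no genuine edges in practice, while the joint
  probability that an unrelated pair both shares a 6-mer and produces a
  spurious over-threshold alignment is of order $10^{-7}$. Pairs where
  either sequence is shorter than 30 residues are always aligned (short
  sequences can lose all shared words to a single substitution), and
  `prefilter_k = 0` forces literal all-pairs evaluation.
* **Tie-breaks.** The dynamic program and traceback are deterministic:
  diagonal over up over left within a cell, and among equally scoring end
  cells the one nearest the corner. Because co-optimal alignments of a
  pair can differ in their aligned region, `align_stats()` canonicalizes
  the argument order (longer sequence first, ties lexicographic) so that
  all three statistics are exactly invariant under argument swap.
* **Self-score denominator.** The smaller of the two self scores, which
  keeps the score ratio at most 1 for positive-diagonal matrices.

## Louvain community detection

Communities of the similarity graph are found by the Louvain method:
greedy maximization of weighted **modularity**

$$Q = \sum_c \left[ \frac{w_{in}(c)}{m} - \left(\frac{d(c)}{2m}\right)^2 \right],$$

the fraction of edge weight inside communities minus its expectation under
degree-preserving random rewiring. Phase 1 scans vertices in ascending
input order and moves each to the neighbouring community with the largest
strictly positive modularity gain (smallest community index on ties; a
vertex stays put when tied with its current community). Phase 2 aggregates
communities into a meta-graph and the phases repeat. Optimization stops
when a full level improves $Q$ by less than $10^{-6}$, a threshold
balancing convergence speed against partition quality. The implementation
is sequential and fully deterministic — given the same graph it always
returns the same partition — which trades away the parallel speedups of
production community-detection codes for exact reproducibility at desk
scale.

```{r}
tri2 <- sim_graph(letters[1:6], data.frame(
  from = c("a", "a", "b", "d", "d", "e"),
  to   = c("b", "c", "c", "e", "f", "f"), weight = 1))
louvain(tri2)
```

Louvain is a heuristic for an NP-complete problem; it does not attain the
global modularity maximum on every graph. The test suite checks it
against exhaustive enumeration over all set partitions on a fixture suite
of small graphs (disjoint cliques, a 5-path, a barbell, two triangles, a
star) where the deterministic scan provably reaches the optimum, and
separately documents the classic counterexample — on a 6-path the greedy
scan settles at $Q = 0.26$ against the true maximum $0.30$, exactly as
randomized reference implementations do for about half their scan orders.

## Iterative batch clustering and sub-cluster merging

Clustering millions of sequences in one batch is infeasible, so the
engine works iteratively. Iteration 1 splits the input into batches and
clusters each independently; the resulting communities are *sub-clusters*
(size ≥ 2) and *singletons*. For the next iteration each sub-cluster is
replaced by its **representative** — its first sequence in within-batch
order, a choice that makes the final back-mapping fast — and
representatives plus singletons from scheduled groups of batches are
combined into new, much smaller batches. The last iteration clusters a
single batch. A schedule (YAML/JSON or `iteration_schedule()`) states
which batch outputs combine at each iteration; unconsumed outputs carry
forward unchanged. Sequences are identified throughout by labels such as
`A_11#a_15` (sequence 15 of batch A lies in its sub-cluster 11) and
`Sa_1#a_1` (sequence 1 of batch A is a singleton), 0-based, with batch
letters extending `A…Z, AA, AB, …` beyond 26 batches.

**Merging** then resolves the final iteration's communities back to the
original sequences: a singleton stands for whatever it stood for when it
was produced, and a representative stands for the union of the expansions
of its sub-cluster's members. Sub-clusters whose representative never
clustered again still merge — sequences grouped at an earlier level stay
together. The result is an exact partition of the filtered input into
final clusters and singletons:

```{r}
merge_all(example_trace())
```

Two details are easy to get wrong and are pinned down by tests:

* **Cross-batch duplicates.** Per-batch filtering removes exact duplicate
  residue strings (and sequences annotated as hypothetical proteins, a
  case-insensitive substring test) before clustering, but identical
  sequences in *different* batches only meet when batches combine. They
  are deduplicated there by default; because a removed duplicate may
  itself represent an earlier sub-cluster, the removal is recorded as an
  alias and the removed sequence's lineage merges into the kept
  sequence's cluster, preserving the partition invariant. Indices are
  frozen before any dedup, so representative selection never shifts.
* **Equivalence with direct clustering.** When the planted families of a
  dataset are separable — within-family length ratios above the
  threshold, between-family at or below it — the iterative result is
  identical to clustering everything as a single batch, whatever the
  batch split. The acceptance suite verifies this exactly, along with
  recovery of the planted truth.

## Queries and sequence similarity networks

`build_db()` persists cluster membership — identification number,
accession, annotation, cluster id, validation flag — as a plain TSV table
plus FASTA in a directory; `load_db()` restores it losslessly. A query
(`best_match()`, or `predict()` on a fit) aligns the query against every
stored sequence, ranks by alignment score (ties: higher length ratio,
then accession), and returns the best hit's whole cluster with all FASTA
headers, provided the best hit's length ratio reaches a floor of 0.5
(configurable; below it the query is unsuccessful). Validation flags
start at 0 and `mark_validated()` flips a flag to 1 idempotently — the
hook through which curated experimental evidence enters the store.

For annotation decisions within a cluster, an SSN gives finer resolution:
the user selects at least two cluster members, and a complete weighted
graph over query plus selection is built with **k-mer distances**

$$d(a, b) = 1 - \frac{\sum_w \min(c_a(w), c_b(w))}{\min(|a|, |b|) - k + 1},$$

the alignment-free distance over shared k-length words (default $k = 3$)
used to build guide distance matrices from unaligned sequences. A
distance of 0 means the sequences are identical; distances are reported
to six decimals. The k-mer distance is symmetric with zero diagonal but
is *not* a metric (no triangle inequality is claimed), and $d = 0$ does
not imply identity in general — only the converse direction is
guaranteed. Matrices export in PHYLIP square format and networks as
GraphML or TSV edge lists.

## The synthetic-data generator

`make_family()` plants a homologous family: one random seed sequence
(uniform over the 20 standard residues), descendants generated by i.i.d.
per-site substitution (uniform over the 19 alternatives) and per-site
indels of length $1 + \mathrm{Geom}(0.5)$, insertion or deletion with
equal probability. `make_dataset()` adds length-matched random decoys (so
that the length-ratio statistic, not mere length, must separate them),
exact duplicates, and hypothetical-protein records, then shuffles
deterministically and returns truth labels. Defaults — 5 members per
family, seed length 120, substitution rate 0.05, indel rate 0.01 — keep
within-family length ratios comfortably above the 0.8 threshold
(expected pairwise identity $\approx 0.90$) while unrelated pairs stay
far below it; rates up to 0.15 substitutions and 0.02 indels per site
remain separable. Everything is reproducible from integer seeds and
leaves the caller's RNG stream untouched.

What the generator does *not* emulate: phylogenetic rate heterogeneity,
domain shuffling and partial homology, compositional bias, and the
remote-homology regime (20–30% identity) where real clusters live. A
green test suite on planted families therefore demonstrates the
correctness of the machinery — graph construction, community detection,
batching, merging, bookkeeping — not the biological recall of the 80%
threshold on hard real data, which the production-scale experiments that
motivated this design addressed separately.

## Problem sizes and limitations

The package targets desk scale deliberately: all-pairs graph construction
is quadratic, and the test and acceptance workloads use datasets of
around 50–60 sequences of length ~120 (a few thousand alignments,
seconds of compute), fixture graphs of at most 8 vertices for exhaustive
modularity enumeration (Bell(8) = 4140 partitions), and brute-force
alignment oracles up to length 6 over a 4-letter alphabet. Known
limitations: Louvain's greedy suboptimality on adversarial graphs (see
above); the length-ratio statistic can exceed 1 for pathological
gap-inflated alignments (excluded by the default scoring but possible
under user-supplied penalties); the membership store is a flat file, not
a concurrent database server; and no attempt is made to reproduce
production-scale cluster counts, which depend on a full repository
download.
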