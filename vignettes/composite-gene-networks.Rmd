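---
title: "Detecting composite genes in sequence similarity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting composite genes in sequence similarity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicnet)
```

## The problem

Composite (mosaic) genes combine genetic segments traceable to two or more
unrelated gene families, the outcome of gene fusion or, symmetrically, of
fission of an ancestral gene. In fast-evolving, recombinogenic gene pools —
viral genomes being the canonical example — such remodeling happens outside
any single gene family, so family-by-family phylogenetics cannot see it. A
sequence similarity network (SSN) can: nodes are protein sequences, and an
edge joins two sequences whenever an all-against-all local alignment search
returns a hit below an E-value threshold. A composite gene then leaves a
characteristic footprint, bridging otherwise unconnected families.

`mosaicnet` implements that analysis as a tested pipeline: inclusive network
construction from a BLAST-style tabular hit file, composite and
multicomposite calling by non-transitive triplet mining, a conservative
"safest" refinement, the network statistics used to characterise remodeling
(first-pass Louvain communities, community-supergraph cycles, class
assortativity, betweenness contrasts), functional-category enrichment, and a
ground-truth simulator that makes every stage testable without external
data.

## Network construction

Pairs of sequences are joined when at least one directed hit has
`E < 1e-5`; the comparison is *strict*, so a hit at exactly the threshold
does not create an edge. The hit table is symmetrized and parallel edges are
reduced by keeping the hit with the smallest E-value; because the input may
list several HSPs per pair in either orientation, ties are broken
deterministically (higher bitscore, then the direction whose query id sorts
first). Each retained edge keeps the hit's alignment interval *on both
endpoints*, in each endpoint's own 1-based inclusive coordinates — these
intervals are what the triplet conditions consume. All sequences remain as
nodes, so both data-set-wide and network-wide fractions are computable;
singletons are reported separately from components of two or more sequences.

## The three triplet conditions

A candidate `b` is called composite when some pair of its neighbors
`a`, `c` forms a triplet passing all of:

1. **Non-transitivity** — no `a`–`c` edge exists at the build threshold
   (`1e-5`). Homologs of a single family produce triangles and are never
   called.
2. **Non-overlap** — the retained hits of `b`–`a` and `b`–`c` on `b`'s own
   coordinates overlap by at most `w = 20` amino acids. Local aligners
   slightly extend hits past the homologous region; the tolerance absorbs
   that. The overlap is computed as
   `max(0, min(e_a, e_c) - max(s_a, s_c) + 1)`.
3. **Stringency** — both candidate edges have `E < 1e-10`, well above the
   twilight zone, so no similarity however weak links the two components.
   Without this condition, chains of diverging homologs aligned over
   different regions would masquerade as fusions.

Multicomposite genes — fusions whose components are themselves composite —
are found by re-running the same three conditions on the subgraph induced by
the composite calls, with non-transitivity judged inside that subgraph.
No attempt is made to distinguish fusion from fission; both leave the same
footprint, with the roles of center and components exchanged.

### Enumeration and the triplet funnel

Candidate triplets are enumerated per candidate node over pairs of its
neighbors; the cube of all node triples is never materialized. With
`funnel = TRUE` (the default) all neighbor pairs are visited and the exact
count surviving each condition — total, non-transitive, overlap-passing,
stringent — is reported in that order. With `funnel = FALSE` only pairs of
stringent neighbors are visited: the calls are provably identical (any
passing triplet has two stringent edges), the work drops roughly with the
square of the stringent degree fraction, and the two intermediate funnel
stages are reported as `NA` because counting them requires the non-stringent
pairs. The overlap condition uses the single retained best hit per edge;
when an aligner reports several HSPs per pair, the choice of HSP is the
best-E-value one by construction.

Stored evidence is capped (50 triplets per call by default) while
`n_supporting_triplets` stays exact; any consumer that needs complete
evidence (the safest filters) recomputes it from the network.

## The safest subset

Three additional conditions guard against annotation artifacts:

1. Triplets in which a component comes from the *same genome* as the
   candidate and is covered by the retained hit over at least 95% of its
   length are discarded (overlapping-gene annotations); calls that lose all
   their support are dropped. "Embedded" is operationalized as sequence
   containment — the data model is protein-only, so genomic gene coordinates
   are unavailable; the coverage fraction is an exposed parameter.
2. Calls found in exactly one surviving triplet whose two components come
   from a single genome are dropped (genes split during that genome's
   annotation). The count is taken on triplets surviving filter 1; two
   single-genome triplets do *not* trigger the rule, which reads
   "exclusively one".
3. Calls all of whose network neighbors share the call's genome are dropped
   (genes fused during annotation; no external homolog anywhere).

Multicomposites are then recomputed on the subgraph induced by the safest
composites. With these definitions the filters are idempotent and the final
set does not depend on the application order, except that filter 2 counts
triplets surviving filter 1 — the narrative order is therefore fixed.

## Network statistics

* **Communities** are the *first pass* of the Louvain algorithm only: the
  local-moving phase from singleton communities, sweeping nodes in a
  seed-shuffled order and applying the best positive modularity gain (ties
  to the smallest community id) until a full sweep makes no move. No
  hierarchical aggregation is performed; the point is to pool densely
  connected homologs, not to coarsen maximally. Edges are unweighted. An
  edgeless (but non-empty) network yields the all-singleton partition with
  modularity 0 by convention.
* The **community supergraph** has one node per community and one edge per
  community pair, weighted by the inter-community edge count (the
  `1 + log(count)` display width is exported as an attribute only). An edge
  is flagged `in_cycle` iff it is not a bridge — equivalently, iff it lies
  in the union of any cycle basis. Divergence alone produces trees and
  chains of communities; cycles between communities are the network-level
  diagnostic of gene remodeling.
* **Assortativity** is Newman's categorical coefficient over the
  edge-endpoint mixing matrix, each undirected edge counted in both
  orientations. Per-class values use the standard binary-indicator
  construction (class vs rest), the usual way to obtain one coefficient per
  class from a categorical labeling. Edges touching unlabeled nodes are
  excluded by default. When every labeled edge joins nodes of one single
  label the coefficient is undefined (zero denominator) and the function
  says so explicitly rather than returning 1.
* **Betweenness** is normalized shortest-path betweenness with endpoints
  excluded (`2 / ((n-1)(n-2))` for undirected graphs). The approximate mode
  is the random-pivot estimator — single-source dependency accumulation
  from `k` uniformly sampled pivots, rescaled by `n/k`. Pivots are sampled
  *without replacement*, so `k = n` reproduces the exact values bit for bit,
  and the estimator is unbiased for `k < n`. The pipeline uses exact
  betweenness up to 2000 nodes and `k = 5000` pivots beyond; both modes are
  available at any size. Composite calls are summarised by the ratio of
  group mean centralities, reported to one decimal and as the nearest
  integer.

## Enrichment

Functional categories are the 25 one-letter COG/KOG classes. Composition
plots redistribute multi-category genes evenly (`1/m` per category);
count-based testing uses full membership. For each category a two-sided
Fisher exact test compares the category against the combination of all
others between two disjoint gene sets; when the natural comparison is
subset-vs-superset (composites against the whole data set) the complement is
used as the second set so the 2x2 table stays well-defined. The two-sided p
sums hypergeometric probabilities not exceeding the observed table's (with
the customary `1 + 1e-7` tie tolerance). Family-wise control is Bonferroni
at `alpha / m` computed exactly — for 25 categories at `alpha = 0.05` the
per-test threshold is 0.002; an explicit `per_test_alpha` override is
available for reproducing analyses that used a different cut.

## The simulator

`synthetic_config()` fixes the study conditions; the defaults are 30 root
families of 200-500 aa with 10 members each at substitution divergence
`d = 0.15`, indel rate 0.01/site (geometric lengths, mean 2), 20 planted
composites, 5 multicomposites, fusion fractions drawn from (0.6, 0.9),
50 genomes assigned round-robin, no noise hits, seed 42.

Design choices that matter:

* **Truth-derived hits instead of an aligner.** Every pair sharing ancestry
  on a common family-root interval receives one hit whose coordinates are
  the exactly mapped shared intervals and whose score follows a simple
  Karlin–Altschul-shaped surrogate: `S = 2 * Lseg * (1 - 2 * d_pair)`
  clamped at zero, `E = min(1, m * n * 2^-S)`. `d_pair` is the *realized*
  mismatch fraction computed from the residues, not an expectation. The
  model only needs to be monotone in shared length and divergence. Rare
  indels inside a shared interval are bridged into a single hit, as a
  gapped local alignment would; splitting at indels would fragment hits
  into sub-threshold pieces and manufacture spurious non-transitive
  patterns that no aligner would produce.
* **Fusion fractions of 0.6-0.9.** Real fusion proteins typically retain
  most of each partner, and the lower bound has a structural consequence:
  any two composites reusing the same family share at least 20% of its root,
  which guarantees either a direct edge between them (making
  member-centered triplets transitive) or an overlap far above 20 aa on the
  shared member. Family reuse therefore cannot generate component-level
  false positives, and planted composites with segments of at least 100 aa
  always acquire stringent edges into both parent families while the
  parents stay unconnected — the detectable fusion footprint by
  construction.
* **Multicomposite construction.** The prefix part taken from the first
  parent composite always covers that parent's junction, and the suffix
  part covers the second parent's junction, so every multicomposite traces
  to four root families (at least three is the defining requirement) on
  every draw, not merely in expectation. Parent composites are built over
  disjoint family pairs reserved up front; if the family pool cannot supply
  them the generator refuses and says to raise `n_families`.
* **No noise hits by default.** At `E < 1e-5` false hits between unrelated
  proteins are not expected in real searches; tests switch
  `noise_hit_rate` on explicitly to exercise the threshold boundary
  (noise E-values are drawn uniformly from `[1e-6, 1e-5)`).
* **Determinism.** All randomness derives from the configured seed;
  identical configurations produce byte-identical sequences, truth tables
  and hit files.

What the simulator does *not* emulate: realistic substitution matrices and
rate heterogeneity, genome structure (gene order, overlapping genes),
domain-level architecture, and the long tail of weak homology that a real
aligner produces around the twilight zone. Passing the recovery suite
therefore shows the pipeline is correct on data whose signal structure
matches its assumptions; it does not certify recall on real proteomes,
where divergence beyond recognition and short hits at low E-values (the
conservative bias measured by the hit-length/E-value correlation
diagnostics) reduce sensitivity.

## Numerical choices and degenerate inputs

* Thresholds compare strictly (`<`); boundary E-values never qualify.
* Tie-breaks in edge reduction and community moves are fully specified
  (bitscore then lexicographic; smallest community id), so results are
  independent of input order and thread count.
* `-log10(E)` caps underflowed E-values at the double floor (`1e-320`) so
  correlation diagnostics stay finite.
* Zero-margin Fisher tables return `p = 1` with a degenerate flag; empty
  composite or non-composite groups, empty networks, and single-label edge
  sets raise errors rather than returning conventional values.
* Percentages round half away from zero to one decimal — the rule that
  reproduces published per-class count tables from their printed counts.

## Problem sizes

The validation suite runs the default 325-sequence study (oracle
equivalence additionally uses 200 random graphs of up to 40 nodes for
calling, graphs up to 30 nodes for cycle edges, an exhaustive sweep of 2x2
tables with row sums up to 15 plus sampled cross-checks for the Fisher p,
and 200-node graphs for the pivot estimator). These sizes were chosen so
the full suite exercises every code path in under a minute on one core;
the pipeline itself scales to the hundreds of thousands of sequences such
analyses target, with the stringent-pair enumeration and pivot betweenness
as the designated large-`n` paths.

## A worked example

```{r example}
ds <- simulate_dataset(synthetic_config())
net <- build_network(ds$hits, ds$sequences)
net
calls <- call_composites(net, max_evidence = Inf)
calls
multis <- call_multicomposites(net, calls)
safest <- apply_safest(calls, net, ds$metadata)
safest
truth <- ds$truth$levels
mean(truth$seq_id[truth$level != "component"] %in% calls$calls$seq_id)
```
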