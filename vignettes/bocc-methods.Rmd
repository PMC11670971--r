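---
title: "Methods: clustering and classifying a time-versioned gene-phenotype network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering and classifying a time-versioned gene-phenotype network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bocc)
```

## The model

`bocc` rests on guilt-by-association: in a network joining protein
interactions (gene-gene), ontology structure (phenotype-phenotype "is a"
relations), and curated gene-to-phenotype (g2p) annotations, densely
interconnected regions tend to reflect shared biology, so a gene and a
phenotype that co-occur in such a region *without* a direct edge are a
plausible latent connection. The method's evaluation device is temporal:
with one network snapshot per release year, a cluster computed on year *t*
is scored by how many of year *t+1*'s new g2p edges fall entirely inside
it ("rediscoveries"). A cluster that anticipates more future edges than
chance is useful for hypothesis generation today.

Assumptions worth keeping in view:

* Guilt-by-association is imperfect; the pipeline quantifies, per cluster,
  where it holds, rather than assuming it globally.
* Edge growth reflects curation priorities as much as biology; rediscovery
  counts are bounded by what the community happened to study.
* All edges are treated as undirected and (for clustering) unweighted.
  The ontology's is-a direction is kept only in a parent map, where it
  drives sub-ontology pruning; STRING confidence scores are kept on the
  edges but not fed to the community algorithms, because a confidence is
  not a random-walk affinity and ontology-derived edges have no comparable
  weight (they carry weight 0).

### Network construction

Phenotype terms outside the "Phenotypic abnormality" sub-ontology
(`HP:0000118`) are removed before the network is assembled, along with
every edge touching them. Terms such as inheritance modes are hubs with
thousands of gene neighbours; they compress graph distances without
carrying phenotype similarity, which misleads topology-driven clustering.
The pruning rule is reachability from the root in the parent map: a term
under both the root and a pruned branch is kept.

Identifier hygiene is structural: an id matching `HP:NNNNNNN` is a
phenotype, anything else a gene symbol, and an id used inconsistently
(e.g. an HP term inside the protein layer) is an integrity error rather
than a warning. STRING protein ids are translated to gene symbols only
through a user-supplied alias table; unmapped ids are dropped and counted,
never guessed.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_confidence` (STRING) | 0 | STRING combined score (0-1000) | keep the full graph; thresholding is a study-level decision |
| walktrap `steps` | 4 | random-walk length | the algorithm's common default |
| CESNA `n_communities` | `ceiling(n / 50)` | communities | targets mean community size near half the 100-node cap |
| Paris `max_size` | 100 | nodes | the curation limit: clusters above this are unusable for human review |
| null `replicates` | 10,000 (full scale) | synthetic clusters | empirical p resolution of 1e-4; tests and the acceptance script use 100-1,000 |
| p-value thresholds | 1.00, 0.35, 0.10, 0.05 | — | the four label definitions the threshold models predict |
| GA `population` / `generations` | 40 / 100 | — | full-scale tuning budget; fixture runs use far less |
| DART `rate_drop` / `skip_drop` | 0.1 / 0.5 | probabilities | mild dropout regularisation; exposed as arguments |
| variant filter | `(f < 0.01 \| i) & (e \| s) & (c \| l)` | — | rare or frequency-unknown, exonic/splice, consequential or ClinVar P/LP |

## Numerical and design choices

**Empirical p-values.** `p = #{synthetic >= observed} / R`, the plain
proportion without a +1 correction, so a cluster with zero rediscoveries
gets exactly `p = 1` and the attainable values form the grid
`0, 1/R, ..., 1`. The +1 variant is available behind `plus_one = TRUE`.
Because the snowball null's distribution depends on the cluster only
through its size, `cluster_pvalues()` shares null draws across equal-sized
clusters.

**Snowball sampling.** Breadth-first growth from a uniformly drawn seed;
when absorbing the whole next frontier would overshoot the target size the
remainder is filled uniformly at random from that frontier. If the seed's
component is smaller than the target, the truncated sample (the whole
component) is kept — resampling a fresh seed would bias the null toward
large components.

**Edge-shuffle comparison null.** Implemented as degree-preserving
double-edge swaps of the *new-edge set* (rejecting self-loops, duplicates,
and collisions with existing snapshot edges), counted against the fixed
cluster membership. Rewiring the snapshot itself while keeping both the
cluster and the new edges fixed cannot change any count — degree-preserving
swaps never add or remove nodes — so the new-edge randomisation is the
non-degenerate reading, and it coincides exactly with the other two nulls
on the fully-degenerate single-clique case.

**Paris size capping.** The Paris agglomerative hierarchy (merge distance
`d(a,b) = w(a)w(b) / (W w(a,b))`, ties broken by smallest node index pair,
disconnected parts attached last at infinite distance) is built per parent
cluster, and the dendrogram is cut by descending from the root and
emitting every maximal subtree with at most `max_size` leaves. This is
deterministic, guarantees the cap, and conserves membership exactly.
Parents already under the cap are emitted whole.

**Greedy modularity.** The merge tree is cut at the first modularity
maximum (the finer partition on ties), which also handles tiny graphs
where the default igraph membership stops one merge short.

**CESNA.** Overlapping memberships are fit by projected batch gradient
ascent on the affiliation-model likelihood (`P(u~v) = 1 - exp(-F_u.F_v)`)
plus a logistic attribute term, with three random restarts (best
likelihood kept) and a normalized step `eta G / (1 + |G|)` that bounds
per-entry moves — a plain step is unstable because the batch non-edge
gradient scales with the total membership mass. Each binary attribute is
one-hot encoded with zero-initialised weights, making the fit exactly
symmetric under flipping an attribute's coding. Nodes whose maximum
membership falls below the background-density threshold stay unassigned;
they simply do not participate in rediscovery. The default (and only
default) attribute is the node's gene/phenotype type.

**Classifier.** Labels use the strict inequality `p < threshold`; the
majority class is down-sampled without replacement to the minority size;
`temporal_split()` refuses any split in which a training timestamp is not
strictly earlier than every test timestamp. Cross-validation for feature
selection and GA fitness is 5-fold and stratified, with fold assignment
fixed by the seed. GA operators: tournament selection (k = 3), uniform
crossover (p = 0.5), per-gene uniform-resample mutation (p = 0.1),
elitism of 1 — only population, generations and the F1 fitness are
externally prescribed, the operators are this package's choices. One
shared feature set is used across the four thresholds. The binary call
threshold on predicted probability is 0.5.

**Degenerate inputs.** A cluster equal to the whole graph has conductance
and cut 0 and embeddedness 1; an isolated member contributes embeddedness
0; an all-phenotype cluster has disease specificity 0. "Disease
specificity" itself is implemented as the fraction of a cluster's genes
carrying at least one g2p annotation in the snapshot — the simplest
reading with the documented 0-1 range; the accessor is pluggable via
`annotated_genes` for enrichment-test variants. Conductance uses the
standard community formula `b / (2 e_in + b)`; cut uses the cut-ratio
denominator `size (N - size)`.

## The synthetic generator

`generate_series()` emulates the structural assumptions the pipeline
relies on, at a scale where every test runs in seconds: a two-layer
stochastic block model (default 120 nodes, 6 blocks, within/between edge
probabilities 0.25 / 0.015), a sparse g2p annotation layer, a two-point
expected-degree mixture (5% of nodes at 3x degree) to exercise hub
handling, and a later snapshot adding `n_future_edges` new g2p edges.
Future edges land inside designated *signal blocks* with odds
`enrichment`; signal blocks also carry a denser baseline annotation rate
(`signal_g2p_boost`, default 4x), the synthetic analogue of well-curated
disease modules continuing to accrue annotations. That density is what
gives cluster features genuine predictive power over future enrichment —
with uniform enrichment every block-aligned cluster would be positive and
there would be nothing to learn. With `enrichment = 1` placement is
exactly uniform over eligible pairs.

`generate_patient_cohort()` draws per-patient HPO term counts from a
truncated-geometric distribution on 1-17 with median 3 (the shape of real
rare-disease phenotype profiles), quantile-matched so the cohort median is
exact; signal patients draw genes and terms from one planted block, all
others independently (hence exchangeable, for calibration tests).

What the generator does *not* emulate: literature and curation bias in
edge growth, the heavy-tailed degree distribution of real interactomes,
ontology depth structure, and annotation redundancy. Passing tests
therefore demonstrate correctness and calibration of the machinery under
the stated structural assumptions, not performance on real yearly STRING/
HPO/OMIM releases — the published full-scale numbers depend on archived
versions of those sources and on private clinical data, and are out of
scope here.

## Problem sizes

The test-suite and acceptance-script runs use: 120-node fixtures; 500
calibration trials at 200 null replicates; 500 replicates for planted
blocks versus 90 random connected sets (pooled over 3 fixtures); 24
independent fixtures (~150 non-trivial clusters, temporal split 16/8
snapshots) at 150 null replicates for the classifier; and a 30-patient
cohort at 100 permutation replicates. These sizes were chosen so each
statistical check retains power while the whole suite stays interactive.

## Known limitations

* CESNA here is a compact reimplementation of the affiliation-plus-
  attributes model, adequate at fixture scale; very large graphs would
  want the original block-coordinate implementation.
* The Paris implementation is dense-matrix `O(n^2)` per parent cluster —
  fine under the 100-node cap regime, not for re-clustering million-edge
  parents.
* The patient permutation null conditions on the cohort's term sets;
  cohorts with systematically correlated phenotype profiles will make it
  conservative.
* The variant filter consumes whatever annotations the VCF INFO fields
  provide (mapping configurable via `vcf_field_map()`); it performs no
  calling, annotation, or prioritisation of its own.
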