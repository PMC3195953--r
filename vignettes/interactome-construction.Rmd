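---
title: "Building and evaluating query-centred interactomes with orthonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating query-centred interactomes with orthonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthonet)
```

## The model

`orthonet` treats a protein–protein interaction (PPI) dataset as a simple
undirected graph per species: proteins are vertices, physical associations
are edges, and each edge carries the union of its provenance (source
databases, detection methods, PubMed ids) over all records that reported it.
Two modelling commitments are made up front and everything downstream
depends on them:

* **Loop-free simple graphs.** Self-interactions (homodimers) are retained
  as records and exported, but never enter the edge set. Degree, clustering
  and assortativity all assume simple-graph semantics; silently counting
  loops would distort each of them differently.
* **Canonical undirected edges.** Databases report both orientations of the
  same pair; the canonical key is the lexicographically sorted identifier
  pair, and duplicate reports union-merge their provenance.

The scientific object of interest is the *query network*: given a list of
query proteins (a molecular machine and its cofactors), select the query
vertices, their first neighbours, and every edge among the selected set —
first-level interactions plus second-level (neighbour–neighbour) edges.
Non-human query networks are projected onto human genes through ortholog
groups: if proteins a and b interact in some species, every pair of human
orthologs (h_a, h_b) of a and b is a candidate *interolog*. Projected edges
already known in human are subtracted, and the per-species results merge
into one human-projected interactome whose edges are tagged `human` or
`interolog:<taxid>` (both, when an edge arrives by both routes across merge
batches — display layers may then prioritise the direct evidence).

Assumptions worth stating: orthology comes only from the supplied group
table (no sequence-based inference); annotation sets are flat (no GO
parent–child propagation — propagate upstream if the hierarchy should
count); and the interolog hypothesis itself, which is a heuristic — the
pipeline records the origin of every projected edge precisely so that users
can weigh that evidence.

## Pipeline order

Stages run per species in the order *clean → query-extract → project →
subtract → merge*. Extracting before projecting is deliberate: under
one-to-many orthology, projection does not commute with first-neighbour
extraction, and extraction in the species' own namespace is the operation
with a clear biological reading (the species' observed neighbourhood of the
query machine). The query list is translated into each species' identifiers
through the ortholog map before extraction.

Subtraction removes projected edges present anywhere in the *full* cleaned
human network, not merely in the human query network: an interolog that
merely falls outside the human query neighbourhood but is already known in
human is not a novel prediction.

## Graph measures and their conventions

`compute_measures()` reports nine quantities. Conventions that required a
decision:

* **Connectivity** is global edge density, 2|E|/(|V|(|V|−1)). It is listed
  in this family of measures alongside mean degree and clustering as a
  density measure, and density is the standard third member of that family;
  the implementation keeps it behind a named field so an alternative
  definition can be slotted in if needed.
* **Diameter** is computed within the largest connected component. A merged
  interactome routinely has a handful of satellite components; the
  disconnected-graph convention (infinite diameter) would make the measure
  useless exactly where it is most interesting.
* **Clustering coefficient** is the average local coefficient with
  degree-<2 vertices contributing 0 (not excluded, and not the global
  triangle ratio). This is the convention under which the per-node
  clustering distribution is defined for every node of the network.
* **Assortativity** is the Pearson correlation of endpoint degrees over both
  orientations of every edge. It is undefined when endpoint degrees have
  zero variance (regular graphs); the implementation flags this
  (`assortativity_defined = FALSE`) rather than emitting a number.
* Degenerate inputs: a single-vertex graph has diameter 0 and density 0 by
  convention, with `density_defined = FALSE`.

All measures are cross-checked in the test suite against brute-force
implementations (all-pairs BFS, triple enumeration, explicit correlation)
on randomly generated graphs of up to 12 vertices, to 1e-9.

## The random-query null model

Whether a query network is "denser than expected" is judged against
networks extracted identically but from random query sets: `sample_null()`
draws `query_size` vertices uniformly without replacement from the base
network (default 300 replicates, matching standard practice for this kind
of control), runs the same first-neighbour extraction, and computes the same
measures. The replicate query size defaults to the real query list's
length — control networks must answer "what would a random query of the same
size have returned", not "what does a random network of the same node count
look like".

Each replicate draws from an RNG stream derived deterministically from
(seed, replicate index), so a null distribution is a pure function of (base
network, query size, replicate count, seed); the seed is mandatory.
`compare_to_null()` reports the null mean and SD, a z-score, and an
*add-one* empirical two-sided p-value, p = (1 + #{|x−μ| ≥ |obs−μ|}) / (n+1);
the pseudo-count avoids reporting p = 0 from finite sampling. Replicates
with undefined assortativity are excluded from that measure's summary, with
the exclusion count reported.

## Enrichment and the functional map

Over-representation uses the hypergeometric upper tail P(X ≥ k) for k
annotated members among n network members, against a background universe
that defaults to *all proteins the interaction data could have returned* —
the human network's proteins plus the human projections of every species
network's proteins — rather than the whole genome. The genome-wide
background answers a different question (is this network enriched relative
to all genes?) and systematically flatters any interaction dataset;
a whole-annotation background remains available by passing `universe`
explicitly. Benjamini–Hochberg is the default correction (Bonferroni
available).

The functional map keeps terms with adjusted p ≤ 0.05 **and** at least 8
contributing network members — term size cutoffs of this kind suppress the
long tail of tiny, unstable terms — and connects term pairs whose binary
membership vectors over the member set agree with Cohen's κ ≥ 0.4
(Jaccard overlap is available as an alternative since the requirement is
only "shares members"). The `min_proteins` rule is applied to the overlap k
(proteins from the network), not to the term's total annotation count.
Connected clusters are labelled by their most significant member term, with
ties broken by term id so the map is invariant to input ordering.

## What the synthetic generator emulates

`generate_fixture()` builds a deterministic multi-species bundle from a
single "ancestral" human edge layer: an Erdős–Rényi background
(`background_edge_p`) with a dense planted *query machine* — the query
proteins plus a designated neighbour shell — wired at `planted_p_in`. Each
species receives a copy of the ancestral edges restricted to its mapped
genes (per-species ortholog coverage is sampled at `ortholog_coverage`),
plus private noise among pairs touching unmapped genes. The human table
keeps each conserved edge with probability `human_overlap_fraction`, which
is precisely the knob that exercises known-human subtraction. Tables are
dressed with duplicate orientations, genetic-category rows, cross-species
rows, a self-interaction and identifier aliases, so every cleaning stage has
work to do, and the generator emits its own ground truth — the exact merged
edge set with origins — computed by plain set arithmetic independent of the
pipeline operations.

Default conditions: seven species (human plus six model organisms, 2 400
nodes in total), background density 0.01, a 39-protein query list with a
40-node shell at within-machine density 0.25, 60% ortholog coverage, 30%
human overlap, and 25 GO terms of which one annotates 75% of the machine.
The query list size matches the scale at which a molecular machine is
typically queried; coverage and overlap sit in the range observed between
HomoloGene and the primary PPI databases.

What the generator does **not** emulate: study bias (well-studied proteins
attract reports), detection-method correlation between databases, and
heavy-tailed degree distributions (the background is Erdős–Rényi because the
contracts under test — extraction, projection, null calibration — are
degree-distribution-agnostic and ER gives closed-form expectations).
Passing tests therefore certify the pipeline's *operations and statistics*,
not robustness to real-data pathologies.

## Statistical validation design

Two properties tie the null model to the generator, both run on
single-network configurations so that the designated query set is
*exchangeable* with the null's random draws (in a multi-species run the
observed network is a cross-species union and no such exchangeability
holds):

* **Calibration.** With `planted_p_in == background_edge_p` the machine is
  statistically invisible and the empirical p for the clustering coefficient
  must be uniform: over 200 seeded runs (300-node network, query 15, 59 null
  replicates — chosen so that p ≤ 0.05 has probability exactly 3/60 under
  exchangeability), the rejection count must fall inside the 99% binomial
  band around 5%. The generator's spec permits equality of the two densities
  for exactly this purpose.
* **Power.** With a dense planted machine the null must be rejected on mean
  degree and clustering in at least 90% of 100 seeded runs. The test design
  — a 2000-node background at density 0.001 (mean degree ≈ 3, the sparse
  regime typical of per-species query neighbourhoods), query 30, shell 30,
  within-machine density 0.5 — was fixed by an a-priori power analysis: the
  null distribution of clustering is bimodal (replicates that touch the
  planted machine versus those that do not), and because the base network
  contains the machine, random draws landing two or more queries inside it
  produce clustering values approaching the observed one. The chosen design
  keeps the machine dense enough, and the background sparse enough, that
  such draws are too rare to erode the rejection rate.

Problem sizes throughout the suite (300–2 400-node networks, 59–300 null
replicates, 100–200 seeds) were chosen as the smallest at which these
binomial criteria are stable.

## Known limitations

* One-to-many orthology expands to the full cross product of human group
  members, which can inflate interolog counts for large paralog families;
  the alternative (choosing one member) silently loses candidates, so
  expansion is the default and the origin tags keep it auditable.
* Identifier normalisation is only as good as the supplied map; unmapped
  identifiers pass through (or are dropped and counted, under
  `policy = "strict"`), and isoform ambiguity must be encoded by the caller
  as one-to-many map entries.
* The XGMML reader resolves nodes by id or label and ignores layout; exotic
  Cytoscape attribute schemas beyond that are not interpreted.
* Empirical p-values are bounded below by 1/(n_reps + 1); claims beyond
  that resolution require more replicates, not smaller numbers.
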