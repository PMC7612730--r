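---
title: "Discovering recurrent multicellular TME structures from multiplexed imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering recurrent multicellular TME structures from multiplexed imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmestruct)
```

## The problem this package addresses

Highly multiplexed tissue imaging (imaging mass cytometry and related
platforms) measures dozens of protein markers per cell while preserving
each cell's position in the tissue. In solid tumors, the non-epithelial
cells — the tumor microenvironment (TME) of stromal, vascular and
immune cells — organize into multicellular structures whose composition
and connectivity reflect local function: activated peritumoral stroma,
perivascular niches, lymphoid aggregates, niches of regulatory and
dysfunctional T cells. `tmestruct` implements a multitiered analysis
that goes from segmented single-cell tables to a catalog of recurrent
TME structures and their genomic and prognostic associations:

1. **Phenotyping.** Spillover-compensated, arcsinh-transformed marker
   expression; per-image epithelial/TME split; self-organizing-map
   (SOM) clustering with graph-community detection and automated
   cluster merging into cell phenotypes.
2. **Interfaces.** Enrichment and depletion of TME phenotypes at the
   tumor–stroma interface and in the perivascular space, by weighted
   binomial generalized linear models.
3. **Structure discovery.** Cell-contact graphs (8 µm rule), Walktrap
   community detection, per-community connectivity profiles, and
   consensus clustering to find the number of recurrent structures.
4. **Associations and outcome.** Per-patient structure burden,
   enrichment against subtype and alteration labels, feature-category
   prediction with L1-regularized logistic regression, and
   ER-stratified Cox models of disease-specific survival.

Because raw imaging cohorts are large and access-controlled, the
package ships a seed-deterministic synthetic-cohort generator that
reproduces the statistical structure each stage assumes. Every claim in
the test suite is computed on data the generator (or a purpose-built
count-level simulation) produces.

## The contact rule and its geometric proxy

Cell–cell relationships are defined by centroid distance: two cells are
in contact when their centroids lie within **8 µm** (inclusive). In the
original imaging workflow, adjacency comes from shared pixels between
expanded segmentation masks; since cell-mask geometry is not
reproducible from tabular data, the same 8 µm scale is applied to
centroids, both for cell–cell contacts and for relating cells to tumor
or vessel region masks (`attach_mask_overlap()`: inside a region, or
within 8 µm of a region pixel center, inclusive). Enlarging the contact
distance can only add relationships, never remove them — a property the
tests exercise.

## Phenotyping choices

* **Transformation.** `asinh(count / 0.8)` with per-marker clipping at
  the 99th centile, the standard variance-stabilizing treatment for
  right-skewed ion counts.
* **Compartment split.** Per image, a two-component Gaussian mixture on
  `log(1 + panCK)`; the higher-mean component is epithelial, with
  posterior ties resolved toward the TME so that ambiguous cells do not
  inflate the tumor compartment. The mixture is a small deterministic
  EM (quartile initialization, scale-relative variance floor), which
  makes the fit reproducible and equivariant under affine rescaling of
  the input. Images with fewer than 20 cells fall back to the
  tumor-mask rule; `method = "auto"` picks, per image, whichever of the
  mixture and mask assignments yields the higher mean pan-cytokeratin
  contrast between compartments — a quantitative surrogate for
  morphology-guided expert adjudication.
* **Clustering.** A 35×35 SOM (1,225 nodes) segregates cells; node
  median profiles are clustered by Louvain community detection on a
  k-nearest-neighbor graph (k = 30). Edges carry self-tuning Gaussian
  kernel weights, `exp(-d²/(σᵢσⱼ))` with σᵢ the distance to the
  (k/3)-th neighbor: with a fixed k, phenotype "islands" smaller than k
  nodes would otherwise be fully interconnected and fuse, whereas the
  local scale makes between-island edges vanish. The Louvain resolution
  defaults to 2 — a deliberate oversplit — because the next step merges
  clusters whose median profiles correlate at ≥ 0.9 (average-linkage
  agglomeration). Oversplitting then merging is recoverable; an
  undersplit is not. An explicit cluster-to-phenotype mapping file can
  replace the automated merge to reproduce curated groupings.

## Connectivity profiles and the number of structures

Communities are detected per image in the TME contact graph (epithelial
and perivascular cells excluded) with Walktrap at 4 random-walk steps;
communities under 10 cells are discarded. Each community is summarized
by its **connectivity profile**: for each of the 16 TME phenotypes, the
number of within-community contacts incident to cells of that phenotype.
Profile entries always sum to exactly twice the internal edge count — an
invariant asserted for every community in every test cohort.

Profiles are clustered with Ward's method. The representation matters:
raw connection counts conflate a structure's identity with its size —
random-walk partitions fragment large homogeneous structures, and sizes
within an archetype vary severalfold, so Euclidean distances on raw
counts are dominated by magnitude. On default synthetic cohorts this
selected far too few clusters and misassigned communities
(ARI ≈ 0.2 against the planted archetypes). The default therefore
clusters **connection proportions** (each profile divided by its total):
still a connectivity description — how a community's contacts distribute
across phenotypes — but independent of how many contacts it has. Raw
counts and a log1p compromise remain available via `scale =`.

The number of structures is chosen by consensus clustering
(`select_n_structures()`): for each candidate k, 100 subsamples of 80%
of the profiles are Ward-clustered; the consensus matrix, its CDF area
and delta area are recorded, together with the **subsample stability** —
the mean adjusted Rand index between replicate clusterings on their
shared items. Solutions at or below the true number of clusters
reproduce almost perfectly under subsampling; beyond it, clusters are
split arbitrarily and reproducibility drops and stays low. The selected
k is the largest one whose stability exceeds the midpoint between the
stability curve's maximum and minimum — a self-calibrating threshold
with no tuned constant — subject to a recurrence floor: a candidate k is
disqualified if the full-data Ward cut would create a structure with
fewer than 10 member communities, since a "recurrent structure" observed
a handful of times is not recurrent. The classical delta-area elbow
(largest k with relative delta area > 0.05) was evaluated first and
failed on planted-archetype cohorts (it has no stable crossing at the
planted k); the stability rule recovers the planted k = 10 on
independent cohort seeds, and k = 3 on three-archetype cohorts. The
`k_range` should always extend past the expected number of structures so
the stability drop is observable.

Out-of-sample classification uses a random forest on the same scaled
profiles; its out-of-bag accuracy is reported and held-out accuracy on
planted cohorts exceeds 0.9, collapsing to chance when labels are
shuffled.

## Enrichment models

Composition comparisons use binomial-logit GLMs on proportions with the
stratum total as the binomial denominator, so tumors contributing more
cells (or more cell–cell connections) carry proportionally more weight:

* **Interfaces** (`interface_enrichment()`): per phenotype, the
  proportion of TME cells of that phenotype at versus off the interface,
  across tumor × membership strata; tumors lacking the phenotype are
  excluded from that phenotype's model; Benjamini–Hochberg adjustment
  is applied across the phenotypes of one interface analysis (the
  tumor–stroma and perivascular analyses are separate families).
* **Structure burden** (`enrichment_glm()`): per structure, the
  fraction of all TME connections occupied by that structure against a
  binary subtype/alteration label, weighted by total connections per
  tumor. Patients with zero TME edges are dropped rather than
  zero-weighted.

Estimates are exactly antisymmetric under flipping the interface flag
or the label, and invariant to duplicating every cell — both asserted in
the tests. Calibration (type-I error within [0.03, 0.07] at α = 0.05)
is checked on count-level simulations where the binomial sampling
assumption holds by construction; on real cohorts, between-tumor
heterogeneity beyond binomial sampling would make these tests
anticonservative, which is the main caveat when interpreting small
adjusted p values.

## Survival modeling

Structure burden is discretized per structure into four ordered
categories: tumors without the structure are the `absent` baseline;
tumors containing it are split at the empirical tertiles of the
positive fractions (boundary ties fall to the lower category, and the
discretization is invariant to rescaling all fractions). Cox
proportional-hazards models of disease-specific survival are fitted
separately by ER status (ER violates proportional hazards) and adjusted
for HER2 as a covariate. The ordered category enters as a numeric 0–3
score by default, yielding a single hazard ratio per structure;
`coding = "categorical"` provides tertile-versus-absent contrasts
instead, since the score coding is a modeling choice rather than a
forced one. Proportional hazards of the structure terms is not formally
tested. Presence/absence comparisons use two-group log-rank tests with
Kaplan–Meier tables.

## What the synthetic generator emulates — and what it does not

Each image emulates a tissue-microarray spot (600 µm square, 1 µm mask
pixels): 2–3 tumor nests of hexagonally packed epithelial cells with a
tumor mask; 3–6 vessels with vessel masks and perivascular cells; 2–5
planted structure instances; and ~150 sparse background TME cells.
Expression is log-normal around per-phenotype archetype locations
(16 TME + 16 epithelial archetypes whose pairwise log-mean cosine
similarity is below 0.8, so they are recoverable in principle);
counts are `exp(normal) − 0.2`, floored at zero. Planted structures are
jittered hexagonal packings at 6 µm spacing — below the 8 µm contact
radius with a jitter bound that cannot break adjacency, so every
planted instance is a connected contact subgraph by construction. The
ten structure archetypes encode the qualitative biology of vascular and
activated stroma, immune-response variants, lymphoid-aggregate-like and
suppressed-expansion-like structures, with the latter two drawn larger
(triangular size distributions with modes near 110–120 cells versus
30–45 for stromal structures). Survival times are exponential with
log-hazard linear in structure connection fractions; censoring is
independent exponential calibrated to the configured rate; alteration
labels are logistic in standardized fractions.

The generator does **not** emulate pixel-level noise, spillover at the
raster level, segmentation errors, spatial gradients within structures,
background cells infiltrating structures, multi-spot tumors, or
between-tumor overdispersion of compositions. Passing tests therefore
demonstrate that the pipeline recovers planted statistical structure
under its own assumptions — not that those assumptions hold in any
particular real cohort.

Ground-truth phenotype, compartment and community labels are kept in a
sidecar table (`cohort$truth`), separate from the cell table the
pipeline consumes, so no stage can accidentally use them.

## Problem sizes and determinism

Default verification scales, chosen to exercise each stage at full
parameterization while staying desk-sized: 20,000 cells for phenotype
recovery (full 35×35 SOM); 160-image cohorts (~100,000 cells, ~1,000
communities) for structure-count recovery with 100 consensus
repetitions over k = 2–15; 200 replicates for GLM calibration; 100
replicates for Cox coverage. Every stochastic step takes an explicit
seed, per-task streams are derived with a fixed multiplier and kept in
32-bit range, and identical configurations produce byte-identical stage
tables (asserted on reruns of the full discovery pipeline).

## Known limitations

* Walktrap fragments large homogeneous structures into several
  communities; fragments carry the correct composition, so structure
  assignment is unaffected, but community counts should not be read as
  instance counts.
* The stability rule for k needs `k_range` to extend beyond the true
  number of structures, and at least a few dozen communities per
  structure; tiny cohorts will fall back to smaller k.
* Separate per-image SOM runs (discovery versus validation) produce
  different cluster vocabularies; validation phenotypes are aligned to
  discovery phenotypes by median-profile correlation, which assumes the
  discovery catalog covers the validation phenotypes.
* Weighted binomial GLMs ignore between-tumor overdispersion (see
  above); interval estimates on real data are best treated as
  descriptive rankings.
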