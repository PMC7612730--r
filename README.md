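# tmestruct

Multitiered spatial analysis of the breast tumor microenvironment (TME)
from highly multiplexed tissue imaging. Starting from segmented
single-cell tables (centroid coordinates and per-marker ion counts),
`tmestruct` phenotypes cells, quantifies composition shifts at tissue
interfaces, discovers recurrent multicellular TME structures from
cell-contact graphs, classifies structures out of sample, and relates
structure burden to genomic labels and survival. A seed-deterministic
synthetic-cohort generator with planted phenotype and structure
archetypes makes every stage testable without raw imaging data.

## Who it is for

Computational biologists analyzing imaging mass cytometry (or CODEX /
MIBI-style) cohorts of solid tumors who want a tested, reusable
implementation of the contact-graph / community / connectivity-profile
workflow, and methodologists who need a ground-truthed simulation bed
for spatial single-cell methods.

## The method in brief

- **Phenotyping.** Non-negative least-squares spillover compensation;
  `asinh(count/0.8)` transform clipped at the 99th centile; per-image
  two-component Gaussian mixture on log pan-cytokeratin (or a tumor
  mask) to split epithelial from TME cells; a 35×35 self-organizing map
  whose node profiles are clustered by Louvain communities on a
  kernel-weighted kNN graph, then merged at profile correlation ≥ 0.9
  into final phenotypes.
- **Contact graphs.** Cells are vertices; an edge joins cells whose
  centroids lie within 8 µm (inclusive). TME graphs exclude epithelial
  and perivascular cells. Walktrap (4-step random walks) yields
  communities of ≥ 10 cells.
- **Connectivity profiles.** For community *c* and phenotype *f*,
  profile entry `P_cf = Σ_{i∈c, pheno(i)=f} deg_c(i)`; rows sum to
  `2 × |E_c|` exactly. Ward clustering of connection proportions with
  consensus-clustering model selection (subsample stability) gives the
  catalog of recurrent structures; a random forest classifies new
  communities into it.
- **Associations.** Structure burden per patient = fraction of all TME
  connections in communities of each structure; binomial-logit GLMs
  weighted by total connections test enrichment against binary labels;
  L1-regularized logistic regression compares feature categories by
  out-of-sample AUC.
- **Survival.** Burden discretized as absent / low / mid / high
  (tertiles among positive tumors); Cox models of disease-specific
  survival per structure, stratified by ER status and adjusted for
  HER2; log-rank presence tests.

See `vignettes/tme-structure-discovery.Rmd` for the full model
description, parameter defaults, and design rationale.

## Worked example

```r
library(tmestruct)

cfg <- cohort_config(n_images = 60, seed = 11)
cohort <- generate_cohort(cfg)
communities <- do.call(rbind, lapply(cohort$tme_graphs, detect_communities))
profiles <- connectivity_profile(communities, cohort$tme_graphs)
nrow(profiles)
#> communities: 395

catalog <- select_n_structures(profiles, k_range = 2:15, reps = 50, seed = 11)
catalog$k
#> selected k: 11

fr <- structure_connection_fractions(communities, catalog$labels,
                                     cohort$tme_graphs, cohort$image_patient)
fr[1:3, c("patient_id", "S01", "S02", "total_connections")]
#>   patient_id  S01  S02 total_connections
#> 1      P0001 0.00 0.00               416
#> 2      P0002 0.46 0.00              1120
#> 3      P0003 0.00 0.53              1096

clin <- generate_clinical(cohort)
cats <- discretize_connectivity(fr)
cox_structures(cats, clin[clin$patient_id %in% fr$patient_id, ], "pos")[1:3,
    c("structure", "hr", "ci_lo", "ci_hi", "p")]
#>   structure   hr ci_lo ci_hi    p
#> 1       S01 0.88  0.58   1.3 0.56
#> 2       S02 1.16  0.81   1.7 0.41
#> 3       S03 1.04  0.65   1.7 0.86
```

Reading the output: 395 contact-graph communities were detected across
60 images; consensus clustering keeps 11 stable profile clusters at
this cohort size (at the 160-image scale the test suite runs, the ten
planted archetypes are recovered exactly — small cohorts may retain one
extra split). Each patient's burden per structure is the fraction of
their TME connections inside communities of that structure, weighted
downstream by `total_connections`. The default cohort plants no hazard
effects, so the per-tertile-score hazard ratios are appropriately near
1 with confidence intervals covering it. `run_discovery()` /
`run_validation()` wrap the whole chain, write every stage table plus a
run manifest to an output directory, and classify an independent cohort
against the discovered catalog.

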