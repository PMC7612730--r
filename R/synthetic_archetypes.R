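## Default phenotype and structure archetype catalogs for the synthetic
## cohort generator. Phenotype archetypes are log-scale expression
## locations per marker (cells draw log-normal counts around them);
## structure archetypes are composition vectors over the 16 TME
## phenotypes together with a characteristic size range and packing
## spacing. The catalogs encode the qualitative cell biology of a breast
## tumor microenvironment: lymphoid and myeloid lineages, stromal
## activation states, endothelium, and epithelial cytokeratin/hormone
## receptor diversity.

## log-scale intensity tiers (raw ion counts ~ exp of these)
.TIER <- c(base = log(0.5), mid = log(6), hi = log(30))

.pheno_profile <- function(panel, hi = character(), mid = character(),
                           h3 = log(5)) {
  v <- setNames(rep(.TIER[["base"]], length(panel)), panel)
  v[hi] <- .TIER[["hi"]]
  v[mid] <- .TIER[["mid"]]
  if ("HistoneH3" %in% panel) v["HistoneH3"] <- h3
  v
}

.tme_marker_sets <- function() list(
  T_CD4              = list(hi = c("CD3", "CD4", "CD45RO")),
  T_CD8              = list(hi = c("CD3", "CD8", "CD45RA")),
  T_reg              = list(hi = c("CD3", "CD4", "FOXP3", "ICOS")),
  T_ex               = list(hi = c("CD3", "CD8", "PD1", "GITR", "OX40")),
  B_cells            = list(hi = c("CD20", "CD45RA"), mid = "HLA_DR"),
  CD38_lymphocytes   = list(hi = "CD38", mid = c("CD31_vWF", "CD45RO")),
  Macrophages        = list(hi = c("CD68", "CD163"), mid = "HLA_DR"),
  Granulocytes       = list(hi = c("CD15", "CD16")),
  APC_CD11c          = list(hi = c("CD11c", "HLA_DR"), mid = "B2M"),
  Endothelial        = list(hi = c("CD31_vWF", "CAV1")),
  Myofibroblasts     = list(hi = c("SMA", "PDGFRB")),
  Myofibroblasts_PDPN = list(hi = c("SMA", "PDPN"), mid = "CAV1"),
  Fibroblasts        = list(hi = "PDGFRB", mid = "CAV1"),
  Fibroblasts_FSP1   = list(hi = "FSP1", mid = "PDGFRB"),
  Ki67_TME           = list(hi = "Ki67", mid = c("CD3", "CD45RO")),
  CD57_TME           = list(hi = "CD57", mid = "CD16")
)

.epi_marker_sets <- function() list(
  Ep_CK8_ER       = list(hi = c("CK8_18", "ER")),
  Ep_CK8_CXCL12   = list(hi = c("CK8_18", "CXCL12")),
  Ep_ER_CXCL12    = list(hi = c("ER", "CXCL12")),
  Ep_HER2         = list(hi = c("HER2_3B5", "HER2_D8F12")),
  Ep_Basal_PDPN   = list(hi = c("CK5", "PDPN")),
  Ep_Basal_MHC_I  = list(hi = c("CK5", "HLA_ABC")),
  Ep_CD15         = list(hi = c("CD15", "CK8_18")),
  Ep_CD57_ER      = list(hi = c("CD57", "ER")),
  Ep_MHC_hi       = list(hi = c("HLA_DR", "HLA_ABC")),
  Ep_APM_B2M      = list(hi = c("B2M", "HLA_DR")),
  Ep_Ki67         = list(hi = c("Ki67", "CK8_18")),
  Ep_Apoptotic    = list(hi = c("cCASP3", "B2M")),
  Ep_CK5_CK8      = list(hi = c("CK5", "CK8_18")),
  Ep_HER2_ER      = list(hi = c("HER2_3B5", "ER")),
  Ep_CD57_CXCL12  = list(hi = c("CXCL12", "CD57")),
  Ep_CK_low       = list(hi = character())
)

#' TME phenotype names of the default catalog
#' @return Character vector of 16 names (fixed order).
#' @export
tme_phenotype_names <- function() names(.tme_marker_sets())

#' Build a phenotype archetype catalog
#'
#' @param panel Marker panel (character vector).
#' @param sets Named list of `list(hi=, mid=)` marker sets.
#' @param compartment `"tme"` or `"epithelial"`.
#' @param log_sd Common log-scale dispersion (default 0.35).
#' @return A `phenotype_catalog`: list with `names`, `compartment`,
#'   `panel`, `log_mean` (phenotype x marker matrix) and `log_sd`.
#' @export
phenotype_catalog <- function(panel, sets, compartment, log_sd = 0.35) {
  if (anyDuplicated(names(sets)))
    stop("duplicate archetype names in catalog")
  lm <- t(vapply(sets, function(s) {
    missing <- setdiff(c(s$hi, s$mid), panel)
    if (length(missing))
      stop("panel is missing required marker(s): ",
           paste(missing, collapse = ", "))
    v <- .pheno_profile(panel, hi = s$hi, mid = s$mid %||% character())
    if (compartment == "epithelial" && "panCK" %in% panel)
      v["panCK"] <- if (identical(s$hi, character())) log(4) else log(12)
    v
  }, numeric(length(panel))))
  colnames(lm) <- panel
  structure(list(names = names(sets), compartment = compartment,
                 panel = panel, log_mean = lm,
                 log_sd = matrix(log_sd, nrow(lm), ncol(lm),
                                 dimnames = dimnames(lm))),
            class = "phenotype_catalog")
}

.structure_defs <- function() list(
  vascular_stroma = list(
    mix = c(Endothelial = .30, Fibroblasts = .20, Myofibroblasts = .12,
            CD38_lymphocytes = .10, Macrophages = .06,
            Myofibroblasts_PDPN = .05),
    size = c(18, 32, 55)),
  active_stroma = list(
    mix = c(Myofibroblasts = .38, Fibroblasts = .18,
            Myofibroblasts_PDPN = .10, Endothelial = .06,
            Fibroblasts_FSP1 = .06),
    size = c(18, 35, 60)),
  pdpn_active_stroma = list(
    mix = c(Myofibroblasts_PDPN = .34, Myofibroblasts = .12,
            B_cells = .12, Fibroblasts = .08, T_CD4 = .06),
    size = c(18, 35, 60)),
  fsp1_enriched = list(
    mix = c(Fibroblasts_FSP1 = .40, Fibroblasts = .12, B_cells = .10,
            Myofibroblasts = .06, T_CD4 = .05),
    size = c(18, 32, 55)),
  active_ir = list(
    mix = c(T_CD4 = .22, T_CD8 = .18, B_cells = .14, Macrophages = .10,
            APC_CD11c = .06),
    size = c(25, 45, 85)),
  cd8_macrophages = list(
    mix = c(T_CD8 = .30, Macrophages = .28, T_CD4 = .06, CD57_TME = .05),
    size = c(20, 38, 65)),
  granulocyte_enriched = list(
    mix = c(Granulocytes = .38, Macrophages = .10, T_CD8 = .08,
            CD57_TME = .05),
    size = c(18, 32, 55)),
  apc_enriched = list(
    mix = c(APC_CD11c = .30, Macrophages = .16, T_CD4 = .10,
            CD38_lymphocytes = .06),
    size = c(20, 38, 65)),
  tls_like = list(
    mix = c(B_cells = .32, T_CD4 = .18, T_CD8 = .10, APC_CD11c = .08,
            CD38_lymphocytes = .08),
    size = c(60, 110, 210)),
  suppressed_expansion = list(
    mix = c(T_ex = .20, T_reg = .15, Ki67_TME = .14, T_CD4 = .10,
            APC_CD11c = .08, B_cells = .08),
    size = c(60, 120, 230))
)

#' Build a structure archetype catalog
#'
#' Each archetype has a composition probability vector over the 16 TME
#' phenotypes (a small floor is spread over all phenotypes, then the
#' vector is normalized to sum to 1), a triangular size distribution
#' (min, mode, max cell count), and a target inter-cell packing spacing
#' below the 8 micrometer contact radius so planted instances form
#' connected contact subgraphs.
#'
#' @param defs Named list of `list(mix=, size=)` definitions.
#' @param phenotypes TME phenotype names the compositions index.
#' @param spacing_um Packing spacing in micrometers (must be < 8).
#' @return A `structure_catalog_archetypes` list.
#' @export
structure_archetypes <- function(defs = .structure_defs(),
                                 phenotypes = tme_phenotype_names(),
                                 spacing_um = 6) {
  if (anyDuplicated(names(defs))) stop("duplicate archetype names")
  if (spacing_um >= 8) stop("spacing_um must be < 8 (the contact radius)")
  comp <- t(vapply(defs, function(d) {
    unknown <- setdiff(names(d$mix), phenotypes)
    if (length(unknown))
      stop("unknown phenotype(s) in composition: ",
           paste(unknown, collapse = ", "))
    v <- setNames(rep(0.01, length(phenotypes)), phenotypes)
    v[names(d$mix)] <- v[names(d$mix)] + d$mix
    v / sum(v)
  }, numeric(length(phenotypes))))
  sizes <- t(vapply(defs, function(d) d$size, numeric(3)))
  colnames(sizes) <- c("min", "mode", "max")
  structure(list(names = names(defs), composition = comp,
                 size_distribution = sizes, spacing_um = spacing_um,
                 phenotypes = phenotypes),
            class = "structure_catalog_archetypes")
}

#' Build the default phenotype and structure archetype catalogs
#'
#' Returns the 16 TME + 16 epithelial phenotype expression archetypes and
#' the ten TME structure connectivity archetypes used by the synthetic
#' cohort generator. Phenotype profiles are validated to be well
#' separated (pairwise cosine similarity of log-mean vectors < 0.8).
#'
#' @param panel Marker panel; must cover the markers the catalogs use.
#' @return List with elements `tme`, `epithelial` (phenotype catalogs)
#'   and `structures` (structure archetype catalog).
#' @export
build_default_archetypes <- function(panel = default_panel()) {
  tme <- phenotype_catalog(panel, .tme_marker_sets(), "tme")
  epi <- phenotype_catalog(panel, .epi_marker_sets(), "epithelial")
  for (cat in list(tme, epi)) {
    lm <- cat$log_mean
    for (i in seq_len(nrow(lm) - 1)) for (j in (i + 1):nrow(lm)) {
      cs <- cosine_sim(lm[i, ], lm[j, ])
      if (cs >= 0.8)
        stop(sprintf("archetypes %s and %s are not well separated (cosine %.2f)",
                     cat$names[i], cat$names[j], cs))
    }
  }
  list(tme = tme, epithelial = epi, structures = structure_archetypes())
}

#' Draw raw marker counts for cells of given phenotype archetypes
#'
#' Counts are log-normal around the archetype log-mean (ion-count data
#' are right-skewed), shifted by a small offset and floored at zero so
#' genuinely negative markers yield exact zeros.
#'
#' @param catalog A `phenotype_catalog`.
#' @param phenotype Character vector of archetype names, one per cell.
#' @param offset Subtracted from the log-normal draw before flooring.
#' @return Matrix (cells x panel markers) of non-negative counts.
#' @export
draw_expression <- function(catalog, phenotype, offset = 0.2) {
  idx <- match(phenotype, catalog$names)
  if (anyNA(idx)) stop("unknown phenotype archetype")
  n <- length(idx); p <- ncol(catalog$log_mean)
  z <- matrix(rnorm(n * p), n, p)
  counts <- exp(catalog$log_mean[idx, , drop = FALSE] +
                z * catalog$log_sd[idx, , drop = FALSE]) - offset
  counts[counts < 0] <- 0
  colnames(counts) <- catalog$panel
  counts
}
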