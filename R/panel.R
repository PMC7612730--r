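#' Default 37-marker antibody panel
#'
#' Marker names for a breast-cancer imaging-mass-cytometry panel covering
#' cytokeratins and hormone receptors (epithelial heterogeneity), stromal,
#' myeloid and lymphoid lineage markers, antigen-presentation machinery,
#' immune checkpoints, and proliferation/apoptosis markers.
#'
#' @return Character vector of 37 marker names.
#' @export
default_panel <- function() {
  c("panCK", "CK5", "CK8_18", "HER2_3B5", "HER2_D8F12", "ER", "CXCL12",
    "HistoneH3", "SMA", "CD38", "HLA_DR", "CD15", "FSP1", "CD163", "ICOS",
    "OX40", "CD68", "CD3", "PDPN", "CD11c", "PD1", "GITR", "CD16",
    "CD45RA", "B2M", "CD45RO", "FOXP3", "CD20", "CD8", "CD57", "Ki67",
    "PDGFRB", "CAV1", "CD4", "CD31_vWF", "HLA_ABC", "cCASP3")
}

#' Compartment-specific clustering marker repertoires
#'
#' Phenotype clustering is run separately within the epithelial and TME
#' compartments, each on the markers informative for that compartment
#' (e.g. cytokeratins and hormone receptors for epithelial cells; immune
#' and stromal lineage markers for TME cells).
#'
#' @param compartment `"epithelial"` or `"tme"`.
#' @return Character vector of marker names.
#' @export
clustering_markers <- function(compartment = c("tme", "epithelial")) {
  compartment <- match.arg(compartment)
  if (compartment == "epithelial") {
    c("HistoneH3", "CK5", "HLA_DR", "CK8_18", "CD15", "HER2_3B5", "PDPN",
      "HER2_D8F12", "B2M", "ER", "CD57", "Ki67", "CXCL12", "HLA_ABC",
      "panCK", "cCASP3")
  } else {
    c("HistoneH3", "SMA", "CD38", "HLA_DR", "CD15", "FSP1", "CD163",
      "ICOS", "OX40", "CD68", "CD3", "PDPN", "CD11c", "PD1", "GITR",
      "CD16", "CD45RA", "B2M", "CD45RO", "FOXP3", "CD20", "CD8", "CD57",
      "Ki67", "PDGFRB", "CAV1", "CD4", "CD31_vWF", "HLA_ABC", "cCASP3")
  }
}
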