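## End-to-end orchestration. run_discovery() executes filtering,
## phenotyping, interface analysis, structure discovery, association and
## survival stages on a discovery cohort and writes every stage artifact
## as CSV/JSON to an output directory together with a run manifest;
## run_validation() phenotypes a validation cohort with the discovery
## catalogs and classifies its communities with the trained classifier.

write_stage_csv <- function(df, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the discovery pipeline on a synthetic or supplied cohort
#'
#' Stages: hot-pixel filtering, expression transformation, compartment
#' assignment, SOM phenotyping with profile-correlation merging,
#' interface flags and enrichment, contact-graph community detection,
#' connectivity profiles, consensus-clustering structure discovery,
#' random-forest classifier training, structure connection fractions,
#' and (when clinical data are generated) category discretization and
#' ER-stratified Cox models. All stage outputs and a manifest (seeds,
#' row counts, package version) are written to `out_dir`.
#'
#' @param config A `cohort_config` describing the cohort to simulate.
#' @param out_dir Output directory (created if missing).
#' @param k_range Candidate structure numbers (default 2:12).
#' @param min_size Minimum community size (default 10).
#' @param consensus_reps Consensus repetitions (default 50).
#' @return List of in-memory artifacts (invisible copies of what is
#'   written): cohort, phenotyped cells, communities, profiles, catalog,
#'   classifier, fractions, clinical results.
#' @export
run_discovery <- function(config, out_dir, k_range = 2:12, min_size = 10,
                          consensus_reps = 50) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  catalogs <- build_default_archetypes(config$panel)
  cohort <- generate_cohort(config, catalogs)
  cells <- filter_cells(cohort$cells)
  ## compartments via per-image GMM with tumor-mask fallback
  cells <- classify_epithelial(cells, method = "auto")
  ## phenotype the TME compartment
  tme_idx <- which(cells$compartment != "epithelial")
  markers <- clustering_markers("tme")
  expr <- transform_expression(as.matrix(
    as.data.frame(cells)[tme_idx, markers]))
  cl <- cluster_phenotypes(expr, markers, seed = config$seed)
  catalog_map <- merge_clusters(cl$profiles)
  cells$phenotype[tme_idx] <- catalog_map$phenotype[
    match(cl$cell_labels, as.integer(catalog_map$cluster_id))]
  cells$phenotype[cells$compartment == "epithelial"] <- "epithelial"
  ## graphs, interfaces, communities
  graphs <- build_contact_graph(cells)
  if (inherits(graphs, "spatial_graph"))
    graphs <- setNames(list(graphs), graphs$image_id)
  flags <- flag_interface_cells(cells, graphs)
  enr <- interface_enrichment(cells, flags, "tumor_stroma")
  tme_graphs <- lapply(graphs, function(g) split_compartment_graphs(g)$tme)
  communities <- do.call(rbind, lapply(tme_graphs, detect_communities,
                                       min_size = min_size))
  rownames(communities) <- NULL
  phenos <- sort(unique(cells$phenotype[tme_idx]))
  profiles <- connectivity_profile(communities, tme_graphs, phenos)
  k_range <- k_range[k_range <= nrow(profiles) - 1]
  catalog <- select_n_structures(profiles, k_range = k_range,
                                 reps = consensus_reps,
                                 seed = config$seed)
  classifier <- train_structure_classifier(
    scale_profiles(profiles, catalog$scale), catalog$labels,
    seed = config$seed)
  image_patient <- setNames(as.character(cells$patient_id),
                            as.character(cells$image_id))
  image_patient <- image_patient[!duplicated(names(image_patient))]
  fractions <- structure_connection_fractions(communities, catalog$labels,
                                              tme_graphs, image_patient)
  clinical <- generate_clinical(cohort)
  categories <- discretize_connectivity(fractions)
  clin_sub <- clinical[clinical$patient_id %in% fractions$patient_id, ]
  cox <- tryCatch(cox_structures(categories, clin_sub, "pos"),
                  error = function(e) NULL, warning = function(w)
                    suppressWarnings(cox_structures(categories, clin_sub,
                                                    "pos")))
  ## artifacts
  write_stage_csv(as.data.frame(cells), out_dir, "cells_phenotyped")
  write_stage_csv(communities, out_dir, "communities")
  write_stage_csv(data.frame(community_id = rownames(profiles), profiles,
                             check.names = FALSE), out_dir, "profiles")
  write_stage_csv(enr, out_dir, "interface_enrichment")
  write_stage_csv(fractions, out_dir, "structure_fractions")
  write_stage_csv(clinical, out_dir, "clinical")
  if (!is.null(cox)) write_stage_csv(cox, out_dir, "cox_er_pos")
  jsonlite::write_json(
    list(k = catalog$k,
         structure_names = rownames(catalog$centroids),
         centroids = as.data.frame(catalog$centroids),
         diagnostics = catalog$diagnostics,
         oob_accuracy = classifier$oob_accuracy),
    file.path(out_dir, "structure_catalog.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("tmestruct")),
                   seed = config$seed, n_images = config$n_images,
                   n_cells = nrow(cells),
                   n_communities = nrow(profiles),
                   k_selected = catalog$k,
                   stages = c("filter", "phenotype", "interfaces",
                              "discover", "associate", "survival"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, cells = cells, communities = communities,
                 profiles = profiles, catalog = catalog,
                 classifier = classifier, fractions = fractions,
                 interface_enrichment = enr, clinical = clinical,
                 cox = cox))
}

#' Classify a validation cohort with a discovery catalog
#'
#' Detects communities in the validation cohort, computes connectivity
#' profiles over the discovery phenotype set, classifies them with the
#' trained random-forest classifier, and writes a discovery-versus-
#' validation structure-proportion comparison.
#'
#' @param config `cohort_config` for the validation cohort (use a
#'   different seed than discovery).
#' @param discovery Output of [run_discovery()].
#' @param out_dir Output directory.
#' @return Invisible list with validation communities, profiles, labels
#'   and the proportion comparison table.
#' @export
run_validation <- function(config, discovery, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  phenos <- colnames(discovery$profiles)
  cohort <- generate_cohort(config)
  ## ground-truth compartments/phenotypes are withheld; rerun the
  ## discovery phenotyping path
  cells <- filter_cells(cohort$cells)
  cells <- classify_epithelial(cells, method = "auto")
  tme_idx <- which(cells$compartment != "epithelial")
  markers <- clustering_markers("tme")
  expr <- transform_expression(as.matrix(
    as.data.frame(cells)[tme_idx, markers]))
  cl <- cluster_phenotypes(expr, markers, seed = config$seed)
  ## align validation phenotype labels to discovery phenotypes by
  ## nearest discovery cluster profile (correlation)
  cells$phenotype[tme_idx] <- align_phenotypes(
    cl$profiles, cl$cell_labels, discovery)
  cells$phenotype[cells$compartment == "epithelial"] <- "epithelial"
  graphs <- build_contact_graph(cells)
  if (inherits(graphs, "spatial_graph"))
    graphs <- setNames(list(graphs), graphs$image_id)
  tme_graphs <- lapply(graphs, function(g) split_compartment_graphs(g)$tme)
  communities <- do.call(rbind, lapply(tme_graphs, detect_communities))
  if (is.null(communities) || nrow(communities) == 0) {
    empty <- data.frame()
    write_stage_csv(empty, out_dir, "validation_labels")
    return(invisible(list(communities = NULL, labels = character(0))))
  }
  rownames(communities) <- NULL
  profiles <- connectivity_profile(communities, tme_graphs, phenos)
  labels <- classify_structures(discovery$classifier,
                                scale_profiles(profiles,
                                               discovery$catalog$scale))
  disc_prop <- prop.table(table(discovery$catalog$labels))
  val_prop <- attr(labels, "proportions")
  all_s <- sort(union(names(disc_prop), names(val_prop)))
  comparison <- data.frame(
    structure = all_s,
    discovery = as.numeric(disc_prop[all_s]),
    validation = as.numeric(val_prop[all_s]))
  comparison[is.na(comparison)] <- 0
  write_stage_csv(data.frame(community_id = names(labels),
                             structure = as.character(labels)),
                  out_dir, "validation_labels")
  write_stage_csv(comparison, out_dir, "structure_proportions")
  invisible(list(communities = communities, profiles = profiles,
                 labels = labels, comparison = comparison))
}

## map validation cluster phenotype names onto the discovery phenotype
## vocabulary by highest profile correlation
align_phenotypes <- function(profiles, cell_labels, discovery) {
  disc_phenos <- colnames(discovery$profiles)
  ## discovery phenotype median expression over the clustering markers
  disc_cells <- discovery$cells
  markers <- colnames(profiles)
  tme <- disc_cells[disc_cells$compartment != "epithelial", ]
  expr <- transform_expression(as.matrix(as.data.frame(tme)[, markers]))
  disc_prof <- t(vapply(disc_phenos, function(ph)
    apply(expr[tme$phenotype == ph, , drop = FALSE], 2, median),
    numeric(ncol(expr))))
  cluster_pheno <- vapply(seq_len(nrow(profiles)), function(i) {
    cors <- apply(disc_prof, 1, function(r)
      suppressWarnings(cor(r, profiles[i, ])))
    disc_phenos[which.max(cors)]
  }, "")
  cluster_pheno[cell_labels]
}
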