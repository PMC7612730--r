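## Seed-deterministic synthetic cohort generator. Each image emulates a
## tissue-microarray spot: tumor nests of epithelial cells with a tumor
## region mask, vessels with a vessel mask and perivascular cells,
## planted multicellular TME structure instances (hexagonally packed at
## sub-contact spacing so each instance is a connected contact
## subgraph), and sparse background TME cells. Ground-truth phenotype
## and community labels are kept in a sidecar table so pipeline stages
## cannot consume them. Clinical outcomes and genomic labels are drawn
## from configurable structure-dependent hazard and logistic models.

#' Cohort generator configuration
#'
#' Defaults describe a breast-tumor TMA-spot cohort: 600 um square
#' images, 2-3 tumor nests, 3-6 vessels, 2-5 planted structure instances
#' drawn from the ten-archetype catalog, and sparse background TME
#' cells. Hazard multipliers (per-structure log-hazard coefficients on
#' connection fractions) and enrichment log-odds (per label, per
#' structure, on standardized fractions) default to zero, i.e. outcomes
#' independent of structure.
#'
#' @param n_images Number of images (one patient per image).
#' @param image_size_um Image edge length in micrometers.
#' @param structures_per_image Integer range `c(min, max)`.
#' @param n_background Background TME cells per image.
#' @param n_nests,nest_radius_um Tumor nest count range and radius range.
#' @param n_vessels,vessel_radius_um Vessel count range and radius range.
#' @param panel Marker panel.
#' @param seed Base seed; fixed seed implies identical output.
#' @param hazard_multipliers Named per-structure log-hazard coefficients.
#' @param baseline_hazard Baseline event rate per month.
#' @param censoring_rate Target censoring fraction in [0, 1].
#' @param enrichment_log_odds Named list: alteration -> named vector of
#'   per-structure log-odds on standardized fractions.
#' @param er_pos_rate,her2_pos_rate Marginal positivity rates.
#' @param hot_pixel_rate Fraction of cells flagged as hot-pixel-affected.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_images = 20, image_size_um = 600,
                          structures_per_image = c(2, 5),
                          n_background = 150,
                          n_nests = c(2, 3), nest_radius_um = c(50, 110),
                          n_vessels = c(3, 6), vessel_radius_um = c(8, 18),
                          panel = default_panel(), seed = 1,
                          hazard_multipliers = NULL,
                          baseline_hazard = 0.01, censoring_rate = 0.3,
                          enrichment_log_odds = list(),
                          er_pos_rate = 0.75, her2_pos_rate = 0.15,
                          hot_pixel_rate = 0.01) {
  stopifnot(n_images >= 1, image_size_um > 0, n_background >= 0,
            baseline_hazard > 0, censoring_rate >= 0, censoring_rate <= 1,
            hot_pixel_rate >= 0, hot_pixel_rate < 1)
  structure(as.list(environment()), class = "cohort_config")
}

## hexagonal-lattice blob: n points packed at `spacing` around a center,
## with a small uniform jitter that cannot break 8-um adjacency
hex_blob <- function(center, n, spacing, jitter = 0.7) {
  m <- ceiling(sqrt(n)) + 3
  ij <- expand.grid(i = -m:m, j = -m:m)
  x <- (ij$i + ij$j / 2) * spacing
  y <- ij$j * spacing * sqrt(3) / 2
  ord <- order(x^2 + y^2)
  x <- x[ord][seq_len(n)] + center[1]
  y <- y[ord][seq_len(n)] + center[2]
  cbind(x = x + runif(n, -jitter, jitter),
        y = y + runif(n, -jitter, jitter))
}

## paint filled disks into an integer raster (1 um pixels by default)
paint_disks <- function(grid, centers, radii, start_id = 1L) {
  nr <- nrow(grid); nc <- ncol(grid)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]; r <- radii[i]
    cols <- max(1, floor(cx - r)):min(nc, ceiling(cx + r))
    rows <- max(1, floor(cy - r)):min(nr, ceiling(cy + r))
    px <- outer((rows - 0.5) - cy, (cols - 0.5) - cx,
                function(dy, dx) sqrt(dx^2 + dy^2) <= r)
    grid[rows, cols][px] <- start_id + i - 1L
  }
  grid
}

## rejection-sample a point at least `min_dist[i]` from each `taken[i,]`
place_center <- function(size_um, margin, taken, min_dist, max_tries = 200) {
  for (t in seq_len(max_tries)) {
    p <- runif(2, margin, size_um - margin)
    if (nrow(taken) == 0 ||
        all(sqrt((taken[, 1] - p[1])^2 + (taken[, 2] - p[2])^2) >= min_dist))
      return(p)
  }
  NULL
}

#' Generate one synthetic image
#'
#' @param config A `cohort_config`.
#' @param catalogs Output of [build_default_archetypes()].
#' @param image_index Image number within the cohort.
#' @param seed Base seed (per-image stream derived from it).
#' @param planted_archetypes Optional character vector forcing the
#'   planted structure archetypes for this image.
#' @return List with `cells` (a `cell_table`), `truth` (sidecar
#'   data.frame with `true_phenotype`, `true_structure`,
#'   `true_community`), and `masks` (list of tumor and vessel
#'   `mask_grid`s).
#' @export
generate_image <- function(config, catalogs, image_index, seed = config$seed,
                           planted_archetypes = NULL) {
  withr::with_seed(derive_seed(seed, image_index), {
    size <- config$image_size_um
    image_id <- sprintf("img%03d", image_index)
    patient_id <- sprintf("P%04d", image_index)
    strs <- catalogs$structures
    ## choose planted structures and their sizes first (space check)
    if (is.null(planted_archetypes)) {
      n_str <- sample(config$structures_per_image[1]:
                      config$structures_per_image[2], 1)
      planted_archetypes <- sample(strs$names, n_str, replace = TRUE)
    }
    n_str <- length(planted_archetypes)
    sdist <- strs$size_distribution[planted_archetypes, , drop = FALSE]
    str_sizes <- pmax(3L, round(rtri(n_str, sdist[, "min"],
                                     sdist[, "mode"], sdist[, "max"])))
    str_radii <- strs$spacing_um * sqrt(str_sizes) / 1.6 + 8
    ## tumor nests
    n_nest <- sample(config$n_nests[1]:config$n_nests[2], 1)
    nest_r <- runif(n_nest, config$nest_radius_um[1],
                    config$nest_radius_um[2])
    taken <- matrix(numeric(0), 0, 2); taken_r <- numeric(0)
    nest_centers <- matrix(NA_real_, n_nest, 2)
    for (i in seq_len(n_nest)) {
      p <- place_center(size, nest_r[i] + 5, taken,
                        if (length(taken_r)) taken_r + nest_r[i] + 10 else 0)
      if (is.null(p)) { nest_centers <- nest_centers[seq_len(i - 1), , drop = FALSE]
                        nest_r <- nest_r[seq_len(i - 1)]; break }
      nest_centers[i, ] <- p
      taken <- rbind(taken, p); taken_r <- c(taken_r, nest_r[i])
    }
    n_nest <- nrow(nest_centers)
    ## structure centers, avoiding nests and each other
    str_centers <- matrix(NA_real_, n_str, 2)
    keep_str <- logical(n_str)
    for (i in seq_len(n_str)) {
      p <- place_center(size, str_radii[i] + 5, taken,
                        if (length(taken_r)) taken_r + str_radii[i] + 10 else 0)
      if (!is.null(p)) {
        str_centers[i, ] <- p; keep_str[i] <- TRUE
        taken <- rbind(taken, p); taken_r <- c(taken_r, str_radii[i])
      }
    }
    if (n_str > 0 && !any(keep_str))
      stop("image too small for requested content")
    planted_archetypes <- planted_archetypes[keep_str]
    str_sizes <- str_sizes[keep_str]
    str_centers <- str_centers[keep_str, , drop = FALSE]
    str_radii <- str_radii[keep_str]
    n_str <- length(planted_archetypes)
    ## vessels
    n_ves <- sample(config$n_vessels[1]:config$n_vessels[2], 1)
    ves_centers <- matrix(runif(2 * n_ves, 20, size - 20), n_ves, 2)
    ves_r <- runif(n_ves, config$vessel_radius_um[1],
                   config$vessel_radius_um[2])
    ## masks (1 um pixels)
    dim_px <- ceiling(size)
    tumor_grid <- matrix(0L, dim_px, dim_px)
    if (n_nest > 0)
      tumor_grid <- paint_disks(tumor_grid, nest_centers[, c(1, 2),
                                drop = FALSE], nest_r)
    vessel_grid <- paint_disks(matrix(0L, dim_px, dim_px),
                               ves_centers, ves_r)
    ## --- cells ---
    xs <- list(); phenos <- list(); comps <- list()
    structs <- list(); comm <- list()
    ## epithelial cells inside nests (hex at 9 um)
    epi_arch <- sample(catalogs$epithelial$names, min(3, 16))
    for (i in seq_len(n_nest)) {
      n_epi <- max(5L, round(0.55 * (nest_r[i] / 9)^2 * pi * 0.9))
      pts <- hex_blob(nest_centers[i, ], n_epi, 9, jitter = 1.2)
      xs[[length(xs) + 1]] <- pts
      phenos[[length(phenos) + 1]] <- sample(epi_arch, n_epi, replace = TRUE)
      comps[[length(comps) + 1]] <- rep("epithelial", n_epi)
      structs[[length(structs) + 1]] <- rep(NA_character_, n_epi)
      comm[[length(comm) + 1]] <- rep(NA_character_, n_epi)
    }
    ## perivascular cells on vessel rims
    pv_mix <- c(Endothelial = 0.5, CD38_lymphocytes = 0.2,
                Myofibroblasts = 0.15, T_CD4 = 0.15)
    for (i in seq_len(n_ves)) {
      n_pv <- max(3L, round(ves_r[i] / 2))
      ang <- runif(n_pv, 0, 2 * pi)
      rr <- ves_r[i] + runif(n_pv, -2, 3)
      pts <- cbind(x = ves_centers[i, 1] + rr * cos(ang),
                   y = ves_centers[i, 2] + rr * sin(ang))
      xs[[length(xs) + 1]] <- pts
      phenos[[length(phenos) + 1]] <- sample(names(pv_mix), n_pv,
                                             replace = TRUE, prob = pv_mix)
      comps[[length(comps) + 1]] <- rep("tme", n_pv)
      structs[[length(structs) + 1]] <- rep(NA_character_, n_pv)
      comm[[length(comm) + 1]] <- rep(NA_character_, n_pv)
    }
    ## planted structure instances
    for (i in seq_len(n_str)) {
      arch <- planted_archetypes[i]
      pts <- hex_blob(str_centers[i, ], str_sizes[i], strs$spacing_um)
      xs[[length(xs) + 1]] <- pts
      phenos[[length(phenos) + 1]] <- sample(strs$phenotypes, str_sizes[i],
        replace = TRUE, prob = strs$composition[arch, ])
      comps[[length(comps) + 1]] <- rep("tme", str_sizes[i])
      structs[[length(structs) + 1]] <- rep(arch, str_sizes[i])
      comm[[length(comm) + 1]] <- rep(sprintf("%s_t%02d", image_id, i),
                                      str_sizes[i])
    }
    ## background TME cells, kept clear of planted structures
    bg_mix <- c(Fibroblasts = 0.25, Myofibroblasts = 0.15, T_CD4 = 0.12,
                Macrophages = 0.12, T_CD8 = 0.10, Endothelial = 0.08,
                Fibroblasts_FSP1 = 0.08, B_cells = 0.05,
                Granulocytes = 0.05)
    n_bg <- config$n_background
    if (n_bg > 0) {
      bg <- matrix(runif(2 * n_bg * 3, 1, size - 1), ncol = 2)
      if (n_str > 0) {
        ok <- apply(bg, 1, function(p)
          all(sqrt((str_centers[, 1] - p[1])^2 +
                   (str_centers[, 2] - p[2])^2) > str_radii + 10))
        bg <- bg[ok, , drop = FALSE]
      }
      bg <- bg[seq_len(min(n_bg, nrow(bg))), , drop = FALSE]
      xs[[length(xs) + 1]] <- bg
      phenos[[length(phenos) + 1]] <- sample(names(bg_mix), nrow(bg),
                                             replace = TRUE, prob = bg_mix)
      comps[[length(comps) + 1]] <- rep("tme", nrow(bg))
      structs[[length(structs) + 1]] <- rep(NA_character_, nrow(bg))
      comm[[length(comm) + 1]] <- rep(NA_character_, nrow(bg))
    }
    xy <- do.call(rbind, xs)
    xy[, 1] <- pmin(pmax(xy[, 1], 0.5), size - 0.5)
    xy[, 2] <- pmin(pmax(xy[, 2], 0.5), size - 0.5)
    pheno <- unlist(phenos); compartment <- unlist(comps)
    n_cells <- nrow(xy)
    counts <- matrix(0, n_cells, length(config$panel),
                     dimnames = list(NULL, config$panel))
    is_epi <- compartment == "epithelial"
    if (any(is_epi))
      counts[is_epi, ] <- draw_expression(catalogs$epithelial,
                                          pheno[is_epi])
    if (any(!is_epi))
      counts[!is_epi, ] <- draw_expression(catalogs$tme, pheno[!is_epi])
    df <- data.frame(image_id = image_id, patient_id = patient_id,
                     cell_id = seq_len(n_cells),
                     x_um = xy[, 1], y_um = xy[, 2],
                     counts, check.names = FALSE,
                     hot_pixel_flag = runif(n_cells) < config$hot_pixel_rate,
                     stringsAsFactors = FALSE)
    cells <- cell_table(df, config$panel)
    tumor_mask <- mask_grid(image_id, "tumor", tumor_grid, 1)
    vessel_mask <- mask_grid(image_id, "vessel", vessel_grid, 1)
    cells <- attach_mask_overlap(cells, tumor_mask, contact_um = 8)
    cells <- attach_mask_overlap(cells, vessel_mask, contact_um = 8)
    truth <- data.frame(image_id = image_id, patient_id = patient_id,
                        cell_id = seq_len(n_cells),
                        true_phenotype = pheno,
                        true_compartment = compartment,
                        true_structure = unlist(structs),
                        true_community = unlist(comm),
                        stringsAsFactors = FALSE)
    list(cells = cells, truth = truth,
         masks = list(tumor = tumor_mask, vessel = vessel_mask))
  })
}

#' Generate a synthetic cohort
#'
#' Generates `config$n_images` images (one patient each), guaranteeing
#' that with enough images every structure archetype is planted at least
#' once, and computes ground-truth per-patient structure connection
#' fractions from the realized TME contact graphs.
#'
#' @param config A `cohort_config`.
#' @param catalogs Archetype catalogs (default
#'   [build_default_archetypes()]).
#' @return List with `cells` (cohort `cell_table`), `truth`, `masks`
#'   (per image), `tme_graphs` (per image, ground-truth compartments,
#'   perivascular excluded), `fractions` (ground-truth structure
#'   connection fractions), `image_patient`, and `config`.
#' @export
generate_cohort <- function(config,
                            catalogs = build_default_archetypes(config$panel)) {
  strs <- catalogs$structures
  ## round-robin base assignment so every archetype appears when
  ## n_images * min structures >= catalog size
  plan <- withr::with_seed(derive_seed(config$seed, 0), {
    lapply(seq_len(config$n_images), function(i) {
      n_i <- sample(config$structures_per_image[1]:
                    config$structures_per_image[2], 1)
      first <- strs$names[(i - 1) %% length(strs$names) + 1]
      c(first, sample(strs$names, n_i - 1, replace = TRUE))
    })
  })
  images <- lapply(seq_len(config$n_images), function(i)
    generate_image(config, catalogs, i, seed = config$seed,
                   planted_archetypes = plan[[i]]))
  cells <- do.call(rbind, lapply(images, function(im)
    as.data.frame(im$cells)))
  cells <- cell_table(cells, config$panel)
  truth <- do.call(rbind, lapply(images, `[[`, "truth"))
  masks <- lapply(images, `[[`, "masks")
  names(masks) <- vapply(images, function(im) im$cells$image_id[1], "")
  ## ground-truth TME graphs (truth compartments, perivascular excluded)
  tme_graphs <- list()
  for (im in images) {
    tab <- im$cells
    tab$compartment <- im$truth$true_compartment
    tab$phenotype <- im$truth$true_phenotype
    g <- build_contact_graph(tab, radius_um = 8)
    tme_graphs[[tab$image_id[1]]] <- split_compartment_graphs(g)$tme
  }
  image_patient <- setNames(vapply(images, function(im)
    im$cells$patient_id[1], ""), names(masks))
  ## ground-truth communities = planted instances (TME graph members)
  gt_comm <- truth[!is.na(truth$true_community), ]
  gt_comm <- data.frame(image_id = gt_comm$image_id,
                        community_id = gt_comm$true_community,
                        cell_id = as.character(gt_comm$cell_id),
                        structure = gt_comm$true_structure,
                        stringsAsFactors = FALSE)
  ## planted cells flagged perivascular are outside the TME graph
  in_graph <- mapply(function(img, cid)
    cid %in% tme_graphs[[img]]$vertices$cell_id,
    gt_comm$image_id, gt_comm$cell_id)
  gt_comm <- gt_comm[in_graph, ]
  labels <- setNames(
    gt_comm$structure[!duplicated(gt_comm$community_id)],
    gt_comm$community_id[!duplicated(gt_comm$community_id)])
  fractions <- structure_connection_fractions(gt_comm, labels, tme_graphs,
                                              image_patient)
  ## patients can drop out (0 TME edges); ensure all structures present
  for (s in setdiff(strs$names, names(fractions)))
    fractions[[s]] <- 0
  list(cells = cells, truth = truth, masks = masks,
       tme_graphs = tme_graphs, fractions = fractions,
       ground_truth_communities = gt_comm,
       image_patient = image_patient, config = config)
}

#' Generate a clinical table for a synthetic cohort
#'
#' Survival times are exponential with log-hazard equal to the inner
#' product of `config$hazard_multipliers` with the patient's structure
#' connection fractions; censoring is independent exponential calibrated
#' to the configured censoring rate. ER and HER2 status are Bernoulli
#' with the configured rates.
#'
#' @param cohort Output of [generate_cohort()].
#' @param config The cohort's `cohort_config` (default taken from it).
#' @param seed Integer seed.
#' @return Clinical data.frame (see [read_clinical()]).
#' @export
generate_clinical <- function(cohort, config = cohort$config,
                              seed = config$seed) {
  fr <- cohort$fractions
  structures <- setdiff(names(fr), c("patient_id", "total_connections"))
  hm <- setNames(rep(0, length(structures)), structures)
  if (!is.null(config$hazard_multipliers)) {
    known <- intersect(names(config$hazard_multipliers), structures)
    hm[known] <- config$hazard_multipliers[known]
  }
  withr::with_seed(derive_seed(seed, 9001), {
    n <- nrow(fr)
    lp <- as.matrix(fr[structures]) %*% hm
    rate <- config$baseline_hazard * exp(lp)
    t_event <- rexp(n, rate)
    cr <- config$censoring_rate
    if (cr >= 1) {
      time <- t_event; event <- rep(0L, n)
    } else if (cr <= 0) {
      time <- t_event; event <- rep(1L, n)
    } else {
      t_cens <- rexp(n, config$baseline_hazard * cr / (1 - cr))
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    }
    data.frame(patient_id = fr$patient_id,
               er_status = ifelse(runif(n) < config$er_pos_rate,
                                  "pos", "neg"),
               her2_status = ifelse(runif(n) < config$her2_pos_rate,
                                    "pos", "neg"),
               dss_time_months = pmax(time, 0.01), dss_event = event,
               intrinsic_subtype = sample(c("LumA", "LumB", "HER2",
                                            "Basal", "Normal"), n, TRUE),
               intclust = paste0("IC", sample(1:10, n, TRUE)),
               stringsAsFactors = FALSE)
  })
}

#' Generate genomic labels for a synthetic cohort
#'
#' Binary alteration indicators are drawn from logistic models whose
#' linear predictor adds the configured per-structure enrichment
#' log-odds applied to standardized structure connection fractions;
#' alterations without configured enrichment are independent of
#' structure.
#'
#' @param cohort Output of [generate_cohort()].
#' @param config The cohort's `cohort_config`.
#' @param seed Integer seed.
#' @param alteration_names Alteration columns to generate.
#' @return Binary patient x alteration matrix with an `alteration_kind`
#'   attribute (mutation/gain/loss per column).
#' @export
generate_genomics <- function(cohort, config = cohort$config,
                              seed = config$seed,
                              alteration_names = default_alterations()) {
  fr <- cohort$fractions
  structures <- setdiff(names(fr), c("patient_id", "total_connections"))
  z <- scale(as.matrix(fr[structures]))
  z[is.nan(z)] <- 0
  withr::with_seed(derive_seed(seed, 9002), {
    n <- nrow(fr)
    prev <- runif(length(alteration_names), 0.05, 0.3)
    m <- vapply(seq_along(alteration_names), function(j) {
      eta <- rep(qlogis(prev[j]), n)
      lo <- config$enrichment_log_odds[[alteration_names[j]]]
      if (!is.null(lo)) {
        known <- intersect(names(lo), structures)
        eta <- eta + as.vector(z[, known, drop = FALSE] %*% lo[known])
      }
      rbinom(n, 1, plogis(eta))
    }, integer(n))
    colnames(m) <- alteration_names
    rownames(m) <- fr$patient_id
    attr(m, "alteration_kind") <- setNames(
      sample(c("mutation", "gain", "loss"), length(alteration_names),
             replace = TRUE), alteration_names)
    m
  })
}

#' Default synthetic alteration names
#' @return Character vector of 40 alteration labels.
#' @export
default_alterations <- function() {
  c("TP53_mut", "PIK3CA_mut", "BRCA1_mut", "BRCA2_mut", "CASP8_mut",
    "CDH1_mut", "GATA3_mut", "MAP3K1_mut", "AKT1_mut", "PTEN_mut",
    "KMT2C_mut", "NF1_mut", "RB1_mut", "ARID1A_mut", "CBFB_mut",
    "ERBB2_gain", "CCND1_gain", "MYC_gain", "CCNE1_gain", "ZNF703_gain",
    "CD274_gain", "IGF1R_gain", "MDM2_gain", "FGFR1_gain", "EGFR_gain",
    "ZNF217_gain", "RPS6KB1_gain", "AURKA_gain", "MCL1_gain", "AKT2_gain",
    "B2M_loss", "PTEN_loss", "MAP2K4_loss", "MTAP_loss", "PPP2R2A_loss",
    "CDKN2AIP_loss", "RB1_loss", "CDKN2A_loss", "TP53_loss", "NF1_loss")
}
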