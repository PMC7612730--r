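## Tissue-interface analysis: flag TME cells in contact with the
## tumor-stroma interface (at least one epithelial contact) or the
## perivascular space (vessel-mask contact), then estimate per-phenotype
## enrichment or depletion at each interface with weighted binomial
## logit models across tumors.

#' Flag TME cells at tissue interfaces
#'
#' A TME cell is at the tumor-stroma interface when it contacts at least
#' one epithelial cell in the full contact graph, and perivascular when
#' it is related to a vessel mask. Flags are emitted for TME cells only;
#' a cell may carry both.
#'
#' @param table A `cell_table` with compartments assigned and vessel
#'   overlap attached.
#' @param graph `spatial_graph` over all cells (or named list per image).
#' @return Data frame `image_id`, `cell_id`, `at_tumor_stroma`,
#'   `perivascular` for TME cells.
#' @export
flag_interface_cells <- function(table, graph) {
  graphs <- if (inherits(graph, "spatial_graph"))
    setNames(list(graph), graph$image_id) else graph
  out <- lapply(unique(table$image_id), function(im) {
    sub <- table[table$image_id == im, ]
    g <- graphs[[as.character(im)]]
    if (is.null(g)) stop("no graph for image ", im)
    if (!all(as.character(sub$cell_id) %in% g$vertices$cell_id))
      stop("graph does not cover all cells of image ", im)
    epi_ids <- as.character(sub$cell_id[sub$compartment == "epithelial"])
    e <- g$edges
    touches_epi <- unique(c(e[e[, 2] %in% epi_ids, 1],
                            e[e[, 1] %in% epi_ids, 2]))
    tme <- sub[sub$compartment != "epithelial", ]
    data.frame(image_id = im, cell_id = as.character(tme$cell_id),
               at_tumor_stroma = as.character(tme$cell_id) %in% touches_epi,
               perivascular = tme$in_vessel_mask,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-phenotype enrichment at a tissue interface
#'
#' For each TME phenotype, fits a binomial-logit GLM of the phenotype's
#' proportion among TME cells against interface membership, across
#' (tumor x membership) strata, with the stratum cell total as the
#' binomial denominator so that tumors contributing more cells carry
#' proportionally more weight. Tumors lacking the phenotype entirely are
#' excluded from that phenotype's model; phenotypes present in fewer
#' than two tumors are skipped. P values are Benjamini-Hochberg adjusted
#' across the phenotypes of one interface analysis.
#'
#' @param table A `cell_table` (TME cells are selected internally).
#' @param flags Output of [flag_interface_cells()].
#' @param which `"tumor_stroma"` or `"perivascular"`.
#' @param group Column grouping images into tumors (default
#'   `"patient_id"`).
#' @return Data frame with phenotype, log-odds estimate, standard error,
#'   95% CI, raw and adjusted p, and `n_tumors_included`.
#' @export
interface_enrichment <- function(table, flags,
                                 which = c("tumor_stroma", "perivascular"),
                                 group = "patient_id") {
  which <- match.arg(which)
  flag_col <- if (which == "tumor_stroma") "at_tumor_stroma"
              else "perivascular"
  tme <- table[table$compartment != "epithelial", ]
  key <- paste(tme$image_id, tme$cell_id)
  fkey <- paste(flags$image_id, flags$cell_id)
  tme$at_interface <- flags[[flag_col]][match(key, fkey)]
  if (anyNA(tme$at_interface)) stop("flags do not cover all TME cells")
  tme$tumor <- tme[[group]]
  phenos <- sort(unique(tme$phenotype))
  rows <- list()
  for (ph in phenos) {
    ## stratum counts: phenotype cells and totals per tumor x membership
    tot <- aggregate(list(n = rep(1L, nrow(tme))),
                     tme[c("tumor", "at_interface")], sum)
    hit <- aggregate(list(k = as.integer(tme$phenotype == ph)),
                     tme[c("tumor", "at_interface")], sum)
    d <- merge(tot, hit)
    present <- unique(d$tumor[d$k > 0])
    if (length(present) < 2) {
      message(sprintf("interface_enrichment: phenotype %s present in < 2 tumors; skipped", ph))
      next
    }
    d <- d[d$tumor %in% present, ]
    fit <- glm(cbind(k, n - k) ~ at_interface, family = binomial(), data = d)
    sm <- summary(fit)$coefficients
    est <- sm["at_interfaceTRUE", "Estimate"]
    se <- sm["at_interfaceTRUE", "Std. Error"]
    rows[[ph]] <- data.frame(phenotype = ph, estimate = est, se = se,
                             ci_lo = est - 1.96 * se,
                             ci_hi = est + 1.96 * se,
                             p = sm["at_interfaceTRUE", "Pr(>|z|)"],
                             n_tumors_included = length(present),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out)) out$p_adj <- p.adjust(out$p, method = "BH")
  out
}
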