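## Associations between TME structure burden and genomic labels.
## Structure burden per patient is the fraction of all TME cell-cell
## connections occupied by each structure; enrichment against binary
## labels uses weighted binomial-logit GLMs, and the predictive value of
## feature categories is compared with L1-regularized logistic
## regression and out-of-sample AUC.

#' Per-patient structure connection fractions
#'
#' For each patient, the fraction of all TME connections (cell-cell
#' contacts) occupied by each structure: connection endpoints within
#' communities of that structure divided by twice the patient's total
#' TME edge count. Patients with zero TME edges are excluded.
#'
#' @param communities Data frame from [detect_communities()] (cohort).
#' @param structure_labels Named vector, community id -> structure.
#' @param tme_graphs Named list of per-image TME `spatial_graph`s.
#' @param image_patient Named vector mapping image id -> patient id.
#' @return Data frame: `patient_id`, one fraction column per structure,
#'   `total_connections` (2 x total TME edges, the model weight).
#' @export
structure_connection_fractions <- function(communities, structure_labels,
                                           tme_graphs, image_patient) {
  structures <- sort(unique(unname(structure_labels)))
  img_ids <- names(tme_graphs)
  patients <- unique(unname(image_patient[img_ids]))
  frac <- matrix(0, length(patients), length(structures),
                 dimnames = list(patients, structures))
  totals <- setNames(numeric(length(patients)), patients)
  internal <- setNames(numeric(length(patients)), patients)
  for (im in img_ids) {
    p <- as.character(image_patient[[im]])
    totals[p] <- totals[p] + 2 * nrow(tme_graphs[[im]]$edges)
  }
  for (cid in unique(communities$community_id)) {
    sub <- communities[communities$community_id == cid, ]
    im <- as.character(sub$image_id[1])
    p <- as.character(image_patient[[im]])
    g <- tme_graphs[[im]]
    e <- g$edges
    n_int <- sum(e[, 1] %in% sub$cell_id & e[, 2] %in% sub$cell_id)
    s <- unname(structure_labels[cid])
    if (is.na(s)) stop("community without structure label: ", cid)
    frac[p, s] <- frac[p, s] + 2 * n_int
  }
  no_edges <- totals == 0
  if (any(no_edges))
    message(sprintf("structure_connection_fractions: excluded %d patient(s) with 0 TME edges",
                    sum(no_edges)))
  keep <- !no_edges
  frac <- frac[keep, , drop = FALSE] / totals[keep]
  out <- data.frame(patient_id = rownames(frac), frac,
                    total_connections = unname(totals[keep]),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Structure enrichment against a binary label
#'
#' For each structure, fits a binomial-logit GLM of the patient's
#' structure connection fraction on the binary label, using the total
#' connection count as the binomial denominator so tumors with more
#' measured contacts carry more weight. Estimates are the log-odds
#' difference in structure burden between label-positive and -negative
#' tumors; p values are BH-adjusted across the tested family.
#'
#' @param fractions Output of [structure_connection_fractions()].
#' @param label Named (by patient id) binary vector (0/1 or logical).
#' @return Data frame per structure with estimate, se, CI, p, p_adj and
#'   a `note` column flagging separation.
#' @export
enrichment_glm <- function(fractions, label) {
  lab <- label[match(fractions$patient_id, names(label))]
  if (anyNA(lab)) stop("label missing for some patients")
  lab <- as.integer(lab)
  if (length(unique(lab)) < 2) stop("label is constant")
  structures <- setdiff(names(fractions),
                        c("patient_id", "total_connections"))
  tot <- round(fractions$total_connections)
  rows <- lapply(structures, function(s) {
    k <- round(fractions[[s]] * fractions$total_connections)
    fit <- glm(cbind(k, tot - k) ~ lab, family = binomial())
    sm <- summary(fit)$coefficients
    est <- sm["lab", "Estimate"]; se <- sm["lab", "Std. Error"]
    note <- if (abs(est) > 10 || se > 10) "possible separation" else ""
    data.frame(structure = s, estimate = est, se = se,
               ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
               p = sm["lab", "Pr(>|z|)"], note = note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Per-patient feature tables by category
#'
#' Builds the predictor categories compared in the association stage:
#' phenotype proportions per compartment, structure connection
#' fractions, per-patient summaries (mean, median, max) of the six
#' community network properties, and their concatenation. Patients
#' without communities get zero-imputed network features plus an
#' indicator flag.
#'
#' @param table Phenotyped `cell_table` for the cohort.
#' @param fractions Output of [structure_connection_fractions()].
#' @param communities,graphs Community table and per-image graph list.
#' @param compartment Compartment for phenotype proportions and network
#'   summaries (`"tme"` or `"epithelial"`).
#' @return Named list of matrices: `cell_phenotype`, `structure`,
#'   `network_properties`, `combined` (patients x features).
#' @export
build_feature_tables <- function(table, fractions, communities, graphs,
                                 compartment = "tme") {
  cells <- if (compartment == "epithelial")
    table[table$compartment == "epithelial", ]
  else table[table$compartment != "epithelial", ]
  patients <- sort(unique(as.character(table$patient_id)))
  phenos <- sort(unique(cells$phenotype))
  prop <- matrix(0, length(patients), length(phenos),
                 dimnames = list(patients, paste0("prop_", phenos)))
  tab <- table(as.character(cells$patient_id), cells$phenotype)
  tab <- tab / pmax(rowSums(tab), 1)
  prop[rownames(tab), paste0("prop_", colnames(tab))] <- tab
  structures <- setdiff(names(fractions),
                        c("patient_id", "total_connections"))
  sf <- matrix(0, length(patients), length(structures),
               dimnames = list(patients, paste0("frac_", structures)))
  sf[fractions$patient_id, ] <- as.matrix(fractions[structures])
  np <- community_network_properties(communities, graphs)
  img_patient <- setNames(as.character(table$patient_id),
                          as.character(table$image_id))
  img_patient <- img_patient[!duplicated(names(img_patient))]
  comm_patient <- img_patient[as.character(
    communities$image_id[match(np$community_id, communities$community_id)])]
  stats_names <- as.vector(outer(np_names, c("mean", "median", "max"),
                                 function(a, b) paste0(b, "_", a)))
  nps <- matrix(0, length(patients), length(stats_names) + 1,
                dimnames = list(patients, c(stats_names, "no_communities")))
  nps[, "no_communities"] <- 1
  for (p in intersect(unique(comm_patient), patients)) {
    sub <- np[comm_patient == p, np_names, drop = FALSE]
    sub[is.na(sub)] <- 0
    vals <- c(apply(sub, 2, mean), apply(sub, 2, median),
              apply(sub, 2, max))
    nps[p, stats_names] <- vals
    nps[p, "no_communities"] <- 0
  }
  list(cell_phenotype = prop, structure = sf, network_properties = nps,
       combined = cbind(prop, sf, nps))
}

#' Out-of-sample prediction of binary labels by feature category
#'
#' Fits an L1-regularized logistic regression (penalty chosen by
#' cross-validation on the training patients) for each feature category
#' and reports the AUC on the held-out test patients.
#'
#' @param features Named list of patient x feature matrices (e.g. from
#'   [build_feature_tables()]).
#' @param label Named binary vector (by patient id).
#' @param train_ids,test_ids Disjoint patient id sets.
#' @param seed Integer seed (cross-validation folds).
#' @return Data frame: feature category, test AUC, n_train, n_test.
#' @export
fit_label_predictors <- function(features, label, train_ids, test_ids,
                                 seed = 1) {
  if (length(intersect(train_ids, test_ids)))
    stop("train and test sets overlap")
  rows <- lapply(names(features), function(cat) {
    x <- features[[cat]]
    ytr <- label[train_ids]; yte <- label[test_ids]
    if (length(unique(ytr)) < 2) stop("single class in training labels")
    keep <- apply(x[train_ids, , drop = FALSE], 2, var) > 0
    xtr <- x[train_ids, keep, drop = FALSE]
    xte <- x[test_ids, keep, drop = FALSE]
    fit <- withr::with_seed(derive_seed(seed, 1),
      glmnet::cv.glmnet(xtr, ytr, family = "binomial", alpha = 1,
                        nfolds = 5))
    pred <- as.numeric(predict(fit, xte, s = "lambda.min",
                               type = "response"))
    auc <- if (length(unique(yte)) < 2) NA_real_ else
      as.numeric(pROC::auc(pROC::roc(yte, pred, quiet = TRUE,
                                     direction = "<")))
    data.frame(category = cat, auc = auc, n_train = length(train_ids),
               n_test = length(test_ids), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Derive HER2 status from an expression value per patient
#'
#' Two-component Gaussian mixture on the expression vector; patients in
#' the higher-mean component are called positive. A degenerate unimodal
#' fit yields all-negative with a warning.
#'
#' @param expression Numeric vector (>= 20 patients).
#' @return Character vector `"pos"`/`"neg"`.
#' @export
her2_from_expression <- function(expression) {
  if (length(expression) < 20) stop("need >= 20 patients")
  hi <- if (length(unique(expression)) < 3) NULL
        else gmm_high_component(expression)
  if (is.null(hi)) {
    warning("degenerate mixture fit; all patients called HER2-negative")
    return(rep("neg", length(expression)))
  }
  ifelse(hi, "pos", "neg")
}

#' Filter alterations by minimum carrier count
#'
#' Drops alteration columns carried by fewer than `min_carriers`
#' patients.
#'
#' @param matrix Binary patient x alteration matrix.
#' @param min_carriers Minimum number of carriers (default 5).
#' @return The filtered matrix.
#' @export
filter_alterations <- function(matrix, min_carriers = 5) {
  matrix[, colSums(matrix) >= min_carriers, drop = FALSE]
}
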