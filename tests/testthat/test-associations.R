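## two-image toy world: patient P1's community holds all TME edges,
## patient P2 has edges but no community
toy_fraction_world <- function() {
  g1 <- graph_from_coords(c(0, 5, 10), c(0, 0, 0), image_id = "imgA")
  g2 <- graph_from_coords(c(0, 5), c(0, 0), image_id = "imgB")
  comms <- data.frame(image_id = "imgA", community_id = "imgA_c01",
                      cell_id = c("1", "2", "3"))
  list(graphs = list(imgA = g1, imgB = g2), comms = comms,
       labels = c(imgA_c01 = "S1"),
       image_patient = c(imgA = "P1", imgB = "P2"))
}

test_that("structure connection fractions count edge endpoints per patient", {
  w <- toy_fraction_world()
  fr <- structure_connection_fractions(w$comms, w$labels, w$graphs,
                                       w$image_patient)
  expect_equal(fr$S1[fr$patient_id == "P1"], 1)   # community holds all edges
  expect_equal(fr$S1[fr$patient_id == "P2"], 0)   # no communities
  expect_equal(fr$total_connections, c(4, 2))

  ## cross-check: fractions recomputed from profiles match edge counts
  profs <- connectivity_profile(w$comms, w$graphs, c("A"))
  expect_equal(sum(profs) / fr$total_connections[1],
               fr$S1[fr$patient_id == "P1"])
})

test_that("patients without TME edges are excluded", {
  w <- toy_fraction_world()
  lone <- graph_from_coords(c(0, 100), c(0, 0), image_id = "imgC")
  w$graphs$imgC <- lone
  w$image_patient <- c(w$image_patient, imgC = "P3")
  fr <- suppressMessages(structure_connection_fractions(
    w$comms, w$labels, w$graphs, w$image_patient))
  expect_false("P3" %in% fr$patient_id)
})

test_that("enrichment GLM recovers planted log-odds and is antisymmetric", {
  set.seed(31)
  n <- 300
  label <- rbinom(n, 1, 0.5)
  p0 <- plogis(-3); p1 <- plogis(-3 + 1)
  fr <- simulate_fractions_accept(n, c(p0, p1), label)
  names(label) <- fr$patient_id
  res <- enrichment_glm(fr, label)
  expect_equal(res$estimate, 1, tolerance = 0.15)
  expect_lt(res$p_adj, 0.001)

  flipped <- enrichment_glm(fr, setNames(1 - label, names(label)))
  expect_equal(flipped$estimate, -res$estimate, tolerance = 1e-9)

  expect_error(enrichment_glm(fr, setNames(rep(1, n), fr$patient_id)),
               "constant")
})

test_that("feature tables are rectangular with unit phenotype proportions", {
  co <- small_cohort()
  comms <- do.call(rbind, lapply(co$tme_graphs, detect_communities))
  profs <- connectivity_profile(comms, co$tme_graphs)
  fit <- assign_structures(profs, k = 4)
  ip <- co$image_patient
  fr <- suppressMessages(structure_connection_fractions(
    comms, fit$labels, co$tme_graphs, ip))
  cells <- co$cells
  cells$compartment <- co$truth$true_compartment
  cells$phenotype <- co$truth$true_phenotype
  ft <- build_feature_tables(cells, fr, comms, co$tme_graphs)
  ## constant width across patients, no missing values
  for (m in ft) {
    expect_false(anyNA(m))
    expect_equal(nrow(m), length(unique(cells$patient_id)))
  }
  expect_equal(unname(rowSums(ft$cell_phenotype)),
               rep(1, nrow(ft$cell_phenotype)), tolerance = 1e-9)
  expect_equal(ncol(ft$combined),
               ncol(ft$cell_phenotype) + ncol(ft$structure) +
                 ncol(ft$network_properties))
})

test_that("label prediction ranks the generating feature category first", {
  set.seed(32)
  n <- 500
  ids <- paste0("P", seq_len(n))
  informative <- matrix(rnorm(n * 5), n, 5,
                        dimnames = list(ids, paste0("f", 1:5)))
  noise <- matrix(rnorm(n * 5), n, 5,
                  dimnames = list(ids, paste0("g", 1:5)))
  label <- setNames(rbinom(n, 1, plogis(2 * informative[, 1])), ids)
  train <- ids[1:300]; test <- ids[301:500]
  res <- fit_label_predictors(list(structure = informative,
                                   cell_phenotype = noise),
                              label, train, test, seed = 4)
  auc <- setNames(res$auc, res$category)
  expect_gt(auc["structure"], auc["cell_phenotype"])
  expect_gt(auc["structure"], 0.75)
  expect_true(auc["cell_phenotype"] > 0.35 && auc["cell_phenotype"] < 0.65)

  ## perfectly separable label
  sep <- setNames(as.integer(informative[, 2] > 0), ids)
  res2 <- fit_label_predictors(list(structure = informative), sep,
                               train, test, seed = 4)
  expect_gte(res2$auc, 0.95)

  expect_error(fit_label_predictors(list(a = informative), label,
                                    train, c(train[1], test)), "overlap")
})

test_that("HER2 calls derive from the mixture's high component", {
  set.seed(33)
  x <- c(rnorm(40, -1, 0.3), rnorm(40, 3, 0.3))
  call <- her2_from_expression(x)
  expect_true(all(call[41:80] == "pos"))
  expect_true(all(call[1:40] == "neg"))
  ## invariant to affine rescaling
  expect_identical(her2_from_expression(2 * x + 1), call)
  expect_warning(all_neg <- her2_from_expression(rep(1, 30)),
                 "degenerate")
  expect_true(all(all_neg == "neg"))
  expect_error(her2_from_expression(rnorm(5)), ">= 20")
})

test_that("alteration filtering applies the minimum-carrier rule", {
  m <- cbind(a = c(1, 1, 1, 1, 0, 0), b = c(1, 1, 1, 1, 1, 0),
             c = rep(0, 6))
  expect_identical(colnames(filter_alterations(m, 5)), "b")
  expect_equal(ncol(filter_alterations(matrix(0, 4, 3), 1)), 0L)
  expect_identical(filter_alterations(m, 0), m)
})
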