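test_that("contact graphs use the inclusive 8 um centroid rule", {
  g <- graph_from_coords(c(0, 7.9, 16.0), c(0, 0, 0))
  ## 0-7.9 within 8; 7.9-16.0 = 8.1 apart; 0-16 16 apart
  expect_equal(nrow(g$edges), 1L)
  expect_setequal(as.vector(g$edges[1, ]), c("1", "2"))

  ## exactly 8.0 is an edge (inclusive convention)
  g8 <- graph_from_coords(c(0, 8), c(0, 0))
  expect_equal(nrow(g8$edges), 1L)

  ## 3 collinear cells at 5 um spacing: consecutive pairs only
  g3 <- graph_from_coords(c(0, 5, 10), c(0, 0, 0))
  expect_equal(nrow(g3$edges), 2L)

  dup <- toy_cells(2); dup$cell_id <- c(1, 1)
  expect_error(build_contact_graph(dup), "duplicate")
})

test_that("compartment splitting drops cross edges and perivascular cells", {
  x <- c(0, 5, 10, 15, 20); y <- rep(0, 5)
  comp <- c("epithelial", "epithelial", "tme", "tme", "tme")
  peri <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
  g <- graph_from_coords(x, y, compartment = comp, perivascular = peri)
  sp <- split_compartment_graphs(g)
  expect_equal(nrow(sp$epithelial$vertices), 2L)
  expect_equal(nrow(sp$tme$vertices), 2L)  # cell 5 is perivascular
  ## partition: epithelial + tme + perivascular = all cells
  expect_equal(nrow(sp$epithelial$vertices) + nrow(sp$tme$vertices) +
               sum(peri), 5L)
  ## only TME-TME edges remain
  expect_true(all(sp$tme$edges %in% c("3", "4")))

  gall <- graph_from_coords(x[3:5], y[3:5], perivascular = rep(TRUE, 3))
  expect_equal(nrow(split_compartment_graphs(gall)$tme$vertices), 0L)
})

## clique coordinates: n points packed within an 8 um ball
clique_coords <- function(n, cx) {
  ang <- 2 * pi * seq_len(n) / n
  cbind(cx + 2 * cos(ang), 2 * sin(ang))
}

test_that("random-walk community detection separates joined cliques", {
  ## two 12-cliques joined by one edge
  a <- clique_coords(12, 0); b <- clique_coords(12, 11.9)
  xy <- rbind(a, b)
  g <- graph_from_coords(xy[, 1], xy[, 2])
  ## confirm construction: each blob is a clique with one bridge
  comms <- detect_communities(g, min_size = 10)
  expect_equal(length(unique(comms$community_id)), 2L)
  expect_equal(unname(table(comms$community_id)), c(12L, 12L),
               ignore_attr = TRUE)

  ## one clique alone
  g1 <- graph_from_coords(a[, 1], a[, 2])
  expect_equal(length(unique(detect_communities(g1)$community_id)), 1L)

  ## isolated vertices never form communities
  iso <- graph_from_coords(seq(0, 29) * 20, rep(0, 30))
  expect_equal(nrow(detect_communities(iso)), 0L)
})

test_that("connectivity profiles count within-community contacts by phenotype", {
  ## triangle with phenotypes (A, A, B)
  g <- graph_from_coords(c(0, 5, 2.5), c(0, 0, 4),
                         phenotype = c("A", "A", "B"))
  comm <- data.frame(image_id = "img1", community_id = "c1",
                     cell_id = c("1", "2", "3"))
  prof <- connectivity_profile(comm, g, phenotypes = c("A", "B", "C"))
  expect_equal(prof["c1", ], c(A = 4L, B = 2L, C = 0L))
  expect_equal(sum(prof), 2L * 3L)

  ## single edge
  g2 <- graph_from_coords(c(0, 5), c(0, 0), phenotype = c("A", "B"))
  comm2 <- data.frame(image_id = "img1", community_id = "c1",
                      cell_id = c("1", "2"))
  expect_equal(connectivity_profile(comm2, g2, c("A", "B"))["c1", ],
               c(A = 1L, B = 1L))

  expect_error(connectivity_profile(comm, g, phenotypes = c("A")),
               "unknown phenotype")
})

test_that("profile totals equal twice the internal edge count (property)", {
  co <- small_cohort()
  comms <- do.call(rbind, lapply(co$tme_graphs, detect_communities))
  profs <- connectivity_profile(comms, co$tme_graphs)
  for (cid in rownames(profs)) {
    sub <- comms[comms$community_id == cid, ]
    g <- co$tme_graphs[[sub$image_id[1]]]
    e <- g$edges
    n_int <- sum(e[, 1] %in% sub$cell_id & e[, 2] %in% sub$cell_id)
    expect_identical(sum(profs[cid, ]), 2L * n_int)
  }
  ## communities partition retained vertices
  expect_false(anyDuplicated(paste(comms$image_id, comms$cell_id)) > 0)
})

test_that("structure assignment behaves at degenerate k and permutations", {
  set.seed(6)
  profs <- matrix(rpois(60 * 8, 20), 60, 8)
  rownames(profs) <- paste0("c", 1:60)
  one <- assign_structures(profs, k = 1)
  expect_equal(length(unique(one$labels)), 1L)
  a <- assign_structures(profs, k = 4)
  b <- assign_structures(profs, k = 4)
  expect_identical(a$labels, b$labels)
  expect_error(assign_structures(profs, k = 61), "exceeds")
  expect_error(assign_structures(profs, k = 4,
                                 structure_names = c("x", "y")), "length")
})

test_that("random-forest classifier is accurate on real labels, chance on shuffled", {
  set.seed(7)
  comp <- build_default_archetypes()$structures$composition
  n_per <- 40
  labs <- rep(rownames(comp), each = n_per)
  profs <- t(vapply(labs, function(s)
    as.vector(rmultinom(1, 50 + rpois(1, 250), comp[s, ])),
    numeric(ncol(comp))))
  profs <- profs / rowSums(profs)
  colnames(profs) <- colnames(comp)
  rownames(profs) <- NULL
  idx <- sample(nrow(profs))
  train <- idx[1:300]; test <- idx[301:400]
  fit <- train_structure_classifier(profs[train, ], labs[train], seed = 2)
  expect_gt(fit$oob_accuracy, 0.85)
  pred <- classify_structures(fit, profs[test, ])
  expect_gt(mean(pred == labs[test]), 0.85)
  expect_named(attributes(pred), c("proportions"), ignore.order = TRUE)

  ## shuffled labels give chance-level held-out accuracy
  shuf <- withr::with_seed(3, sample(labs[train]))
  fit0 <- train_structure_classifier(profs[train, ], shuf, seed = 2)
  pred0 <- classify_structures(fit0, profs[test, ])
  expect_lt(mean(pred0 == labs[test]), 0.25)  # chance is 1/10

  expect_error(classify_structures(fit, profs[test, 1:5]), "dimension")
  expect_error(train_structure_classifier(profs[1:10, ],
                                          rep("a", 10)), "2 structure")
  ## same seed, same predictions
  fit2 <- train_structure_classifier(profs[train, ], labs[train], seed = 2)
  expect_identical(classify_structures(fit2, profs[test, ]), pred)
})

test_that("network properties match hand-computed small graphs", {
  path3 <- rbind(c("a", "b"), c("b", "c"))
  np <- network_properties(path3, vertex_ids = c("a", "b", "c"))
  expect_equal(unname(np), c(3, 2, 2, 2 / 3, 0, -1), tolerance = 1e-12)

  tri <- rbind(c("a", "b"), c("b", "c"), c("a", "c"))
  npt <- network_properties(tri, vertex_ids = c("a", "b", "c"))
  expect_equal(unname(npt[c("diameter", "density", "transitivity")]),
               c(1, 1, 1))
  expect_true(is.na(npt["assortativity"]))  # zero degree variance

  ## single vertex: counts only
  np1 <- network_properties(matrix(character(0), 0, 2), vertex_ids = "a")
  expect_equal(unname(np1["n_vertices"]), 1)
  expect_true(all(is.na(np1[c("diameter", "density")])))
})

test_that("degree composition normalizes within bins and tracks construction", {
  ## star-augmented community: phenotype H holds the single high-degree hub
  n <- 9
  ang <- 2 * pi * seq_len(n) / n
  x <- c(0, 6 * cos(ang)); y <- c(0, 6 * sin(ang))
  ph <- c("H", rep("L", n))
  g <- graph_from_coords(x, y, phenotype = ph)
  comm <- data.frame(image_id = "img1", community_id = "c1",
                     cell_id = as.character(1:(n + 1)))
  labels <- c(c1 = "S1")
  dc <- degree_composition(comm, g, labels)
  ## proportions sum to 1 within each (structure, bin)
  sums <- tapply(dc$proportion, paste(dc$structure, dc$bin), sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)
  ## the hub phenotype occupies the top bin exclusively
  top <- dc[dc$bin == "7-9", ]
  expect_identical(top$phenotype, "H")
  expect_equal(top$proportion, 1)

  dcc <- degree_composition(comm, g, labels, perspective = "cell")
  sums2 <- tapply(dcc$proportion, paste(dcc$structure, dcc$phenotype), sum)
  expect_equal(as.vector(sums2), rep(1, length(sums2)), tolerance = 1e-12)
})

test_that("subgraph diversity equals the Shannon kernel on member counts", {
  g <- graph_from_coords(c(0, 5, 10, 15), c(0, 0, 0, 0),
                         phenotype = c("A", "A", "B", "C"))
  comm <- data.frame(image_id = "img1", community_id = "c1",
                     cell_id = as.character(1:4))
  expect_equal(unname(subgraph_diversity(comm, g)),
               shannon_diversity(c(2, 1, 1)))
  single <- data.frame(image_id = "img1", community_id = "c2",
                       cell_id = c("1", "2"))
  expect_equal(unname(subgraph_diversity(single, g)), 0)
})
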