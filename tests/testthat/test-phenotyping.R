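test_that("spillover compensation inverts constructed spill exactly", {
  ## identity matrix is the identity map
  y <- matrix(c(1, 2, 0, 5), 2, 2)
  expect_identical(compensate_spillover(y, diag(2)), y)

  ## 2-channel 5% spill: y = t(M) x recovers x
  M <- rbind(c(1, 0.05), c(0.03, 1))
  x <- rbind(c(10, 3), c(0, 7), c(2.5, 0))
  y2 <- x %*% M  # per cell: y = t(M) %*% x
  rec <- compensate_spillover(y2, M)
  expect_equal(rec, x, tolerance = 1e-6, ignore_attr = TRUE)

  ## zero counts map to zero
  expect_equal(compensate_spillover(matrix(0, 1, 2), M),
               matrix(0, 1, 2), ignore_attr = TRUE)

  ## larger random low-spill matrix round-trips too
  set.seed(1)
  p <- 6
  M6 <- diag(p); M6[row(M6) != col(M6)] <- runif(p * p - p, 0, 0.08)
  x6 <- matrix(rexp(20 * p), 20, p)
  expect_equal(compensate_spillover(x6 %*% M6, M6), x6,
               tolerance = 1e-6, ignore_attr = TRUE)

  expect_error(suppressWarnings(compensate_spillover(y, matrix(1, 2, 2))),
               "diagonal|singular")
  expect_error(compensate_spillover(y, diag(3)), "match")
})

test_that("arcsinh transform matches closed forms and clips per marker", {
  expect_equal(transform_expression(matrix(0))[1], 0)
  expect_equal(transform_expression(matrix(0.8), cofactor = 0.8)[1],
               asinh(1), tolerance = 1e-12)
  x <- matrix(1:100, ncol = 1)
  tx <- transform_expression(x)
  cap <- quantile(asinh(x / 0.8), 0.99, names = FALSE)
  expect_true(all(tx <= cap + 1e-12))
  ## monotone below the clip point
  expect_true(all(diff(tx[1:98, 1]) > 0))
  expect_error(transform_expression(x, cofactor = 0), "positive")
  expect_error(transform_expression(matrix(-1)), "non-negative")
})

test_that("epithelial classification works by mixture, mask and auto", {
  set.seed(2)
  n <- 300
  panck <- c(exp(rnorm(n / 2, 0.5, 0.2)), exp(rnorm(n / 2, 4, 0.2)))
  df <- data.frame(image_id = "img1", patient_id = "P1", cell_id = 1:n,
                   x_um = runif(n, 0, 100), y_um = runif(n, 0, 100),
                   panCK = panck)
  tab <- cell_table(df, "panCK")
  out <- classify_epithelial(tab, method = "gmm")
  expect_true(all(out$compartment[(n / 2 + 1):n] == "epithelial"))
  expect_true(all(out$compartment[1:(n / 2)] == "tme"))

  ## mask method follows the tumor mask flag
  tab$in_tumor_mask <- c(rep(FALSE, n / 2), rep(TRUE, n / 2))
  outm <- classify_epithelial(tab, method = "mask")
  expect_identical(outm$compartment == "epithelial", tab$in_tumor_mask)
  ## auto picks a method achieving at least mask-level contrast here
  outa <- classify_epithelial(tab, method = "auto")
  expect_gt(mean(outa$compartment[(n / 2 + 1):n] == "epithelial"), 0.95)

  ## all-zero pan-CK: degenerate, everything TME
  tab0 <- cell_table(data.frame(image_id = "i", patient_id = "p",
                                cell_id = 1:30, x_um = 1:30, y_um = 1:30,
                                panCK = rep(0, 30)), "panCK")
  expect_true(all(classify_epithelial(tab0, "gmm")$compartment == "tme"))

  ## tiny image falls back to the mask method with a warning
  tiny <- toy_cells(5)
  names(tiny)[names(tiny) == "M1"] <- "panCK"
  attr(tiny, "panel") <- c("panCK", "M2")
  tiny$in_tumor_mask <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_warning(outt <- classify_epithelial(tiny, "gmm"), "falling back")
  expect_identical(outt$compartment == "epithelial", tiny$in_tumor_mask)
})

test_that("SOM plus graph communities recover planted phenotypes", {
  arch <- build_default_archetypes()
  markers <- clustering_markers("tme")
  set.seed(10)
  truth <- rep(arch$tme$names, length.out = 4000)
  counts <- draw_expression(arch$tme, truth)
  expr <- transform_expression(counts[, markers])
  cl <- cluster_phenotypes(expr, markers, grid_dim = c(16, 16),
                           knn_k = 15, seed = 8)
  map <- merge_clusters(cl$profiles)
  pheno <- map$phenotype[match(cl$cell_labels,
                               as.integer(map$cluster_id))]
  expect_equal(length(unique(pheno)), 16L)
  expect_gte(mclust::adjustedRandIndex(pheno, truth), 0.9)

  ## determinism under a fixed seed
  cl2 <- cluster_phenotypes(expr, markers, grid_dim = c(16, 16),
                            knn_k = 15, seed = 8)
  expect_identical(cl$cell_labels, cl2$cell_labels)

  ## single archetype collapses to one phenotype after merging
  counts1 <- withr::with_seed(3, draw_expression(
    arch$tme, rep("B_cells", 400)))
  expr1 <- transform_expression(counts1[, markers])
  cl1 <- suppressWarnings(cluster_phenotypes(expr1, markers,
                                             grid_dim = c(6, 6),
                                             knn_k = 10, seed = 8))
  map1 <- merge_clusters(cl1$profiles)
  expect_equal(length(unique(map1$phenotype)), 1L)
})

test_that("cluster merging follows profile correlation and mappings", {
  prof <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4) * 2 + 0.001,
                c = c(4, 3, 2, 1))
  out <- merge_clusters(prof, corr_threshold = 0.9)
  expect_equal(out$phenotype[1], out$phenotype[2])  # correlated pair
  expect_false(out$phenotype[3] == out$phenotype[1])

  ## 16 well-separated archetype profiles stay 16 at threshold 0.9
  lm <- build_default_archetypes()$tme$log_mean
  out16 <- merge_clusters(lm, corr_threshold = 0.9)
  expect_equal(length(unique(out16$phenotype)), 16L)

  ## threshold 1 with distinct profiles merges nothing
  expect_equal(length(unique(merge_clusters(prof[c(1, 3), ],
                                            corr_threshold = 1)$phenotype)),
               2L)

  mapdf <- data.frame(cluster_id = c("a", "b", "c"),
                      phenotype = c("X", "X", "Y"))
  expect_equal(unique(merge_clusters(prof, "mapping",
                                     mapping = mapdf)$phenotype),
               c("X", "X", "Y")[c(1, 3)])
  bad <- data.frame(cluster_id = "zz", phenotype = "X")
  expect_error(merge_clusters(prof, "mapping", mapping = bad), "zz")
})

test_that("subclustering resolves planted subprofiles", {
  set.seed(5)
  centers <- matrix(rnorm(5 * 10, sd = 4), 5, 10)
  truth <- rep(1:5, each = 100)
  x <- centers[truth, ] + matrix(rnorm(500 * 10, sd = 0.5), 500, 10)
  lab <- subcluster(x, k = 5, seed = 2)
  expect_gte(mclust::adjustedRandIndex(lab, truth), 0.8)
  expect_identical(subcluster(x, k = 1), rep(1L, 500))
  expect_error(subcluster(x[1:3, ], k = 5), "fewer cells")
})

test_that("Shannon diversity matches closed forms and its invariances", {
  expect_equal(shannon_diversity(c(10, 10, 10, 10)), log(4))
  expect_equal(shannon_diversity(42), 0)
  expect_equal(shannon_diversity(c(3, 1)), 0.5623351, tolerance = 1e-6)
  expect_true(is.na(shannon_diversity(c(0, 0))))
  ## scale invariance and maximality at uniform composition
  set.seed(3)
  for (r in 1:20) {
    counts <- rpois(6, 20) + 1
    expect_equal(shannon_diversity(counts), shannon_diversity(counts * 7))
    expect_lte(shannon_diversity(counts), log(6) + 1e-12)
  }
  expect_error(shannon_diversity(c(-1, 2)), "non-negative")
})

test_that("diversity comparisons report per-contrast linear models", {
  set.seed(4)
  h <- c(rnorm(50, 1.0, 0.2), rnorm(50, 1.5, 0.2), rnorm(50, 1.0, 0.2))
  g <- rep(c("A", "B", "C"), each = 50)
  out <- compare_diversity(h, g, list(c("B", "A"), c("C", "A")))
  expect_equal(nrow(out), 2L)
  expect_gt(out$estimate[1], 0.3)   # planted 0.5 shift
  expect_lt(out$p[1], 0.001)
  expect_true(out$ci_lo[1] < out$estimate[1] &
              out$estimate[1] < out$ci_hi[1])
  ## single contrast: BH leaves the p value unchanged
  one <- compare_diversity(h, g, list(c("B", "A")))
  expect_equal(one$p_adj, one$p)
  expect_error(compare_diversity(h[1:4], g[1:4], list(c("B", "A"))),
               ">= 3 samples")
})
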