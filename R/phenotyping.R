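## Single-cell phenotyping: spillover compensation, arcsinh expression
## transformation, epithelial/TME compartment assignment, SOM plus
## graph-community clustering into phenotypes, profile-correlation
## merging, subclustering, and diversity comparisons.

#' Compensate channel spillover by non-negative least squares
#'
#' Mass-cytometry channels leak small fractions of signal into
#' neighboring channels due to isotopic impurities. Given a spillover
#' matrix M (rows = source channel, columns = receiving channel,
#' diagonal 1), the observed counts y per cell satisfy y = t(M) x for
#' true counts x; x is recovered per cell by non-negative least squares.
#'
#' @param raw_counts Cell x channel matrix of observed counts.
#' @param M Square spillover matrix with `diag(M) == 1`; channel order
#'   must match `raw_counts` columns.
#' @return Matrix of compensated counts (>= 0), same shape as input.
#' @export
compensate_spillover <- function(raw_counts, M) {
  raw_counts <- as.matrix(raw_counts)
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("M must be square")
  if (ncol(M) != ncol(raw_counts))
    stop("channel sets of counts and spillover matrix do not match")
  if (any(abs(diag(M) - 1) > 1e-8)) stop("spillover matrix diagonal must be 1")
  if (any(M < 0)) stop("spillover matrix must be non-negative")
  if (any(M[row(M) != col(M)] >= 0.5))
    warning("off-diagonal spillover >= 0.5; check the spillover matrix")
  if (abs(det(M)) < 1e-12) stop("singular spillover matrix")
  if (identical(unname(M), diag(ncol(M)))) return(raw_counts)
  C <- t(M)
  out <- t(apply(raw_counts, 1, function(y) {
    if (all(y == 0)) return(numeric(length(y)))
    pracma::lsqnonneg(C, y)$x
  }))
  dimnames(out) <- dimnames(raw_counts)
  out
}

#' Arcsinh-transform raw counts with centile clipping
#'
#' Applies `asinh(count / cofactor)` and then clips each marker column at
#' its own `clip_centile` quantile, the standard variance-stabilizing
#' transform for ion-count data prior to clustering.
#'
#' @param counts Cell x marker matrix of non-negative counts.
#' @param cofactor Arcsinh cofactor (default 0.8).
#' @param clip_centile Upper clipping quantile (default 0.99).
#' @return Transformed matrix.
#' @export
transform_expression <- function(counts, cofactor = 0.8,
                                 clip_centile = 0.99) {
  if (cofactor <= 0) stop("cofactor must be positive")
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  x <- asinh(counts / cofactor)
  caps <- apply(x, 2, quantile, probs = clip_centile, names = FALSE)
  for (j in seq_len(ncol(x))) x[x[, j] > caps[j], j] <- caps[j]
  x
}

## deterministic EM for a univariate two-component Gaussian mixture.
## Initialization from the quartiles and a scale-relative variance floor
## make the fit equivariant under affine rescaling of the input.
fit_gmm2 <- function(x, max_iter = 500, tol = 1e-8) {
  sx <- sd(x)
  if (!is.finite(sx) || sx == 0) return(NULL)
  mu <- as.numeric(quantile(x, c(0.25, 0.75), names = FALSE))
  if (mu[1] == mu[2]) mu <- range(x)
  if (mu[1] == mu[2]) return(NULL)
  s <- rep(sx, 2)
  pi1 <- 0.5
  ll_old <- -Inf
  z <- NULL
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * dnorm(x, mu[1], s[1])
    d2 <- (1 - pi1) * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    z <- d1 / tot
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
    n1 <- sum(z); n2 <- length(x) - n1
    if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
    mu <- c(sum(z * x) / n1, sum((1 - z) * x) / n2)
    s <- sqrt(c(sum(z * (x - mu[1])^2) / n1,
                sum((1 - z) * (x - mu[2])^2) / n2))
    s <- pmax(s, 1e-6 * sx)
    pi1 <- n1 / length(x)
  }
  list(mu = mu, sd = s, pi = c(pi1, 1 - pi1), z = cbind(z, 1 - z))
}

## two-component GMM on a numeric vector; returns logical vector that is
## TRUE for the higher-mean component, or NULL for a degenerate fit.
gmm_high_component <- function(x, min_sep = 1e-3) {
  fit <- tryCatch(fit_gmm2(x), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  mu <- fit$mu
  if (abs(diff(mu)) < min_sep * max(sd(x), 1e-12)) return(NULL)
  hi <- which.max(mu)
  post <- fit$z[, hi]
  post > 0.5  # ties (post == 0.5) resolve to the lower component
}

#' Assign cells to the epithelial or TME compartment
#'
#' Three methods mirror complementary classification strategies:
#' `"gmm"` fits a per-image two-component Gaussian mixture to
#' log(1 + pan-cytokeratin) counts and labels the higher-mean component
#' epithelial; `"mask"` labels cells related to the tumor region mask
#' epithelial; `"auto"` picks, per image, whichever method yields the
#' higher mean pan-cytokeratin contrast between the two compartments (a
#' quantitative surrogate for expert adjudication using cytokeratin
#' expression as a guide).
#'
#' @param table A `cell_table` (tumor mask attached for mask/auto).
#' @param method `"gmm"`, `"mask"` or `"auto"`.
#' @param marker Pan-cytokeratin column name (default `"panCK"`).
#' @param min_cells Images with fewer cells fall back to the mask method
#'   with a warning (default 20).
#' @return The table with `compartment` set to `"epithelial"`/`"tme"`.
#' @export
classify_epithelial <- function(table, method = c("gmm", "mask", "auto"),
                                marker = "panCK", min_cells = 20) {
  method <- match.arg(method)
  stopifnot_cols(table, marker, "cell table")
  if (method %in% c("mask", "auto"))
    stopifnot_cols(table, "in_tumor_mask", "cell table")
  comp <- rep("tme", nrow(table))
  for (im in unique(table$image_id)) {
    rows <- which(table$image_id == im)
    x <- log1p(table[[marker]][rows])
    use <- method
    if (use == "gmm" && length(rows) < min_cells) {
      if (all(c("in_tumor_mask") %in% names(table))) {
        warning(sprintf("image %s has < %d cells; falling back to mask method",
                        im, min_cells))
        use <- "mask"
      }
    }
    epi_gmm <- NULL
    if (use %in% c("gmm", "auto") && length(rows) >= min_cells &&
        length(unique(x)) > 2) {
      epi_gmm <- gmm_high_component(x)
      if (is.null(epi_gmm) && use == "gmm")
        warning(sprintf("image %s: degenerate mixture fit; all cells TME", im))
    }
    epi_mask <- table$in_tumor_mask[rows]
    epi <- switch(use,
      gmm = epi_gmm %||% rep(FALSE, length(rows)),
      mask = epi_mask,
      auto = {
        contrast <- function(flag) {
          if (!any(flag) || all(flag)) return(-Inf)
          mean(x[flag]) - mean(x[!flag])
        }
        if (is.null(epi_gmm) ||
            contrast(epi_mask) >= contrast(epi_gmm)) epi_mask else epi_gmm
      })
    comp[rows][epi] <- "epithelial"
  }
  table$compartment <- comp
  table
}

#' Cluster cells into phenotypes via SOM and graph communities
#'
#' Cells are first segregated into self-organizing-map nodes (default
#' 35 x 35 grid, 1,225 groups); node median expression profiles are then
#' clustered by community detection (Louvain modularity optimization) on
#' a k-nearest-neighbor graph with self-tuning Gaussian kernel edge
#' weights, and node labels are mapped back to cells.
#'
#' @param expression Cell x marker matrix of transformed expression,
#'   restricted to the compartment of interest.
#' @param markers Columns to cluster on (default all).
#' @param grid_dim SOM grid dimensions (default `c(35, 35)`).
#' @param knn_k Neighbors for the node graph (default 30).
#' @param resolution Louvain modularity resolution (default 2; the
#'   deliberate oversplit is consolidated by [merge_clusters()]).
#' @param seed Integer seed (SOM initialization and Louvain).
#' @return List with `cell_labels` (integer cluster per cell),
#'   `profiles` (cluster x marker median matrix), `cluster_sizes`, and
#'   `node_labels`.
#' @export
cluster_phenotypes <- function(expression, markers = colnames(expression),
                               grid_dim = c(35, 35), knn_k = 30,
                               resolution = 2, seed = 1) {
  x <- as.matrix(expression[, markers, drop = FALSE])
  n <- nrow(x)
  n_nodes <- prod(grid_dim)
  if (n < n_nodes) {
    side <- max(2, floor(sqrt(n / 4)))
    warning(sprintf("fewer cells (%d) than SOM nodes (%d); shrinking grid to %dx%d",
                    n, n_nodes, side, side))
    grid_dim <- c(side, side)
  }
  som <- withr::with_seed(derive_seed(seed, 1), {
    grid <- class::somgrid(xdim = grid_dim[1], ydim = grid_dim[2],
                           topo = "hexagonal")
    class::batchSOM(x, grid, radii = seq(4, 0, length.out = 10))
  })
  node_of_cell <- as.integer(class::knn1(
    som$codes, x, factor(seq_len(nrow(som$codes)))))
  used_nodes <- sort(unique(node_of_cell))
  medians <- t(vapply(used_nodes, function(nd)
    apply(x[node_of_cell == nd, , drop = FALSE], 2, median),
    numeric(ncol(x))))
  k_eff <- min(knn_k, nrow(medians) - 1)
  g <- knn_kernel_graph(medians, k_eff)
  comm <- withr::with_seed(derive_seed(seed, 2),
    igraph::cluster_louvain(g, resolution = resolution))
  node_labels <- igraph::membership(comm)
  cell_labels <- as.integer(node_labels[match(node_of_cell, used_nodes)])
  profiles <- t(vapply(sort(unique(cell_labels)), function(cl)
    apply(x[cell_labels == cl, , drop = FALSE], 2, median),
    numeric(ncol(x))))
  rownames(profiles) <- sort(unique(cell_labels))
  list(cell_labels = cell_labels, profiles = profiles,
       cluster_sizes = as.integer(table(cell_labels)),
       node_labels = as.integer(node_labels))
}

## undirected kNN graph with self-tuning Gaussian kernel edge weights:
## w_ij = exp(-d_ij^2 / (sigma_i sigma_j)) with sigma_i the distance to
## the (k/3)-th neighbor. The local scale makes edges between distinct
## phenotype islands vanish even when an island holds fewer than k
## nodes, where a fixed-k unweighted graph would fuse them.
knn_kernel_graph <- function(x, k) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  sigma <- vapply(seq_len(n), function(i)
    d[i, nn[i, max(1, ceiling(k / 3))]], numeric(1))
  sigma <- pmax(sigma, 1e-9)
  from <- rep(seq_len(n), each = k)
  to <- as.vector(t(nn))
  key <- paste(pmin(from, to), pmax(from, to))
  keep <- !duplicated(key)
  from <- from[keep]; to <- to[keep]
  w <- exp(-d[cbind(from, to)]^2 / (sigma[from] * sigma[to]))
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
}

#' Merge similar clusters into final phenotypes
#'
#' `mode = "auto"` merges clusters whose median expression profiles are
#' highly correlated (average-linkage agglomeration on 1 - Pearson
#' correlation, cut at `1 - corr_threshold`), an automated surrogate for
#' curated merging of functionally similar clusters. `mode = "mapping"`
#' applies an explicit user-supplied cluster-to-phenotype mapping.
#'
#' @param profiles Cluster x marker median-profile matrix (rownames =
#'   cluster ids).
#' @param mode `"auto"` or `"mapping"`.
#' @param corr_threshold Correlation at or above which clusters merge
#'   (default 0.9).
#' @param mapping Data frame with columns `cluster_id`, `phenotype`
#'   (required for `mode = "mapping"`).
#' @return Data frame (`cluster_id`, `phenotype`) mapping every cluster
#'   to a final phenotype.
#' @export
merge_clusters <- function(profiles, mode = c("auto", "mapping"),
                           corr_threshold = 0.9, mapping = NULL) {
  mode <- match.arg(mode)
  if (nrow(profiles) == 0) stop("no cluster profiles supplied")
  ids <- rownames(profiles) %||% as.character(seq_len(nrow(profiles)))
  if (mode == "mapping") {
    stopifnot_cols(mapping, c("cluster_id", "phenotype"), "mapping")
    unknown <- setdiff(as.character(mapping$cluster_id), ids)
    if (length(unknown))
      stop("mapping references unknown cluster(s): ",
           paste(unknown, collapse = ", "))
    return(data.frame(cluster_id = as.character(mapping$cluster_id),
                      phenotype = as.character(mapping$phenotype),
                      stringsAsFactors = FALSE))
  }
  if (nrow(profiles) == 1)
    return(data.frame(cluster_id = ids, phenotype = "phenotype_01",
                      stringsAsFactors = FALSE))
  cc <- suppressWarnings(cor(t(profiles)))
  cc[is.na(cc)] <- 0
  hc <- hclust(as.dist(1 - cc), method = "average")
  groups <- cutree(hc, h = 1 - corr_threshold + 1e-12)
  data.frame(cluster_id = ids,
             phenotype = sprintf("phenotype_%02d", groups),
             stringsAsFactors = FALSE)
}

#' Subcluster cells of selected phenotypes
#'
#' k-means clustering of the expression of cells belonging to one
#' phenotype, to resolve finer functional states (e.g. checkpoint
#' heterogeneity within T cells).
#'
#' @param expression Cell x marker matrix for the selected cells.
#' @param k Number of subclusters (default 5).
#' @param seed Integer seed.
#' @return Integer vector of subcluster labels (1..k).
#' @export
subcluster <- function(expression, k = 5, seed = 1) {
  x <- as.matrix(expression)
  if (nrow(x) < k) stop("fewer cells than subclusters requested")
  if (k == 1) return(rep(1L, nrow(x)))
  km <- withr::with_seed(seed, kmeans(x, centers = k, nstart = 10,
                                      iter.max = 100))
  as.integer(km$cluster)
}

#' Compare Shannon diversity between groups with linear models
#'
#' For each requested contrast (group A versus reference group B), fits
#' an ordinary linear model of per-sample diversity on group membership,
#' reporting the estimate, 95% confidence interval, two-sided p value,
#' and Benjamini-Hochberg adjusted p across all contrasts.
#'
#' @param diversity Numeric vector of per-sample diversities.
#' @param groups Group label per sample.
#' @param contrasts List of length-2 character vectors `c(A, B)`.
#' @return Data frame with one row per contrast.
#' @export
compare_diversity <- function(diversity, groups, contrasts) {
  stopifnot(length(diversity) == length(groups))
  rows <- lapply(contrasts, function(ct) {
    sel <- groups %in% ct
    y <- diversity[sel]
    g <- factor(groups[sel], levels = c(ct[2], ct[1]))  # B = reference
    if (min(table(g)) < 3)
      stop("need >= 3 samples per group for contrast ",
           paste(ct, collapse = " vs "))
    if (var(y) == 0) warning("constant diversity; degenerate fit")
    fit <- lm(y ~ g)
    est <- coef(fit)[2]
    ci <- suppressMessages(confint(fit))[2, ]
    p <- summary(fit)$coefficients[2, 4]
    data.frame(contrast = paste(ct[1], "vs", ct[2]),
               estimate = unname(est), ci_lo = ci[1], ci_hi = ci[2],
               p = p, stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}
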