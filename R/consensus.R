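## Consensus clustering for choosing the number of recurrent TME
## structures. For each candidate k, connectivity profiles are
## repeatedly subsampled and clustered with Ward's method. Two families
## of diagnostics are computed: the classical consensus matrix (pairwise
## co-clustering frequencies) with its CDF area, and the subsample
## stability curve (mean adjusted Rand index between replicate
## clusterings). The number of structures is the largest k whose
## stability remains above the midpoint of the curve's range: solutions
## at or below the true cluster number reproduce almost perfectly under
## subsampling, while finer solutions split clusters arbitrarily and
## their stability drops permanently.

## profile representation used for clustering. "prop" divides each
## profile by its total so communities cluster by how their connections
## are distributed across phenotypes rather than by how many they have;
## "log1p" compresses size while retaining it; "none" is raw counts.
scale_profiles <- function(profiles, scale = c("prop", "log1p", "none")) {
  scale <- match.arg(scale)
  switch(scale,
         prop = profiles / pmax(rowSums(profiles), 1),
         log1p = log1p(profiles),
         none = profiles)
}

## one batch of subsampled Ward clusterings: returns consensus matrix
## pieces and the per-replicate labelings
subsample_clusterings <- function(x, k, reps, subsample) {
  n <- nrow(x)
  co <- matrix(0, n, n)
  together <- matrix(0, n, n)
  m <- max(2, floor(subsample * n))
  labs <- vector("list", reps)
  idxs <- vector("list", reps)
  for (r in seq_len(reps)) {
    idx <- sort(sample.int(n, m))
    hc <- hclust(dist(x[idx, , drop = FALSE]), method = "ward.D2")
    cl <- cutree(hc, k = min(k, m))
    together[idx, idx] <- together[idx, idx] + 1
    for (g in unique(cl)) {
      ii <- idx[cl == g]
      co[ii, ii] <- co[ii, ii] + 1
    }
    labs[[r]] <- cl; idxs[[r]] <- idx
  }
  cons <- ifelse(together > 0, co / together, 0)
  diag(cons) <- 1
  list(consensus = cons, labs = labs, idxs = idxs)
}

## mean adjusted Rand index between replicate clusterings, over at most
## `max_pairs` random replicate pairs evaluated on their shared items
replicate_stability <- function(labs, idxs, max_pairs = 100) {
  reps <- length(labs)
  pairs <- utils::combn(reps, 2)
  if (ncol(pairs) > max_pairs)
    pairs <- pairs[, sample.int(ncol(pairs), max_pairs), drop = FALSE]
  aris <- apply(pairs, 2, function(ij) {
    common <- intersect(idxs[[ij[1]]], idxs[[ij[2]]])
    if (length(common) < 3) return(NA_real_)
    mclust::adjustedRandIndex(
      labs[[ij[1]]][match(common, idxs[[ij[1]]])],
      labs[[ij[2]]][match(common, idxs[[ij[2]]])])
  })
  mean(aris, na.rm = TRUE)
}

## area under the empirical CDF of off-diagonal consensus values
consensus_cdf_area <- function(cons) {
  v <- cons[upper.tri(cons)]
  breaks <- seq(0, 1, length.out = 101)
  cdf <- ecdf(v)(breaks)
  sum(diff(breaks) * cdf[-1])
}

#' Choose the number of TME structures by consensus clustering
#'
#' For each k in `k_range`, the profiles are subsampled `reps` times and
#' clustered with Ward's method. The consensus matrix, its CDF area and
#' delta area, and the subsample stability (mean adjusted Rand index
#' between replicate clusterings) are recorded. The selected k is the
#' largest one whose stability stays above the midpoint between the
#' curve's maximum and minimum: up to the true number of structures,
#' subsampled solutions reproduce each other; past it, clusters are
#' split arbitrarily and reproducibility drops for every larger k.
#' `k_range` should extend beyond the expected number of structures so
#' the drop is observable. The chosen k then cuts the full-data Ward
#' tree ([assign_structures()]).
#'
#' @param profiles Connectivity-profile matrix (communities x
#'   phenotypes).
#' @param k_range Candidate cluster numbers (default 2:15).
#' @param reps Subsampling repetitions per k (default 100).
#' @param subsample Fraction of profiles per repetition (default 0.8).
#' @param seed Integer seed.
#' @param structure_names Optional names for the final clusters.
#' @param scale Profile representation: `"prop"` (default; connection
#'   proportions, so structures cluster by connectivity composition
#'   rather than size), `"log1p"`, or `"none"` (raw counts).
#' @param min_recurrence Minimum number of communities per structure: a
#'   candidate k is disqualified when the full-data Ward cut at k
#'   produces a cluster smaller than this, since a structure observed
#'   fewer times is not recurrent (default 10).
#' @return A `structure_catalog`: list with `k`, `centroids` (mean raw
#'   profiles per structure), `labels`, `scale`, `diagnostics` (per-k
#'   stability, CDF areas, relative delta areas), and the consensus
#'   matrix for the chosen k.
#' @export
select_n_structures <- function(profiles, k_range = 2:15, reps = 100,
                                subsample = 0.8, seed = 1,
                                structure_names = NULL,
                                scale = c("prop", "log1p", "none"),
                                min_recurrence = 10) {
  scale <- match.arg(scale)
  n <- nrow(profiles)
  if (max(k_range) > n - 1 || min(k_range) < 2)
    stop("k_range must lie within [2, n - 1]")
  x <- scale_profiles(profiles, scale)
  k_range <- sort(k_range)
  areas <- stab <- numeric(length(k_range))
  cons_list <- vector("list", length(k_range))
  hc_full <- hclust(dist(x), method = "ward.D2")
  min_sizes <- vapply(k_range, function(k)
    min(table(cutree(hc_full, k))), numeric(1))
  for (i in seq_along(k_range)) {
    res <- withr::with_seed(derive_seed(seed, k_range[i]),
      subsample_clusterings(x, k_range[i], reps, subsample))
    areas[i] <- consensus_cdf_area(res$consensus)
    stab[i] <- withr::with_seed(derive_seed(seed, 1000 + k_range[i]),
      replicate_stability(res$labs, res$idxs))
    cons_list[[i]] <- res$consensus
  }
  delta <- c(areas[1], diff(areas) / head(areas, -1))
  thr <- (max(stab) + min(stab)) / 2
  eligible <- min_sizes >= min(min_recurrence, n / (2 * max(k_range)))
  ok <- eligible & (stab >= thr) & (max(stab) - min(stab) >= 0.05)
  k_star <- if (any(ok)) max(k_range[ok])
            else k_range[which.max(stab)]
  fit <- assign_structures(profiles, k_star,
                           structure_names = structure_names,
                           scale = scale)
  structure(list(k = k_star, centroids = fit$centroids,
                 labels = fit$labels, scale = scale,
                 diagnostics = data.frame(k = k_range, stability = stab,
                                          min_cluster_size = min_sizes,
                                          eligible = eligible,
                                          cdf_area = areas,
                                          relative_delta_area = delta),
                 stability_threshold = thr,
                 consensus = cons_list[[match(k_star, k_range)]]),
            class = "structure_catalog")
}
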