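## Spatial cell-contact graphs and multicellular TME structure discovery.
## Cells are vertices; an edge joins two cells whose centroids lie within
## the contact radius (8 um, inclusive). TME graphs (non-epithelial,
## non-perivascular cells) are segregated into communities by random-walk
## community detection; each community is summarized by its connectivity
## profile -- per TME phenotype, the number of within-community contacts
## incident to cells of that phenotype -- and recurrent structures are
## found by clustering these profiles.

#' Build per-image cell-contact graphs
#'
#' An edge connects two cells of the same image whose centroid distance
#' is at most `radius_um` (inclusive).
#'
#' @param table A `cell_table`; may span several images.
#' @param radius_um Contact radius in micrometers (default 8).
#' @return For a single-image table, a `spatial_graph` (list with
#'   `image_id`, `vertices` data.frame and an `edges` two-column matrix
#'   of cell ids); for multiple images, a named list of them.
#' @export
build_contact_graph <- function(table, radius_um = 8) {
  imgs <- unique(table$image_id)
  if (length(imgs) > 1) {
    out <- lapply(imgs, function(im)
      build_contact_graph(table[table$image_id == im, , drop = FALSE],
                          radius_um))
    names(out) <- imgs
    return(out)
  }
  if (anyDuplicated(table$cell_id)) stop("duplicate cell ids in image")
  n <- nrow(table)
  xy <- cbind(table$x_um, table$y_um)
  edges <- matrix(character(0), 0, 2)
  if (n >= 2) {
    d <- as.matrix(dist(xy))
    idx <- which(upper.tri(d) & d <= radius_um + 1e-9, arr.ind = TRUE)
    edges <- cbind(as.character(table$cell_id[idx[, 1]]),
                   as.character(table$cell_id[idx[, 2]]))
  }
  vertices <- data.frame(cell_id = as.character(table$cell_id),
                         x_um = table$x_um, y_um = table$y_um,
                         phenotype = table$phenotype %||%
                           rep("unassigned", n),
                         compartment = table$compartment %||%
                           rep("unassigned", n),
                         perivascular = table$in_vessel_mask %||%
                           rep(FALSE, n),
                         stringsAsFactors = FALSE)
  structure(list(image_id = imgs, vertices = vertices, edges = edges,
                 radius_um = radius_um),
            class = "spatial_graph")
}

## induced subgraph on a subset of cell ids
induced_spatial_graph <- function(graph, keep_ids) {
  keep <- graph$vertices$cell_id %in% keep_ids
  e <- graph$edges
  e <- e[e[, 1] %in% keep_ids & e[, 2] %in% keep_ids, , drop = FALSE]
  structure(list(image_id = graph$image_id,
                 vertices = graph$vertices[keep, , drop = FALSE],
                 edges = e, radius_um = graph$radius_um),
            class = "spatial_graph")
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    d = as.data.frame(graph$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = graph$vertices)
}

#' Split a contact graph into compartment subgraphs
#'
#' The epithelial graph contains epithelial cells only; the TME graph
#' contains non-epithelial cells with perivascular cells (vessel-mask
#' contact) excluded. No cross-compartment edges are retained.
#'
#' @param graph A `spatial_graph` built over all cells of an image.
#' @return List with elements `epithelial` and `tme`.
#' @export
split_compartment_graphs <- function(graph) {
  v <- graph$vertices
  epi_ids <- v$cell_id[v$compartment == "epithelial"]
  tme_ids <- v$cell_id[v$compartment != "epithelial" & !v$perivascular]
  list(epithelial = induced_spatial_graph(graph, epi_ids),
       tme = induced_spatial_graph(graph, tme_ids))
}

#' Detect TME communities by random-walk community detection
#'
#' Runs Walktrap (short random walks tend to stay within densely
#' connected subgraphs) on the TME contact graph and discards communities
#' below `min_size` cells. Retained communities are connected subgraphs.
#'
#' @param tme_graph A `spatial_graph` (TME compartment).
#' @param min_size Minimum community size in cells (default 10).
#' @param walk_steps Random-walk length (default 4).
#' @return Data frame with columns `image_id`, `community_id`, `cell_id`.
#' @export
detect_communities <- function(tme_graph, min_size = 10, walk_steps = 4) {
  empty <- data.frame(image_id = character(0), community_id = character(0),
                      cell_id = character(0), stringsAsFactors = FALSE)
  v <- tme_graph$vertices
  if (nrow(v) == 0) return(empty)
  g <- as_igraph(tme_graph)
  if (igraph::ecount(g) == 0) return(empty)
  wt <- igraph::cluster_walktrap(g, steps = walk_steps, weights = NULL)
  memb <- igraph::membership(wt)
  sizes <- table(memb)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  if (!length(keep)) return(empty)
  rows <- lapply(seq_along(keep), function(i) {
    ids <- names(memb)[memb == keep[i]]
    data.frame(image_id = tme_graph$image_id,
               community_id = sprintf("%s_c%02d", tme_graph$image_id, i),
               cell_id = ids, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Connectivity profiles of communities
#'
#' For each community, counts per TME phenotype the number of
#' within-community contacts incident to cells of that phenotype (the sum
#' over member cells of that phenotype of their within-community degree).
#' Profile entries sum to twice the number of internal edges.
#'
#' @param communities Data frame from [detect_communities()].
#' @param graph The `spatial_graph` the communities were detected in (or
#'   a named list of per-image graphs).
#' @param phenotypes Character vector fixing the profile dimension/order.
#' @return Integer matrix, communities x phenotypes, with community ids
#'   as rownames.
#' @export
connectivity_profile <- function(communities, graph,
                                 phenotypes = tme_phenotype_names()) {
  comm_ids <- unique(communities$community_id)
  prof <- matrix(0L, length(comm_ids), length(phenotypes),
                 dimnames = list(comm_ids, phenotypes))
  graphs <- if (inherits(graph, "spatial_graph"))
    setNames(list(graph), graph$image_id) else graph
  for (cid in comm_ids) {
    sub <- communities[communities$community_id == cid, ]
    g <- graphs[[as.character(sub$image_id[1])]]
    if (is.null(g)) stop("no graph for image ", sub$image_id[1])
    members <- sub$cell_id
    e <- g$edges
    e <- e[e[, 1] %in% members & e[, 2] %in% members, , drop = FALSE]
    deg <- table(factor(c(e[, 1], e[, 2]), levels = members))
    ph <- g$vertices$phenotype[match(members, g$vertices$cell_id)]
    if (any(is.na(ph))) stop("community member missing from graph")
    unknown <- setdiff(unique(ph), phenotypes)
    if (length(unknown))
      stop("unknown phenotype(s): ", paste(unknown, collapse = ", "))
    agg <- tapply(as.integer(deg), ph, sum)
    prof[cid, names(agg)] <- as.integer(agg)
  }
  prof
}

#' Assign structures by Ward clustering of connectivity profiles
#'
#' Agglomerative clustering (Ward's method on Euclidean distance) of the
#' profile vectors, cut at `k` groups. By default profiles are clustered
#' as connection proportions (each profile divided by its total), so
#' that structures are identified by how their connections distribute
#' across phenotypes; `"log1p"` and raw `"none"` representations are
#' available (see the methods vignette for the rationale).
#'
#' @param profiles Profile matrix (communities x phenotypes).
#' @param k Number of structures.
#' @param structure_names Optional character vector of length `k`;
#'   clusters (ordered by decreasing size) receive these names.
#' @param scale `"prop"` (default), `"log1p"` or `"none"`.
#' @return List with `labels` (named character vector per community),
#'   `centroids` (k x phenotypes mean raw-profile matrix), and `k`.
#' @export
assign_structures <- function(profiles, k, structure_names = NULL,
                              scale = c("prop", "log1p", "none")) {
  scale <- match.arg(scale)
  if (k > nrow(profiles)) stop("k exceeds number of profiles")
  x <- scale_profiles(profiles, scale)
  if (k == 1) {
    cl <- rep(1L, nrow(profiles))
  } else {
    hc <- hclust(dist(x), method = "ward.D2")
    cl <- cutree(hc, k = k)
  }
  ord <- order(-tabulate(cl, nbins = k))
  rank <- match(seq_len(k), ord)
  labs <- if (is.null(structure_names)) sprintf("S%02d", rank[cl])
          else {
            if (length(structure_names) != k)
              stop("structure_names must have length k")
            structure_names[rank[cl]]
          }
  names(labs) <- rownames(profiles)
  cent <- do.call(rbind, lapply(sort(unique(labs)), function(l)
    colMeans(profiles[labs == l, , drop = FALSE])))
  rownames(cent) <- sort(unique(labs))
  list(labels = labs, centroids = cent, k = k)
}

#' Train a random-forest structure classifier
#'
#' Fits a random forest to connectivity profiles with structure labels,
#' for out-of-sample classification of communities in validation data.
#'
#' @param profiles Profile matrix.
#' @param labels Structure label per profile (same order).
#' @param seed Integer seed.
#' @param ntree Number of trees (default 500).
#' @return List with `model` (randomForest) and `oob_accuracy`.
#' @export
train_structure_classifier <- function(profiles, labels, seed = 1,
                                       ntree = 500) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 structure classes")
  if (min(table(labels)) < 5)
    warning("some classes have < 5 training examples")
  model <- withr::with_seed(seed,
    randomForest::randomForest(x = profiles, y = labels, ntree = ntree))
  oob <- 1 - model$err.rate[ntree, "OOB"]
  list(model = model, oob_accuracy = unname(oob))
}

#' Classify connectivity profiles with a trained classifier
#'
#' @param classifier Output of [train_structure_classifier()].
#' @param profiles Profile matrix with the training dimensionality.
#' @return Character vector of labels (named by profile rownames), with
#'   per-class proportions in attribute `"proportions"`.
#' @export
classify_structures <- function(classifier, profiles) {
  if (nrow(profiles) == 0) {
    out <- character(0)
    attr(out, "proportions") <- numeric(0)
    return(out)
  }
  model <- classifier$model
  if (ncol(profiles) != length(model$forest$ncat))
    stop("profile dimensionality does not match training data")
  pred <- as.character(predict(model, profiles))
  names(pred) <- rownames(profiles)
  attr(pred, "proportions") <- prop.table(table(pred))
  pred
}

np_names <- c("n_vertices", "n_edges", "diameter", "density",
              "transitivity", "assortativity")

#' Network properties of a community subgraph
#'
#' Computes the six summary statistics: vertex count, edge count,
#' diameter (longest shortest path), density 2E/(V(V-1)), global
#' transitivity (clustering coefficient), and degree assortativity
#' (Pearson correlation of endpoint degrees over edges). Assortativity is
#' `NA` when the degree variance is zero; all but the counts are `NA`
#' for graphs with fewer than two vertices.
#'
#' @param edges Two-column matrix of vertex ids (character) or an
#'   `spatial_graph`.
#' @param vertex_ids All vertex ids (defaults to those in `edges`).
#' @return Named numeric vector of the six properties.
#' @export
network_properties <- function(edges, vertex_ids = NULL) {
  if (inherits(edges, "spatial_graph")) {
    vertex_ids <- edges$vertices$cell_id
    edges <- edges$edges
  }
  if (is.null(vertex_ids)) vertex_ids <- unique(as.vector(edges))
  n <- length(vertex_ids)
  out <- setNames(rep(NA_real_, 6), np_names)
  out["n_vertices"] <- n
  out["n_edges"] <- nrow(edges)
  if (n < 2) return(out)
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE), directed = FALSE,
    vertices = data.frame(name = as.character(vertex_ids)))
  out["diameter"] <- igraph::diameter(g, unconnected = FALSE)
  out["density"] <- 2 * nrow(edges) / (n * (n - 1))
  tr <- igraph::transitivity(g, type = "global")
  out["transitivity"] <- if (is.nan(tr)) 0 else tr
  deg <- igraph::degree(g)
  if (var(deg) > 0 && nrow(edges) > 0) {
    a <- igraph::assortativity_degree(g)
    out["assortativity"] <- if (is.nan(a)) NA_real_ else a
  }
  out
}

#' Network properties for every community
#'
#' @param communities Data frame from [detect_communities()].
#' @param graph `spatial_graph` or named list of per-image graphs.
#' @return Data frame, one row per community, with the six properties.
#' @export
community_network_properties <- function(communities, graph) {
  graphs <- if (inherits(graph, "spatial_graph"))
    setNames(list(graph), graph$image_id) else graph
  comm_ids <- unique(communities$community_id)
  rows <- lapply(comm_ids, function(cid) {
    sub <- communities[communities$community_id == cid, ]
    g <- graphs[[as.character(sub$image_id[1])]]
    sg <- induced_spatial_graph(g, sub$cell_id)
    c(network_properties(sg$edges, vertex_ids = sub$cell_id))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(data.frame(community_id = comm_ids,
                          stringsAsFactors = FALSE), out)
  out
}

#' Phenotype composition by vertex-degree category
#'
#' Categorizes community cells by within-community vertex degree and
#' compares phenotypic composition across categories, either per
#' structure (share of each phenotype within each degree bin) or per
#' cell phenotype (distribution of each phenotype over degree bins).
#'
#' @param communities Data frame from [detect_communities()].
#' @param graph `spatial_graph` or named list of graphs.
#' @param structure_labels Named vector mapping community id to structure.
#' @param degree_bins Increasing lower bin edges (default `c(1,4,7,10)`,
#'   i.e. bins 1-3, 4-6, 7-9, 10+).
#' @param perspective `"structure"` or `"cell"`.
#' @return Data frame of proportions; within each (structure, bin) the
#'   phenotype shares sum to 1 (structure perspective), or within each
#'   (structure, phenotype) the bin shares sum to 1 (cell perspective).
#' @export
degree_composition <- function(communities, graph, structure_labels,
                               degree_bins = c(1, 4, 7, 10),
                               perspective = c("structure", "cell")) {
  perspective <- match.arg(perspective)
  graphs <- if (inherits(graph, "spatial_graph"))
    setNames(list(graph), graph$image_id) else graph
  bin_labels <- c(paste0(head(degree_bins, -1), "-",
                         degree_bins[-1] - 1),
                  paste0(degree_bins[length(degree_bins)], "+"))
  recs <- list()
  for (cid in unique(communities$community_id)) {
    sub <- communities[communities$community_id == cid, ]
    g <- graphs[[as.character(sub$image_id[1])]]
    members <- sub$cell_id
    e <- g$edges
    e <- e[e[, 1] %in% members & e[, 2] %in% members, , drop = FALSE]
    deg <- as.integer(table(factor(c(e[, 1], e[, 2]), levels = members)))
    ph <- g$vertices$phenotype[match(members, g$vertices$cell_id)]
    bin <- bin_labels[findInterval(deg, degree_bins)]
    keep <- deg >= degree_bins[1]
    recs[[cid]] <- data.frame(structure = unname(structure_labels[cid]),
                              phenotype = ph[keep], bin = bin[keep],
                              stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, recs)
  counts <- aggregate(list(n = rep(1, nrow(d))),
                      d[c("structure", "bin", "phenotype")], sum)
  if (perspective == "structure") {
    tot <- aggregate(list(total = counts$n),
                     counts[c("structure", "bin")], sum)
    counts <- merge(counts, tot)
    counts$proportion <- counts$n / counts$total
  } else {
    tot <- aggregate(list(total = counts$n),
                     counts[c("structure", "phenotype")], sum)
    counts <- merge(counts, tot)
    counts$proportion <- counts$n / counts$total
  }
  counts$bin <- factor(counts$bin, levels = bin_labels)
  counts[order(counts$structure, counts$phenotype, counts$bin), ]
}

#' Shannon diversity of each community's phenotype composition
#'
#' @param communities Data frame from [detect_communities()].
#' @param graph `spatial_graph` or named list of graphs.
#' @return Named numeric vector of H per community.
#' @export
subgraph_diversity <- function(communities, graph) {
  graphs <- if (inherits(graph, "spatial_graph"))
    setNames(list(graph), graph$image_id) else graph
  vapply(split(communities, communities$community_id), function(sub) {
    g <- graphs[[as.character(sub$image_id[1])]]
    ph <- g$vertices$phenotype[match(sub$cell_id, g$vertices$cell_id)]
    shannon_diversity(as.integer(table(ph)))
  }, numeric(1))
}
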