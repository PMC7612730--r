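## Shared fixture builders. Everything is generated in code; no files.

## minimal two-marker cell table
toy_cells <- function(n = 5, image_id = "img1", patient_id = "P1",
                      x = seq_len(n), y = rep(1, n)) {
  cell_table(data.frame(image_id = image_id, patient_id = patient_id,
                        cell_id = seq_len(n), x_um = x, y_um = y,
                        M1 = rep(1, n), M2 = rep(2, n),
                        stringsAsFactors = FALSE),
             panel = c("M1", "M2"))
}

## spatial graph from explicit coordinates and annotations
graph_from_coords <- function(x, y, phenotype = NULL, compartment = NULL,
                              perivascular = NULL, image_id = "img1",
                              radius_um = 8) {
  n <- length(x)
  df <- data.frame(image_id = image_id, patient_id = "P1",
                   cell_id = seq_len(n), x_um = x, y_um = y,
                   M1 = rep(0, n), M2 = rep(0, n),
                   stringsAsFactors = FALSE)
  tab <- cell_table(df, c("M1", "M2"))
  tab$phenotype <- phenotype %||% rep("A", n)
  tab$compartment <- compartment %||% rep("tme", n)
  tab$in_vessel_mask <- perivascular %||% rep(FALSE, n)
  build_contact_graph(tab, radius_um = radius_um)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## brute-force network-property oracle on an adjacency matrix
np_oracle <- function(adj) {
  n <- nrow(adj)
  e <- sum(adj) / 2
  out <- c(n_vertices = n, n_edges = e, diameter = NA, density = NA,
           transitivity = NA, assortativity = NA)
  if (n < 2) return(out)
  ## Floyd-Warshall shortest paths
  d <- ifelse(adj == 1, 1, Inf); diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  out["diameter"] <- max(d)
  out["density"] <- 2 * e / (n * (n - 1))
  deg <- rowSums(adj)
  triangles <- sum(diag(adj %*% adj %*% adj)) / 6
  triples <- sum(deg * (deg - 1) / 2)
  out["transitivity"] <- if (triples == 0) 0 else 3 * triangles / triples
  if (stats::var(deg) > 0 && e > 0) {
    ends <- which(adj == 1, arr.ind = TRUE)  # both directions
    out["assortativity"] <- stats::cor(deg[ends[, 1]], deg[ends[, 2]])
  }
  out
}

## memoised small default cohort shared across tests
.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- cohort_config(n_images = 12, seed = 77)
    .fixture_env$cohort <- suppressMessages(generate_cohort(cfg))
  }
  .fixture_env$cohort
}
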