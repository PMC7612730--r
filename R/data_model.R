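## Core data containers: single-cell tables, labeled region masks,
## clinical and alteration tables. Cell tables are plain data.frames
## (long format, one row per cell) carrying the marker panel as an
## attribute; masks are lists with an integer raster. Everything reads
## and writes diff-able CSV so fixtures stay plain text.

CELL_TABLE_SCHEMA_VERSION <- "1.0"

required_cell_columns <- function() {
  c("image_id", "patient_id", "cell_id", "x_um", "y_um")
}

optional_cell_columns <- function() {
  c("compartment", "phenotype", "in_tumor_mask", "in_vessel_mask",
    "hot_pixel_flag")
}

#' Construct and validate a cell table
#'
#' A cell table is a data.frame with one row per segmented cell:
#' identifiers (`image_id`, `patient_id`, `cell_id`), centroid
#' coordinates in micrometers (`x_um`, `y_um`), one raw ion-count column
#' per panel marker, and optional annotation columns (`compartment`,
#' `phenotype`, mask-overlap and hot-pixel flags). Transformed expression
#' is stored in `exp_<marker>` columns once computed. The marker panel is
#' attached as attribute `"panel"`.
#'
#' @param df Data frame with the required columns.
#' @param panel Character vector of marker names; each must be a column.
#' @return Validated data.frame of class `cell_table`.
#' @export
cell_table <- function(df, panel) {
  stopifnot_cols(df, required_cell_columns(), "cell table")
  stopifnot_cols(df, panel, "cell table (panel markers)")
  for (m in panel) {
    bad <- which(df[[m]] < 0)
    if (length(bad))
      stop(sprintf("negative raw count for marker %s at row %d", m, bad[1]),
           call. = FALSE)
  }
  if (anyDuplicated(paste(df$image_id, df$cell_id)))
    stop("cell_id must be unique within image", call. = FALSE)
  for (col in c("compartment", "phenotype"))
    if (is.null(df[[col]])) df[[col]] <- "unassigned"
  for (col in c("in_tumor_mask", "in_vessel_mask", "hot_pixel_flag"))
    if (is.null(df[[col]])) df[[col]] <- FALSE
  attr(df, "panel") <- panel
  class(df) <- c("cell_table", "data.frame")
  df
}

#' Marker panel of a cell table
#' @param table A `cell_table`.
#' @return Character vector of marker names.
#' @export
panel_of <- function(table) attr(table, "panel")

#' Read a cell table from CSV/TSV
#'
#' @param path Path to a UTF-8 CSV or TSV file with a header row. Tab
#'   separation is assumed for `.tsv`/`.txt` extensions.
#' @param panel Character vector of marker names that must be present as
#'   columns. Unknown columns are preserved.
#' @return A `cell_table`.
#' @export
read_cell_table <- function(path, panel) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  cell_table(df, panel)
}

#' Write a cell table to CSV with a provenance sidecar
#'
#' Writes the table as CSV and a `<path>.json` sidecar recording the
#' schema version, marker panel and row count.
#'
#' @param table A `cell_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  sidecar <- list(schema = "cell_table",
                  schema_version = CELL_TABLE_SCHEMA_VERSION,
                  panel = panel_of(table),
                  n_cells = nrow(table),
                  package = "tmestruct")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Remove hot-pixel-affected cells
#'
#' Cells overlapping aggregates of hot pixels carry spurious intensity and
#' are removed before any downstream analysis.
#'
#' @param table A `cell_table` with a `hot_pixel_flag` column.
#' @return The table with all flagged rows removed.
#' @export
filter_cells <- function(table) {
  stopifnot_cols(table, "hot_pixel_flag", "cell table")
  n_flagged <- sum(table$hot_pixel_flag)
  if (n_flagged == nrow(table) && n_flagged > 0)
    warning("all cells are hot-pixel flagged; returning empty table")
  if (n_flagged > 0)
    message(sprintf("filter_cells: removed %d hot-pixel-flagged cell(s)",
                    n_flagged))
  out <- table[!table$hot_pixel_flag, , drop = FALSE]
  attr(out, "panel") <- panel_of(table)
  class(out) <- class(table)
  out
}

#' Construct a labeled region mask
#'
#' @param image_id Image identifier the mask belongs to.
#' @param kind `"tumor"` or `"vessel"`.
#' @param grid Integer matrix; 0 = background, positive values = region
#'   ids. Row index runs along y, column index along x.
#' @param pixel_size_um Edge length of one pixel in micrometers.
#' @return A `mask_grid` object.
#' @export
mask_grid <- function(image_id, kind = c("tumor", "vessel"), grid,
                      pixel_size_um = 1) {
  kind <- match.arg(kind)
  if (!is.matrix(grid)) stop("grid must be a matrix")
  if (any(grid < 0)) stop("grid values must be >= 0")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  ids <- sort(unique(grid[grid > 0]))
  if (length(ids) && !identical(as.integer(ids), seq_along(ids)))
    grid <- matrix(match(grid, c(0, ids), nomatch = 1L) - 1L,
                   nrow = nrow(grid))  # re-label to contiguous ids
  structure(list(image_id = image_id, kind = kind,
                 grid = grid, pixel_size_um = pixel_size_um),
            class = "mask_grid")
}

#' Read a mask raster from a CSV integer grid or single-channel TIFF
#'
#' @param path `.csv` (comma-separated integers, no header) or `.tif(f)`.
#' @param image_id,kind,pixel_size_um Passed to [mask_grid()].
#' @return A `mask_grid`.
#' @export
read_mask <- function(path, image_id, kind, pixel_size_um = 1) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF masks requires the 'tiff' package")
    g <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(g)) == 3) g <- g[, , 1]
    grid <- matrix(as.integer(round(g)), nrow = nrow(g))
  } else {
    grid <- as.matrix(read.csv(path, header = FALSE))
    dimnames(grid) <- NULL
    storage.mode(grid) <- "integer"
  }
  mask_grid(image_id, kind, grid, pixel_size_um)
}

#' Write a mask raster as a CSV integer grid
#' @param mask A `mask_grid`.
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  write.table(mask$grid, path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

## boundary pixels of the positive region (4-neighborhood), as pixel-center
## coordinates in um. Cheap proxy for the full positive set when computing
## distances: the nearest positive pixel to an outside point is on the
## boundary.
mask_boundary_um <- function(mask) {
  g <- mask$grid > 0
  if (!any(g)) return(cbind(x = numeric(0), y = numeric(0)))
  nr <- nrow(g); nc <- ncol(g)
  pad <- function(m) m
  up    <- rbind(g[-1, , drop = FALSE], FALSE)
  down  <- rbind(FALSE, g[-nr, , drop = FALSE])
  left  <- cbind(g[, -1, drop = FALSE], FALSE)
  right <- cbind(FALSE, g[, -nc, drop = FALSE])
  boundary <- g & !(up & down & left & right)
  idx <- which(boundary, arr.ind = TRUE)
  ps <- mask$pixel_size_um
  cbind(x = (idx[, "col"] - 0.5) * ps, y = (idx[, "row"] - 0.5) * ps)
}

## row/col of the pixel containing a point; clamped to the grid
point_pixel <- function(x, y, mask) {
  ps <- mask$pixel_size_um
  row <- pmin(pmax(floor(y / ps) + 1L, 1L), nrow(mask$grid))
  col <- pmin(pmax(floor(x / ps) + 1L, 1L), ncol(mask$grid))
  cbind(row, col)
}

#' Flag cells related to a labeled region mask
#'
#' A cell is "related" to a mask when its centroid lies inside a positive
#' region or within `contact_um` (inclusive) of a region pixel center — a
#' geometric proxy for mask-overlap relatedness when full cell masks are
#' unavailable, at the same 8 micrometer scale used for cell-cell
#' contacts. Sets `in_tumor_mask` or `in_vessel_mask` according to the
#' mask kind.
#'
#' @param table A `cell_table` (single image).
#' @param mask A `mask_grid` with matching `image_id`.
#' @param contact_um Contact distance in micrometers (default 8).
#' @return The table with the overlap flag column updated.
#' @export
attach_mask_overlap <- function(table, mask, contact_um = 8) {
  imgs <- unique(table$image_id)
  if (!identical(as.character(mask$image_id), as.character(imgs)))
    stop("mask image_id does not match cell table image_id")
  flag_col <- if (mask$kind == "tumor") "in_tumor_mask" else "in_vessel_mask"
  n <- nrow(table)
  flags <- logical(n)
  if (n > 0 && any(mask$grid > 0)) {
    px <- point_pixel(table$x_um, table$y_um, mask)
    inside <- mask$grid[cbind(px[, 1], px[, 2])] > 0
    flags[inside] <- TRUE
    if (any(!inside)) {
      bd <- mask_boundary_um(mask)
      out_idx <- which(!inside)
      ## chunked min-distance to boundary pixel centers
      for (start in seq(1, length(out_idx), by = 512)) {
        ii <- out_idx[start:min(start + 511, length(out_idx))]
        dx <- outer(table$x_um[ii], bd[, "x"], "-")
        dy <- outer(table$y_um[ii], bd[, "y"], "-")
        dmin <- sqrt(apply(dx * dx + dy * dy, 1, min))
        flags[ii] <- dmin <= contact_um + 1e-9
      }
    }
  }
  table[[flag_col]] <- flags
  table
}

#' Read and validate a per-patient clinical table
#'
#' Expects columns `patient_id`, `er_status` (pos/neg), `her2_status`
#' (pos/neg/unknown), `dss_time_months` (> 0), `dss_event` (0/1), and
#' optionally `intrinsic_subtype` and `intclust`.
#'
#' @param path CSV path.
#' @return Validated data.frame, one row per patient.
#' @export
read_clinical <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' @rdname read_clinical
#' @param df Clinical data.frame to validate in place.
#' @export
validate_clinical <- function(df) {
  stopifnot_cols(df, c("patient_id", "er_status", "her2_status",
                       "dss_time_months", "dss_event"), "clinical table")
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id")
  if (any(df$dss_time_months <= 0)) stop("dss_time_months must be > 0")
  if (!all(df$dss_event %in% c(0, 1))) stop("dss_event must be 0/1")
  if (!all(df$er_status %in% c("pos", "neg"))) stop("bad er_status")
  if (!all(df$her2_status %in% c("pos", "neg", "unknown")))
    stop("bad her2_status")
  df
}

#' Read a binary patient x alteration matrix
#'
#' @param path CSV with a `patient_id` column; remaining columns are 0/1
#'   alteration indicators.
#' @return Integer matrix with patient ids as rownames.
#' @export
read_alteration_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot_cols(df, "patient_id", "alteration table")
  m <- as.matrix(df[setdiff(names(df), "patient_id")])
  rownames(m) <- df$patient_id
  if (!all(m %in% c(0, 1))) stop("alteration entries must be 0/1")
  storage.mode(m) <- "integer"
  m
}
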