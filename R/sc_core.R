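# Data model and I/O for the pipeline: sparse expression tables with cell
# metadata, clonotype assignments, spatial spot grids, IHC cell tables and
# TIL density grids. All on-disk formats are plain text (Matrix Market +
# TSV/CSV with header rows).

# ---------------------------------------------------------------------------
# CellExpressionTable

#' Construct a cell expression table
#'
#' Bundles a sparse nonnegative-integer gene x cell count matrix with
#' per-cell metadata (patient, cell type, optional subtype). This is the main
#' input object of the pipeline.
#'
#' @param counts A genes x cells matrix coercible to \code{dgCMatrix}, with
#'   unique rownames (gene ids) and colnames (cell barcodes). Entries must be
#'   nonnegative integers.
#' @param cell_meta A data.frame with columns \code{barcode},
#'   \code{patient_id}, \code{cell_type} and optionally \code{subtype}; one
#'   row per cell, covering exactly the columns of \code{counts}.
#' @param cell_types Optional character vector: a controlled vocabulary for
#'   \code{cell_type}; values outside it are an error.
#' @return An object of class \code{cell_expression_table}: a list with
#'   elements \code{counts} (dgCMatrix), \code{gene_ids}, \code{cell_ids} and
#'   \code{cell_meta} (rows aligned to \code{cell_ids}).
#' @export
cell_expression_table <- function(counts, cell_meta, cell_types = NULL) {
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if ((is.null(rownames(counts)) && nrow(counts) > 0) ||
      (is.null(colnames(counts)) && ncol(counts) > 0))
    abort_tme("counts must carry gene rownames and cell colnames")
  gene_ids <- rownames(counts) %||% character(0)
  cell_ids <- colnames(counts) %||% character(0)
  if (anyDuplicated(gene_ids)) abort_tme("duplicate gene ids")
  if (anyDuplicated(cell_ids)) abort_tme("duplicate cell barcodes")
  x <- counts@x
  if (length(x)) {
    if (any(x < 0)) abort_tme("negative count in expression matrix")
    if (any(x != round(x))) abort_tme("non-integer count in expression matrix")
  }
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  req <- c("barcode", "patient_id", "cell_type")
  if (!all(req %in% names(cell_meta)))
    abort_tme("cell_meta must have columns: %s", paste(req, collapse = ", "))
  if (anyDuplicated(cell_meta$barcode)) abort_tme("duplicate barcode in cell_meta")
  if (!setequal(cell_meta$barcode, cell_ids))
    abort_tme("cell_meta barcodes do not match matrix columns")
  if (!is.null(cell_types) && !all(cell_meta$cell_type %in% cell_types))
    abort_tme("unknown cell_type value(s): %s",
              paste(setdiff(cell_meta$cell_type, cell_types), collapse = ", "))
  cell_meta <- cell_meta[match(cell_ids, cell_meta$barcode), , drop = FALSE]
  rownames(cell_meta) <- NULL
  if (!"subtype" %in% names(cell_meta))
    cell_meta$subtype <- rep(NA_character_, nrow(cell_meta))
  structure(
    list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
         cell_meta = cell_meta),
    class = "cell_expression_table"
  )
}

#' @export
print.cell_expression_table <- function(x, ...) {
  cat(sprintf("cell_expression_table: %d genes x %d cells, %d patients, %d cell types\n",
              length(x$gene_ids), length(x$cell_ids),
              length(unique(x$cell_meta$patient_id)),
              length(unique(x$cell_meta$cell_type))))
  invisible(x)
}

#' @export
dim.cell_expression_table <- function(x) dim(x$counts)

#' Read a cell expression table from Matrix Market + TSV files
#'
#' @param matrix_path Matrix Market coordinate file of counts (genes x cells).
#' @param genes_path TSV with header, first column = gene id.
#' @param barcodes_path TSV with header, first column = cell barcode.
#' @param meta_path TSV with header columns barcode, patient_id, cell_type
#'   and optionally subtype.
#' @param cell_types Optional controlled vocabulary for cell types.
#' @return A validated \code{\link{cell_expression_table}}.
#' @export
read_expression <- function(matrix_path, genes_path, barcodes_path, meta_path,
                            cell_types = NULL) {
  m <- Matrix::readMM(matrix_path)
  genes <- read.delim(genes_path, stringsAsFactors = FALSE)[[1]]
  barcodes <- read.delim(barcodes_path, stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
    abort_tme("dimension mismatch: matrix is %d x %d but %d genes, %d barcodes",
              nrow(m), ncol(m), length(genes), length(barcodes))
  dimnames(m) <- list(genes, barcodes)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  extra <- setdiff(meta$barcode, barcodes)
  if (length(extra))
    abort_tme("cells present in metadata but absent from matrix: %s",
              paste(utils::head(extra, 5), collapse = ", "))
  if (length(setdiff(barcodes, meta$barcode)))
    abort_tme("cells present in matrix but absent from metadata")
  cell_expression_table(m, meta, cell_types = cell_types)
}

#' Write a cell expression table to Matrix Market + TSV files
#'
#' Inverse of \code{\link{read_expression}}: integer counts round-trip
#' exactly.
#'
#' @param table A \code{cell_expression_table}.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written (matrix, genes, barcodes, meta).
#' @export
write_expression <- function(table, out_dir) {
  stopifnot(inherits(table, "cell_expression_table"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                                "cell_meta.tsv"))
  Matrix::writeMM(table$counts, paths[1])
  write_tsv_utf8(data.frame(gene_id = table$gene_ids), paths[2])
  write_tsv_utf8(data.frame(barcode = table$cell_ids), paths[3])
  write_tsv_utf8(table$cell_meta, paths[4])
  invisible(setNames(paths, c("matrix", "genes", "barcodes", "meta")))
}

write_tsv_utf8 <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
}

# ---------------------------------------------------------------------------
# ClonotypeTable

#' Construct / read a clonotype table
#'
#' One row per cell with a recovered TCR; cells without a receptor simply
#' have no row (never a sentinel string).
#'
#' @param records data.frame with columns \code{barcode}, \code{clonotype_id}.
#' @param expression_table Companion \code{cell_expression_table}; every
#'   barcode must exist there.
#' @param strict If TRUE (default) unknown barcodes are an error; otherwise
#'   they are dropped with a warning.
#' @return A data.frame of class \code{clonotype_table}.
#' @export
clonotype_table <- function(records, expression_table, strict = TRUE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!all(c("barcode", "clonotype_id") %in% names(records)))
    abort_tme("clonotype records need columns barcode, clonotype_id")
  records <- records[!is.na(records$clonotype_id) & records$clonotype_id != "", ,
                     drop = FALSE]
  if (anyDuplicated(records$barcode)) abort_tme("duplicate barcode in clonotype table")
  unknown <- setdiff(records$barcode, expression_table$cell_ids)
  if (length(unknown)) {
    if (strict)
      abort_tme("clonotype barcodes absent from expression table: %s",
                paste(utils::head(unknown, 5), collapse = ", "))
    warning(sprintf("dropping %d clonotype rows with unknown barcodes",
                    length(unknown)), call. = FALSE)
    records <- records[!records$barcode %in% unknown, , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(records[, c("barcode", "clonotype_id")],
            class = c("clonotype_table", "data.frame"))
}

#' @rdname clonotype_table
#' @param path CSV with columns barcode, clonotype_id.
#' @export
read_clonotypes <- function(path, expression_table, strict = TRUE) {
  clonotype_table(read.csv(path, stringsAsFactors = FALSE),
                  expression_table, strict = strict)
}

#' @rdname clonotype_table
#' @param clonotypes A \code{clonotype_table} to serialize.
#' @export
write_clonotypes <- function(clonotypes, path) {
  write.csv(as.data.frame(clonotypes), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SpotGrid

#' Construct a spatial spot grid
#'
#' Spots live on the Visium array lattice: integer (array_row, array_col)
#' with matching parity (row + col even), so each interior spot has exactly 6
#' first-ring hexagonal neighbors.
#'
#' @param spots data.frame with columns \code{barcode}, \code{array_row},
#'   \code{array_col}, plus one numeric count column per gene of interest.
#' @return data.frame of class \code{spot_grid}; gene columns are recorded in
#'   \code{attr(, "genes")}.
#' @export
spot_grid <- function(spots) {
  spots <- as.data.frame(spots, stringsAsFactors = FALSE)
  req <- c("barcode", "array_row", "array_col")
  if (!all(req %in% names(spots)))
    abort_tme("spot grid needs columns: %s", paste(req, collapse = ", "))
  if (anyDuplicated(spots$barcode)) abort_tme("duplicate spot barcode")
  r <- spots$array_row; c0 <- spots$array_col
  if (any(r != round(r)) || any(c0 != round(c0)))
    abort_tme("array coordinates must be integers")
  if (anyDuplicated(paste(r, c0))) abort_tme("duplicate (array_row, array_col) pair")
  if (any((r + c0) %% 2 != 0))
    abort_tme("array_row + array_col must be even (hexagonal offset convention)")
  genes <- setdiff(names(spots), req)
  for (g in genes) {
    if (!is.numeric(spots[[g]]) || any(spots[[g]] < 0) || any(!is.finite(spots[[g]])))
      abort_tme("gene column '%s' must hold finite nonnegative counts", g)
  }
  rownames(spots) <- NULL
  structure(spots, class = c("spot_grid", "data.frame"), genes = genes)
}

#' @rdname spot_grid
#' @param path TSV file with a header row.
#' @export
read_spots <- function(path) spot_grid(read.delim(path, stringsAsFactors = FALSE))

#' @rdname spot_grid
#' @param grid A \code{spot_grid} to serialize.
#' @export
write_spots <- function(grid, path) {
  write_tsv_utf8(as.data.frame(grid), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# IhcCellTable and TilGrid

#' Construct an IHC cell table
#'
#' One row per detected cell with its region, the region's annotated kind and
#' area, and the DAB staining intensity bin (0 = negative, 1+ weak,
#' 2+ moderate, 3+ strong).
#'
#' @param cells data.frame with columns \code{region_id}, \code{region_kind}
#'   (\code{"epithelial"} or \code{"TIL"}), \code{region_area_mm2} (> 0) and
#'   \code{intensity} (integer 0..3).
#' @return data.frame of class \code{ihc_cell_table}.
#' @export
ihc_cell_table <- function(cells) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  req <- c("region_id", "region_kind", "region_area_mm2", "intensity")
  if (!all(req %in% names(cells)))
    abort_tme("IHC table needs columns: %s", paste(req, collapse = ", "))
  if (!all(cells$intensity %in% 0:3))
    abort_tme("staining intensity must be in {0,1,2,3}")
  if (!all(cells$region_kind %in% c("epithelial", "TIL")))
    abort_tme("region_kind must be 'epithelial' or 'TIL'")
  if (any(!is.finite(cells$region_area_mm2)) || any(cells$region_area_mm2 <= 0))
    abort_tme("region areas must be strictly positive")
  area_per_region <- tapply(cells$region_area_mm2, cells$region_id,
                            function(a) length(unique(a)))
  if (any(area_per_region > 1))
    abort_tme("inconsistent area within a region")
  rownames(cells) <- NULL
  structure(cells, class = c("ihc_cell_table", "data.frame"))
}

#' @rdname ihc_cell_table
#' @param path CSV file with a header row.
#' @export
read_ihc <- function(path) ihc_cell_table(read.csv(path, stringsAsFactors = FALSE))

#' @rdname ihc_cell_table
#' @param cells_table An \code{ihc_cell_table} to serialize.
#' @export
write_ihc <- function(cells_table, path) {
  write.csv(as.data.frame(cells_table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a TIL density grid
#'
#' Whole-slide images are divided into grids (0.25 mm^2 by default); each
#' grid carries an intratumoral and a stromal tumor-infiltrating-lymphocyte
#' density in cells/mm^2.
#'
#' @param grids data.frame with columns \code{grid_id},
#'   \code{intratumoral_density}, \code{stromal_density} and optionally
#'   \code{grid_area_mm2} (default 0.25).
#' @return data.frame of class \code{til_grid}.
#' @export
til_grid <- function(grids) {
  grids <- as.data.frame(grids, stringsAsFactors = FALSE)
  req <- c("grid_id", "intratumoral_density", "stromal_density")
  if (!all(req %in% names(grids)))
    abort_tme("TIL grid needs columns: %s", paste(req, collapse = ", "))
  if (!"grid_area_mm2" %in% names(grids)) grids$grid_area_mm2 <- 0.25
  for (col in c("intratumoral_density", "stromal_density")) {
    v <- grids[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      abort_tme("'%s' must be finite and nonnegative", col)
  }
  if (anyDuplicated(grids$grid_id)) abort_tme("duplicate grid_id")
  rownames(grids) <- NULL
  structure(grids, class = c("til_grid", "data.frame"))
}

#' @rdname til_grid
#' @param path CSV file with a header row.
#' @export
read_til_grid <- function(path) til_grid(read.csv(path, stringsAsFactors = FALSE))

#' @rdname til_grid
#' @param grid_table A \code{til_grid} to serialize.
#' @export
write_til_grid <- function(grid_table, path) {
  write.csv(as.data.frame(grid_table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
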