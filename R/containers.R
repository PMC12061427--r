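#' Expression matrix container
#'
#' A `gene_matrix` is a dense numeric matrix of cells/spots (rows) by genes
#' (columns) carrying unique cell and gene identifiers plus a processing
#' `stage` flag: `"raw"` (non-negative counts), `"lognorm"` (library-size
#' normalized, log1p-transformed) or `"scaled"` (per-gene z-scores).
#'
#' @param values numeric matrix, rows = cells/spots, columns = genes.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   existing rownames or `cell1..cellN`.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   existing colnames or `gene1..geneG`.
#' @param stage one of `"raw"`, `"lognorm"`, `"scaled"`.
#' @return An object of class `gene_matrix`: the matrix with dimnames set and
#'   a `stage` attribute.
#' @export
gene_matrix <- function(values, cell_ids = NULL, gene_ids = NULL,
                        stage = c("raw", "lognorm", "scaled")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values)
    if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  }
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length (", length(cell_ids), ") != row count (", nrow(values), ")")
  if (length(gene_ids) != ncol(values))
    stop("gene_ids length (", length(gene_ids), ") != column count (", ncol(values), ")")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ", paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (stage == "raw" && any(values < 0))
    stop("negative raw count at row ", which(rowSums(values < 0) > 0)[1])
  dimnames(values) <- list(as.character(cell_ids), as.character(gene_ids))
  structure(values, stage = stage, class = c("gene_matrix", "matrix", "array"))
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("gene_matrix: %d cells x %d genes (stage: %s)\n",
              nrow(x), ncol(x), gm_stage(x)))
  invisible(x)
}

#' Processing stage of a gene_matrix
#' @param gm a `gene_matrix`.
#' @return `"raw"`, `"lognorm"` or `"scaled"`.
#' @export
gm_stage <- function(gm) attr(gm, "stage")

gm_values <- function(gm) {
  out <- unclass(gm)
  attr(out, "stage") <- NULL
  out
}

gm_replace <- function(gm, values, stage = gm_stage(gm)) {
  gene_matrix(values, cell_ids = rownames(gm), gene_ids = colnames(gm), stage = stage)
}

#' Spatial transcriptomics slice
#'
#' Pairs a [gene_matrix()] with 2-D spot/cell coordinates and optional
#' per-spot categorical labels (e.g. cortical layers).
#'
#' @param expr a `gene_matrix`.
#' @param coords numeric matrix/data frame with one (x, y) row per cell of
#'   `expr`; rownames, if present, must match the expression cell ids.
#' @param labels optional character/factor vector of per-spot labels.
#' @param slice_id identifier string for the slice.
#' @return An object of class `spatial_slice`.
#' @export
spatial_slice <- function(expr, coords, labels = NULL, slice_id = "slice1") {
  stopifnot(inherits(expr, "gene_matrix"))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2) stop("coords must have exactly 2 columns")
  if (nrow(coords) != nrow(expr))
    stop("coords row count (", nrow(coords), ") != expression cell count (", nrow(expr), ")")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!is.null(rownames(coords)) && !identical(rownames(coords), rownames(expr)))
    stop("coords rownames do not match expression cell ids")
  rownames(coords) <- rownames(expr)
  colnames(coords) <- c("x", "y")
  if (!is.null(labels)) {
    if (length(labels) != nrow(expr))
      stop("labels length != cell count")
    labels <- as.character(labels)
    names(labels) <- rownames(expr)
  }
  structure(list(expr = expr, coords = coords, labels = labels,
                 slice_id = as.character(slice_id)),
            class = "spatial_slice")
}

#' @export
print.spatial_slice <- function(x, ...) {
  cat(sprintf("spatial_slice '%s': %d spots x %d genes (stage: %s)%s\n",
              x$slice_id, nrow(x$expr), ncol(x$expr), gm_stage(x$expr),
              if (is.null(x$labels)) "" else
                sprintf(", %d label classes", length(unique(x$labels)))))
  invisible(x)
}

#' Read an expression matrix from disk
#'
#' Supports a dense CSV (cells as rows, first column cell ids, header row of
#' gene names) or MatrixMarket coordinate format with companion gene and cell
#' name files (`genes.tsv` / `barcodes.tsv` convention, genes as MTX rows).
#'
#' @param path CSV file, or MTX file for `format = "mtx"`.
#' @param format `"csv"` or `"mtx"`.
#' @param genes_path,cells_path companion name files for MTX (default:
#'   `genes.tsv` and `barcodes.tsv` next to the MTX file).
#' @return A `gene_matrix` with `stage = "raw"`, input ordering preserved.
#' @export
read_gene_matrix <- function(path, format = c("csv", "mtx"),
                             genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("malformed header: expected id column plus gene columns in ", path)
    ids <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    if (any(!is.finite(vals))) {
      bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
      stop("non-numeric or missing value at line ", bad[1] + 1L, " of ", path)
    }
    if (any(vals < 0)) {
      bad <- which(rowSums(vals < 0) > 0)[1]
      stop("negative raw count at line ", bad + 1L, " of ", path)
    }
    gene_matrix(vals, cell_ids = ids, gene_ids = colnames(df)[-1], stage = "raw")
  } else {
    dir <- dirname(path)
    if (is.null(genes_path)) genes_path <- file.path(dir, "genes.tsv")
    if (is.null(cells_path)) cells_path <- file.path(dir, "barcodes.tsv")
    m <- Matrix::readMM(path)
    genes <- utils::read.table(genes_path, sep = "\t", stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.table(cells_path, sep = "\t", stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(genes))
      stop("MTX row count (", nrow(m), ") != gene name count (", length(genes), ")")
    if (ncol(m) != length(cells))
      stop("MTX column count (", ncol(m), ") != cell name count (", length(cells), ")")
    vals <- t(as.matrix(m))                     # genes-as-rows on disk -> cells-as-rows
    if (any(vals < 0)) stop("negative raw count in ", path)
    gene_matrix(vals, cell_ids = cells, gene_ids = genes, stage = "raw")
  }
}

#' Write an expression matrix to CSV
#' @param gm a `gene_matrix`.
#' @param path output CSV path (cells as rows, first column `cell_id`).
#' @export
write_gene_matrix <- function(gm, path) {
  df <- data.frame(cell_id = rownames(gm), gm_values(gm), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spatial slice (expression + coordinates + optional labels)
#'
#' @param expr_path expression CSV/MTX path (see [read_gene_matrix()]).
#' @param coords_path coordinate CSV with columns `id,x,y`.
#' @param labels_path optional label CSV with columns `id,label`; label ids
#'   absent from the expression are ignored with a warning.
#' @param format expression format, `"csv"` or `"mtx"`.
#' @param slice_id slice identifier.
#' @return A `spatial_slice` with rows aligned by id.
#' @export
read_spatial_slice <- function(expr_path, coords_path, labels_path = NULL,
                               format = c("csv", "mtx"), slice_id = "slice1") {
  expr <- read_gene_matrix(expr_path, format = match.arg(format))
  co <- utils::read.csv(coords_path, stringsAsFactors = FALSE)
  if (ncol(co) < 3) stop("coordinate CSV must have columns id,x,y")
  ids <- as.character(co[[1]])
  missing_ids <- setdiff(rownames(expr), ids)
  if (length(missing_ids))
    stop("coordinates missing for ids: ", paste(missing_ids, collapse = ", "))
  co <- co[match(rownames(expr), ids), , drop = FALSE]
  coords <- as.matrix(co[, 2:3])
  rownames(coords) <- rownames(expr)
  labels <- NULL
  if (!is.null(labels_path)) {
    lb <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    lids <- as.character(lb[[1]])
    extra <- setdiff(lids, rownames(expr))
    if (length(extra))
      warning(length(extra), " label ids not present in expression were ignored")
    hit <- match(rownames(expr), lids)
    if (anyNA(hit))
      stop("labels missing for ids: ",
           paste(rownames(expr)[is.na(hit)], collapse = ", "))
    labels <- as.character(lb[[2]][hit])
  }
  spatial_slice(expr, coords, labels = labels, slice_id = slice_id)
}

#' Write a spatial slice to CSV files
#' @param slice a `spatial_slice`.
#' @param expr_path,coords_path,labels_path output paths (labels written only
#'   when the slice carries them and `labels_path` is given).
#' @export
write_spatial_slice <- function(slice, expr_path, coords_path, labels_path = NULL) {
  write_gene_matrix(slice$expr, expr_path)
  utils::write.csv(data.frame(id = rownames(slice$coords),
                              x = slice$coords[, 1], y = slice$coords[, 2]),
                   coords_path, row.names = FALSE)
  if (!is.null(labels_path) && !is.null(slice$labels))
    utils::write.csv(data.frame(id = rownames(slice$coords), label = slice$labels),
                     labels_path, row.names = FALSE)
  invisible(coords_path)
}
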