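# Standard-format I/O: Matrix Market triplet + genes.tsv/barcodes.tsv +
# metadata CSV for count matrices; cells.csv (+ optional panel MTX) for
# spatial maps.

#' Write a count matrix as Matrix Market + gene/barcode lists
#'
#' Produces `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and
#' `cell_metadata.csv` under `dir`.
#'
#' @param m `cohort_counts`-like list with `counts` and `cell_meta`.
#' @param dir output directory (created if needed).
#' @export
write_counts <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(m$counts), file.path(dir, "barcodes.tsv"))
  utils::write.csv(m$cell_meta, file.path(dir, "cell_metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load a count matrix
#'
#' Reads either a Matrix Market triplet directory (`matrix.mtx` +
#' `genes.tsv` + `barcodes.tsv`, optional `cell_metadata.csv`) or a dense
#' CSV (genes in rows, first column gene IDs).
#'
#' @param path directory (MTX layout) or CSV file.
#' @return `cohort_counts`-like list (`counts`, `cell_meta`).
#' @export
load_counts <- function(path) {
  if (dir.exists(path)) {
    counts <- methods::as(Matrix::readMM(file.path(path, "matrix.mtx")),
                          "CsparseMatrix")
    genes <- readLines(file.path(path, "genes.tsv"))
    cells <- readLines(file.path(path, "barcodes.tsv"))
    if (nrow(counts) != length(genes)) {
      stop("matrix has ", nrow(counts), " rows but genes.tsv lists ",
           length(genes), " genes")
    }
    if (ncol(counts) != length(cells)) {
      stop("matrix has ", ncol(counts), " columns but barcodes.tsv lists ",
           length(cells), " barcodes")
    }
    if (anyDuplicated(genes)) stop("duplicate gene IDs in genes.tsv")
    if (anyDuplicated(cells)) stop("duplicate cell IDs in barcodes.tsv")
    dimnames(counts) <- list(genes, cells)
    meta_path <- file.path(path, "cell_metadata.csv")
    cell_meta <- NULL
    if (file.exists(meta_path)) {
      cell_meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
      missing <- setdiff(cells, cell_meta$cell_id)
      if (length(missing)) {
        stop("barcode(s) missing from metadata: ",
             paste(utils::head(missing, 5L), collapse = ", "))
      }
      cell_meta <- cell_meta[match(cells, cell_meta$cell_id), , drop = FALSE]
      rownames(cell_meta) <- cell_meta$cell_id
    }
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- df[[1L]]
    if (anyDuplicated(genes)) stop("duplicate gene IDs in ", path)
    counts <- methods::as(Matrix::Matrix(as.matrix(df[, -1L, drop = FALSE]),
                                         sparse = TRUE), "CsparseMatrix")
    rownames(counts) <- genes
    cell_meta <- NULL
  }
  if (any(counts@x < 0)) stop("negative count entries")
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "cohort_counts")
}

#' Write spatial sections as cells.csv (+ panel MTX)
#'
#' @param sections list of `spatial_map`s.
#' @param dir output directory.
#' @export
write_spatial <- function(sections, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- do.call(rbind, lapply(sections, function(s) s$cells))
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  panels <- lapply(sections, function(s) s$panel_counts)
  if (!any(vapply(panels, is.null, logical(1)))) {
    pc <- do.call(cbind, panels)
    Matrix::writeMM(pc, file.path(dir, "panel.mtx"))
    writeLines(rownames(pc), file.path(dir, "panel_genes.tsv"))
    writeLines(colnames(pc), file.path(dir, "panel_barcodes.tsv"))
  }
  invisible(dir)
}

#' Load spatial sections from cells.csv (+ optional panel MTX)
#'
#' When panel counts are present, applies the spatial QC rules: cells with
#' fewer than `spatial_min_counts` total panel counts are excluded
#' (strictly "less than 25" by default), and panel genes detected in more
#' than `max_detect_frac` of cells are dropped from the panel.
#'
#' @param path directory containing `cells.csv` (and optionally
#'   `panel.mtx` + `panel_genes.tsv` + `panel_barcodes.tsv`).
#' @param spatial_min_counts minimum panel counts per cell (default 25,
#'   inclusive).
#' @param max_detect_frac panel genes detected above this cell fraction
#'   are excluded (default 0.95, strict).
#' @return list of `spatial_map`s, one per section_id.
#' @export
load_spatial <- function(path, spatial_min_counts = 25L,
                         max_detect_frac = 0.95) {
  cells <- utils::read.csv(file.path(path, "cells.csv"),
                           stringsAsFactors = FALSE)
  need <- c("cell_id", "section_id", "x_um", "y_um")
  if (!all(need %in% colnames(cells))) {
    stop("cells.csv must contain columns ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(cells$x_um)) || !all(is.finite(cells$y_um))) {
    stop("non-finite coordinates in cells.csv")
  }
  panel <- NULL
  if (file.exists(file.path(path, "panel.mtx"))) {
    panel <- methods::as(Matrix::readMM(file.path(path, "panel.mtx")),
                         "CsparseMatrix")
    dimnames(panel) <- list(
      readLines(file.path(path, "panel_genes.tsv")),
      readLines(file.path(path, "panel_barcodes.tsv")))
    tot <- Matrix::colSums(panel)
    keep_cells <- colnames(panel)[tot >= spatial_min_counts]
    cells <- cells[cells$cell_id %in% keep_cells, , drop = FALSE]
    panel <- panel[, cells$cell_id, drop = FALSE]
    detect <- Matrix::rowMeans(panel > 0)
    panel <- panel[detect <= max_detect_frac, , drop = FALSE]
  }
  lapply(split(cells, cells$section_id), function(sc) {
    structure(list(section_id = sc$section_id[1L], cells = sc,
                   panel_counts = if (is.null(panel)) NULL else
                     panel[, sc$cell_id, drop = FALSE]),
              class = "spatial_map")
  })
}
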