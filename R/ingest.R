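#' Write a cohort as 10x-style MatrixMarket plus metadata tables
#'
#' Writes \code{matrix.mtx} (genes x cells, raw counts),
#' \code{features.tsv} (gene id, mito flag, sex flag), \code{barcodes.tsv},
#' \code{cells.tsv} (cell id, donor id, cell type) and \code{donors.tsv}.
#' All files are plain text.
#'
#' @param cohort A \linkS4class{CellCohort} holding raw counts.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(methods::is(cohort, "CellCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(countsAssay(cohort), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  rd <- rowData(cohort)
  utils::write.table(
    data.frame(gene_id = rownames(cohort),
               mito = as.logical(rd$mito %||% grepl("^MT-", rownames(cohort))),
               sex = as.logical(rd$sex %||% FALSE)),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(colnames(cohort), file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(cell_id = colnames(cohort),
               donor_id = colData(cohort)$donor_id,
               cell_type = colData(cohort)$cell_type),
    file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(donorData(cohort)),
                     file.path(dir, "donors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from MatrixMarket plus metadata tables
#'
#' Reads the layout written by \code{\link{writeCohort}} (MatrixMarket
#' triplet with features/barcodes in the 10x convention: feature rows,
#' barcode columns) together with \code{cells.tsv} and \code{donors.tsv}.
#' Row and column order is preserved from the files. Dimension mismatches,
#' duplicate identifiers and negative counts raise descriptive errors.
#'
#' @param dir Directory holding \code{matrix.mtx}, \code{features.tsv},
#'   \code{barcodes.tsv}, \code{cells.tsv}, \code{donors.tsv}.
#' @return A \linkS4class{CellCohort} in the raw-counts state.
#' @export
readCohort <- function(dir) {
  need <- c("matrix.mtx", "features.tsv", "barcodes.tsv", "cells.tsv",
            "donors.tsv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss))
    stop("missing input file(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  feats <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(feats) != nrow(m))
    stop(sprintf("features.tsv has %d rows but the matrix has %d gene rows",
                 nrow(feats), nrow(m)), call. = FALSE)
  if (length(barcodes) != ncol(m))
    stop(sprintf("barcodes.tsv has %d ids but the matrix has %d cell columns",
                 length(barcodes), ncol(m)), call. = FALSE)
  if (anyDuplicated(feats$gene_id))
    stop("duplicate gene ids in features.tsv", call. = FALSE)
  if (anyDuplicated(barcodes))
    stop("duplicate cell ids in barcodes.tsv", call. = FALSE)
  if (any(m@x < 0)) stop("negative counts in matrix.mtx", call. = FALSE)
  rownames(m) <- feats$gene_id
  colnames(m) <- barcodes
  cells <- utils::read.table(file.path(dir, "cells.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  if (!all(barcodes %in% cells$cell_id))
    stop("cells.tsv does not cover every barcode", call. = FALSE)
  cells <- cells[match(barcodes, cells$cell_id), ]
  donors <- utils::read.table(file.path(dir, "donors.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = DataFrame(donor_id = cells$donor_id,
                        cell_type = cells$cell_type, row.names = barcodes),
    rowData = DataFrame(mito = as.logical(feats$mito %||%
                          grepl("^MT-", feats$gene_id)),
                        sex = as.logical(feats$sex %||% FALSE),
                        row.names = feats$gene_id))
  out <- methods::new("CellCohort", sce,
                      donorData = DataFrame(donors,
                                            row.names = donors$donor_id))
  methods::validObject(out)
  out
}

#' Read a dense gene-by-cell TSV as a cohort matrix
#'
#' A convenience reader for small toy matrices: a tab-separated table with
#' gene ids in the first column and one column per cell. Cell and donor
#' annotation may be supplied directly.
#'
#' @param path TSV file, genes in rows, cells in columns, header row of
#'   cell ids.
#' @param cells Optional data.frame with \code{cell_id}, \code{donor_id},
#'   \code{cell_type}; defaults to one pseudo-donor, cell type "other".
#' @param donors Optional data.frame with \code{donor_id} and \code{age}.
#' @return A \linkS4class{CellCohort} in the raw-counts state.
#' @export
readDenseMatrix <- function(path, cells = NULL, donors = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           row.names = 1, check.names = FALSE)
  m <- methods::as(as.matrix(tab), "CsparseMatrix")
  if (any(m < 0)) stop("negative values in dense matrix", call. = FALSE)
  if (is.null(cells))
    cells <- data.frame(cell_id = colnames(m), donor_id = "D001",
                        cell_type = "other")
  if (is.null(donors))
    donors <- data.frame(donor_id = unique(cells$donor_id), age = 50)
  cells <- cells[match(colnames(m), cells$cell_id), ]
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = DataFrame(donor_id = cells$donor_id,
                        cell_type = cells$cell_type,
                        row.names = colnames(m)),
    rowData = DataFrame(mito = grepl("^MT-", rownames(m)),
                        sex = rep(FALSE, nrow(m)), row.names = rownames(m)))
  out <- methods::new("CellCohort", sce,
                      donorData = DataFrame(donors,
                                            row.names = donors$donor_id))
  methods::validObject(out)
  out
}
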