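#' Nucleus-level quality-control thresholds
#'
#' Defaults follow the standard stringent snRNA-seq gates for post mortem
#' cortex: nuclei with 1,200-100,000 read counts, 800-12,000 detected
#' genes, and strictly less than 5\% mitochondrial transcripts are kept.
#' Count and gene bounds are inclusive; the mitochondrial bound is strict.
#'
#' @param minCounts,maxCounts Inclusive bounds on per-cell total counts.
#' @param minGenes,maxGenes Inclusive bounds on genes detected per cell.
#' @param maxMitoFraction Strict upper bound on the mitochondrial fraction.
#' @return A validated list of class \code{QCThresholds}.
#' @export
qcThresholds <- function(minCounts = 1200, maxCounts = 100000,
                         minGenes = 800, maxGenes = 12000,
                         maxMitoFraction = 0.05) {
  if (minCounts >= maxCounts)
    stop("minCounts must be < maxCounts", call. = FALSE)
  if (minGenes >= maxGenes)
    stop("minGenes must be < maxGenes", call. = FALSE)
  if (maxMitoFraction < 0 || maxMitoFraction > 1)
    stop("maxMitoFraction must lie in [0, 1]", call. = FALSE)
  structure(list(minCounts = minCounts, maxCounts = maxCounts,
                 minGenes = minGenes, maxGenes = maxGenes,
                 maxMitoFraction = maxMitoFraction), class = "QCThresholds")
}

# Ensure total_counts / n_genes_detected / mito_fraction are in colData.
# Supplied values win (supports toy fixtures); missing ones are computed
# from the counts matrix.
addCellQCMetrics <- function(cohort) {
  cd <- colData(cohort)
  m <- countsAssay(cohort)
  if (is.null(cd$total_counts)) cd$total_counts <- Matrix::colSums(m)
  if (is.null(cd$n_genes_detected))
    cd$n_genes_detected <- Matrix::colSums(m > 0)
  if (is.null(cd$mito_fraction)) {
    mitoFlag <- rowData(cohort)$mito %||% grepl("^MT-", rownames(cohort))
    mitoCounts <- if (any(mitoFlag))
      Matrix::colSums(m[mitoFlag, , drop = FALSE]) else 0
    cd$mito_fraction <- ifelse(cd$total_counts > 0,
                               mitoCounts / cd$total_counts, 0)
  }
  colData(cohort) <- cd
  cohort
}

#' Filter nuclei on counts, detected genes and mitochondrial fraction
#'
#' Retains exactly the cells with \code{minCounts <= total_counts <=
#' maxCounts}, \code{minGenes <= n_genes_detected <= maxGenes} and
#' \code{mito_fraction < maxMitoFraction}. QC metrics already present in
#' \code{colData} are trusted; missing ones are computed from the counts
#' matrix. Per-filter removal counts are reported via \code{message} and
#' stored in \code{metadata(x)$qcRemoval}.
#'
#' @param cohort A \linkS4class{CellCohort} in the raw-counts state.
#' @param thresholds A \code{\link{qcThresholds}} object.
#' @return The filtered \linkS4class{CellCohort}.
#' @export
qcFilter <- function(cohort, thresholds = qcThresholds()) {
  stopifnot(methods::is(cohort, "CellCohort"),
            inherits(thresholds, "QCThresholds"))
  if ("logcounts" %in% assayNames(cohort))
    stop("qcFilter expects a raw-counts cohort (filter before normalizing)",
         call. = FALSE)
  cohort <- addCellQCMetrics(cohort)
  cd <- colData(cohort)
  okCounts <- cd$total_counts >= thresholds$minCounts &
              cd$total_counts <= thresholds$maxCounts
  okGenes <- cd$n_genes_detected >= thresholds$minGenes &
             cd$n_genes_detected <= thresholds$maxGenes
  okMito <- cd$mito_fraction < thresholds$maxMitoFraction
  keep <- okCounts & okGenes & okMito
  removal <- c(counts = sum(!okCounts), genes = sum(!okGenes),
               mito = sum(!okMito), total_removed = sum(!keep))
  message(sprintf(
    "qcFilter: kept %d/%d cells (failed counts: %d, genes: %d, mito: %d)",
    sum(keep), length(keep), removal[["counts"]], removal[["genes"]],
    removal[["mito"]]))
  if (!any(keep)) warning("qcFilter removed every cell", call. = FALSE)
  out <- cohort[, keep]
  metadata(out)$qcRemoval <- removal
  out
}

#' Log-normalize raw counts (counts-per-scale, log1p)
#'
#' Each entry becomes \code{log(1 + count / total_counts * scale)}, the
#' standard CP10K transform at the default scale of 10,000. Adds a
#' \code{"logcounts"} assay; the raw counts are kept.
#'
#' @param cohort A \linkS4class{CellCohort} in the raw-counts state.
#' @param scale Library-size scale factor (default 10,000).
#' @return The cohort with a \code{"logcounts"} assay added.
#' @export
logNormalize <- function(cohort, scale = 10000) {
  stopifnot(methods::is(cohort, "CellCohort"))
  if ("logcounts" %in% assayNames(cohort))
    stop("cohort is already log-normalized", call. = FALSE)
  m <- countsAssay(cohort)
  totals <- Matrix::colSums(m)
  if (any(totals == 0))
    stop("cells with zero total counts: ",
         paste(utils::head(colnames(m)[totals == 0], 10), collapse = ", "),
         call. = FALSE)
  norm <- m %*% Matrix::Diagonal(x = scale / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m)
  SummarizedExperiment::assay(cohort, "logcounts") <- norm
  metadata(cohort)$logNormScale <- scale
  cohort
}

#' Remove mitochondrial and sex-related genes
#'
#' Drops all genes flagged mitochondrial or sex-related, preserving the
#' order of the remaining genes. Flags are taken from \code{rowData}
#' columns \code{mito}/\code{sex}; when absent, mitochondrial genes are
#' identified by the "MT-" prefix and sex-related genes by the optional
#' \code{sexGenes} list.
#'
#' @param cohort A \linkS4class{CellCohort}.
#' @param sexGenes Optional character vector of sex-related gene ids used
#'   when \code{rowData(cohort)$sex} is absent.
#' @return The cohort restricted to unflagged genes.
#' @export
dropMitoSexGenes <- function(cohort, sexGenes = NULL) {
  stopifnot(methods::is(cohort, "CellCohort"))
  rd <- rowData(cohort)
  mito <- rd$mito %||% grepl("^MT-", rownames(cohort))
  sex <- rd$sex %||% (rownames(cohort) %in% (sexGenes %||% character()))
  drop <- mito | sex
  if (all(drop)) warning("all genes are flagged; empty matrix returned",
                         call. = FALSE)
  message(sprintf("dropMitoSexGenes: removed %d mito + %d sex genes, %d remain",
                  sum(mito), sum(sex & !mito), sum(!drop)))
  cohort[!drop, ]
}
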