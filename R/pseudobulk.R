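## Pseudobulk aggregation: simple (one sample per donor per unit) and
## bootstrapped (n replicates of k sampled cells per donor per unit), at
## cell-type level or at the glia/neuron/all-cells levels.

# Cells belonging to a unit (cell type or pooling level), per donor.
unitCellIndex <- function(cohort, unit) {
  types <- resolveUnit(unit, available = unique(colData(cohort)$cell_type))
  idx <- which(colData(cohort)$cell_type %in% types)
  split(idx, as.character(colData(cohort)$donor_id[idx]))
}

makePseudobulkSet <- function(exprs, cd, cohort, mode, config = list()) {
  dd <- donorData(cohort)
  cd$age <- as.numeric(dd$age[match(cd$donor_id, dd$donor_id)])
  if (!is.null(dd$condition))
    cd$condition <- as.character(dd$condition[match(cd$donor_id, dd$donor_id)])
  se <- SummarizedExperiment(assays = list(exprs = exprs), colData = cd)
  out <- methods::new("PseudobulkSet", se)
  metadata(out)$mode <- mode
  metadata(out)$config <- config
  methods::validObject(out)
  out
}

#' Simple pseudobulk: one averaged sample per donor per unit
#'
#' Averages log-normalized expression over all of a donor's cells of the
#' given unit. Donors with no cells of the unit are omitted with a
#' message.
#'
#' @param cohort A log-normalized \linkS4class{CellCohort}.
#' @param unit A cell type, or \code{"glia"} (oligodendrocytes, astrocytes,
#'   OPCs), \code{"neuron"} (excitatory + inhibitory), or
#'   \code{"all_cells"} (the six major types).
#' @return A \linkS4class{PseudobulkSet} with one sample per donor
#'   (\code{replicate = 0}).
#' @export
simplePseudobulk <- function(cohort, unit) {
  stopifnot(methods::is(cohort, "CellCohort"))
  L <- logcountsAssay(cohort)
  byDonor <- unitCellIndex(cohort, unit)
  allDonors <- as.character(donorData(cohort)$donor_id)
  omitted <- setdiff(allDonors, names(byDonor))
  if (length(omitted))
    message("simplePseudobulk: omitting donors with no '", unit, "' cells: ",
            paste(omitted, collapse = ", "))
  byDonor <- byDonor[order(match(names(byDonor), allDonors))]
  exprs <- if (length(byDonor))
    vapply(byDonor, function(idx)
      Matrix::rowMeans(L[, idx, drop = FALSE]), numeric(nrow(L)))
  else numeric(0)
  exprs <- matrix(exprs, nrow = nrow(L), ncol = length(byDonor),
                  dimnames = list(rownames(L),
                                  sprintf("%s.%s.r0", names(byDonor), unit)))
  nd <- length(byDonor)
  cd <- DataFrame(donor_id = names(byDonor) %||% character(0),
                  unit = rep(unit, nd), replicate = rep(0L, nd),
                  n_cells_used = unname(lengths(byDonor)),
                  sampled_with_replacement = rep(FALSE, nd),
                  row.names = colnames(exprs))
  makePseudobulkSet(exprs, cd, cohort, "simple")
}

#' Choose the bootstrap sample size k by donor coverage
#'
#' Scans a candidate grid and returns the largest k such that at least a
#' \code{quantile} fraction of donors have more than k cells of the unit —
#' so that sampling k cells without replacement leaves variability for at
#' least that share of donors. When no grid value qualifies, the grid
#' minimum is returned with a warning.
#'
#' @param cohort A \linkS4class{CellCohort}.
#' @param unit Cell type or level.
#' @param quantile Required fraction of donors with more than k cells
#'   (default 0.8).
#' @param grid Candidate values of k.
#' @return A single integer k.
#' @export
#' @examples
#' ## donors with 30/60/80/120/200 unit cells and grid {25,50,100,200}
#' ## yield k = 50: 4/5 donors have more than 50 cells.
chooseK <- function(cohort, unit, quantile = 0.8,
                    grid = c(25, 50, 100, 200, 500)) {
  byDonor <- unitCellIndex(cohort, unit)
  if (!length(byDonor))
    stop("no donor has cells of unit '", unit, "'", call. = FALSE)
  counts <- lengths(byDonor)
  ok <- vapply(grid, function(k) mean(counts > k) >= quantile, logical(1))
  if (!any(ok)) {
    warning("no candidate k satisfies the ", quantile * 100,
            "% coverage rule; returning the grid minimum", call. = FALSE)
    return(as.integer(min(grid)))
  }
  as.integer(max(grid[ok]))
}

#' Bootstrapped pseudobulk: repeated k-cell averages per donor
#'
#' For each donor with at least one cell of the unit, draws
#' \code{nReplicates} samples of \code{k} cells — without replacement when
#' the donor has at least k cells, with replacement otherwise (flagged in
#' \code{sampled_with_replacement}) — and averages the log-normalized
#' expression of each draw. Replicate random streams are derived per
#' (donor, replicate) from the seed, so the result is independent of
#' iteration order.
#'
#' @param cohort A log-normalized \linkS4class{CellCohort}.
#' @param unit Cell type or level (see \code{\link{simplePseudobulk}}).
#' @param k Cells per sample; \code{NULL} selects k with
#'   \code{\link{chooseK}}.
#' @param nReplicates Samples per donor (default 100).
#' @param seed Integer seed.
#' @return A \linkS4class{PseudobulkSet} with \code{nReplicates} samples
#'   per retained donor.
#' @export
bootstrapPseudobulk <- function(cohort, unit, k = NULL, nReplicates = 100,
                                seed = 1L) {
  stopifnot(methods::is(cohort, "CellCohort"), nReplicates >= 1)
  L <- logcountsAssay(cohort)
  if (is.null(k)) k <- chooseK(cohort, unit)
  stopifnot(k >= 1)
  byDonor <- unitCellIndex(cohort, unit)
  allDonors <- as.character(donorData(cohort)$donor_id)
  byDonor <- byDonor[order(match(names(byDonor), allDonors))]
  if (!length(byDonor)) {
    exprs <- matrix(numeric(0), nrow = nrow(L), ncol = 0,
                    dimnames = list(rownames(L), character(0)))
    cd <- DataFrame(donor_id = character(0), unit = character(0),
                    replicate = integer(0), n_cells_used = integer(0),
                    sampled_with_replacement = logical(0))
    return(makePseudobulkSet(exprs, cd, cohort, "bootstrap"))
  }
  blocks <- vector("list", length(byDonor))
  cds <- vector("list", length(byDonor))
  for (d in seq_along(byDonor)) {
    donor <- names(byDonor)[d]
    idx <- byDonor[[d]]
    nc <- length(idx)
    replace <- nc < k
    donorKey <- match(donor, allDonors)
    Ld <- as.matrix(L[, idx, drop = FALSE])
    ii <- jj <- vector("list", nReplicates)
    for (r in seq_len(nReplicates)) {
      set.seed(seedStream(seed, 7L, donorKey, r))
      ii[[r]] <- sample.int(nc, k, replace = replace)
      jj[[r]] <- rep.int(r, k)
    }
    S <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                              dims = c(nc, nReplicates))
    blocks[[d]] <- as.matrix(Ld %*% S) / k
    colnames(blocks[[d]]) <- sprintf("%s.%s.r%d", donor, unit,
                                     seq_len(nReplicates))
    cds[[d]] <- DataFrame(donor_id = donor, unit = unit,
                          replicate = seq_len(nReplicates),
                          n_cells_used = k,
                          sampled_with_replacement = replace,
                          row.names = colnames(blocks[[d]]))
  }
  exprs <- do.call(cbind, blocks)
  rownames(exprs) <- rownames(L)
  makePseudobulkSet(exprs, do.call(rbind, cds), cohort, "bootstrap",
                    config = list(k = k, nReplicates = nReplicates,
                                  seed = seed))
}

#' Level pseudobulk: pooled glia / neuron / all-cells samples
#'
#' Pools the constituent cell types of a level before aggregation: glia =
#' oligodendrocytes + astrocytes + OPCs; neuron = excitatory + inhibitory
#' neurons; all_cells = all six major types. A thin wrapper over
#' \code{\link{simplePseudobulk}} / \code{\link{bootstrapPseudobulk}}.
#'
#' @param cohort A log-normalized \linkS4class{CellCohort}.
#' @param level One of \code{"glia"}, \code{"neuron"}, \code{"all_cells"}.
#' @param mode \code{"simple"} or \code{"bootstrap"}.
#' @param k,nReplicates,seed Passed to \code{\link{bootstrapPseudobulk}}
#'   when \code{mode = "bootstrap"}; typical level k is 100 or 500.
#' @return A \linkS4class{PseudobulkSet}.
#' @export
levelPseudobulk <- function(cohort, level = c("glia", "neuron", "all_cells"),
                            mode = c("simple", "bootstrap"), k = 100,
                            nReplicates = 100, seed = 1L) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  if (mode == "simple") simplePseudobulk(cohort, level)
  else bootstrapPseudobulk(cohort, level, k = k, nReplicates = nReplicates,
                           seed = seed)
}

#' Per-cell samples for single-cell clocks
#'
#' Packs the individual cells of a unit into the same sample container the
#' pseudobulk builders produce (one "sample" per cell,
#' \code{n_cells_used = 1}), so that single-cell clocks share the training
#' and prediction machinery.
#'
#' @param cohort A log-normalized \linkS4class{CellCohort}.
#' @param unit Cell type or level.
#' @return A \linkS4class{PseudobulkSet} with one column per cell and
#'   \code{metadata(x)$mode == "single_cell"}.
#' @export
cellSamples <- function(cohort, unit) {
  stopifnot(methods::is(cohort, "CellCohort"))
  L <- logcountsAssay(cohort)
  byDonor <- unitCellIndex(cohort, unit)
  idx <- unlist(byDonor, use.names = FALSE)
  exprs <- as.matrix(L[, idx, drop = FALSE])
  cd <- DataFrame(donor_id = as.character(colData(cohort)$donor_id[idx]),
                  unit = unit, replicate = seq_along(idx),
                  n_cells_used = 1L, sampled_with_replacement = FALSE,
                  row.names = colnames(exprs))
  makePseudobulkSet(exprs, cd, cohort, "single_cell")
}
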