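suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
  library(Matrix)
})

# Build a CellCohort directly from a counts matrix, bypassing the
# simulator, for full control in QC/pseudobulk toys.
toyCohort <- function(counts, donor, cellType = "astrocyte", ages = NULL,
                      mito = NULL, sex = NULL, cellMeta = NULL,
                      donorExtra = NULL) {
  counts <- as(as.matrix(counts), "CsparseMatrix")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("G%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  donor <- rep_len(donor, ncol(counts))
  cellType <- rep_len(cellType, ncol(counts))
  donors <- unique(donor)
  if (is.null(ages)) ages <- seq(30, 80, length.out = length(donors))
  dd <- DataFrame(donor_id = donors, age = ages, row.names = donors)
  if (!is.null(donorExtra)) for (nm in names(donorExtra))
    dd[[nm]] <- donorExtra[[nm]]
  cd <- DataFrame(donor_id = donor, cell_type = cellType,
                  row.names = colnames(counts))
  if (!is.null(cellMeta)) for (nm in names(cellMeta))
    cd[[nm]] <- cellMeta[[nm]]
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd,
    rowData = DataFrame(
      mito = mito %||% grepl("^MT-", rownames(counts)),
      sex = sex %||% rep(FALSE, nrow(counts)),
      row.names = rownames(counts)))
  new("CellCohort", sce, donorData = dd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small simulated cohort with a clear age signal, log-normalized.
signalCohort <- function(nDonors = 12, nGenes = 300, seed = 3,
                         cellTypes = c(astrocyte = 60), ageEffect = 0.03,
                         ...) {
  spec <- cohortSpec(nDonors = nDonors, nGenes = nGenes,
                     nAgeGenesPos = round(nGenes / 15),
                     nAgeGenesNeg = round(nGenes / 15),
                     cellTypes = cellTypes, ageEffect = ageEffect,
                     seed = seed, ...)
  logNormalize(simulateCohort(spec))
}

# Hand-built ClockModel with five explicit fold models.
toyModel <- function(universe, foldCoefs, intercepts,
                     trainingMeans = NULL, mode = "simple_pseudobulk",
                     unit = "astrocyte") {
  stopifnot(length(foldCoefs) == 5, length(intercepts) == 5)
  folds <- lapply(1:5, function(f) {
    co <- setNames(numeric(length(universe)), universe)
    co[names(foldCoefs[[f]])] <- foldCoefs[[f]]
    list(coefficients = co, intercept = intercepts[f], lambda = 1,
         trainDonors = paste0("D", setdiff(1:5, f)))
  })
  new("ClockModel", unit = unit, mode = mode, alpha = 0.5, folds = folds,
      geneUniverse = universe,
      trainingGeneMeans = trainingMeans %||%
        setNames(numeric(length(universe)), universe),
      donorFolds = setNames(1:5, paste0("D", 1:5)),
      cvPredictions = data.frame(), seed = 1L)
}

# PseudobulkSet built directly from an expression matrix.
toyPseudobulk <- function(exprs, donor, ages, unit = "astrocyte",
                          replicate = NULL, mode = "simple") {
  exprs <- as.matrix(exprs)
  if (is.null(colnames(exprs)))
    colnames(exprs) <- sprintf("s%03d", seq_len(ncol(exprs)))
  donor <- rep_len(donor, ncol(exprs))
  ageOf <- setNames(ages, unique(donor))
  cd <- DataFrame(donor_id = donor, unit = unit,
                  replicate = replicate %||% rep(0L, ncol(exprs)),
                  n_cells_used = 1L, sampled_with_replacement = FALSE,
                  age = as.numeric(ageOf[donor]),
                  row.names = colnames(exprs))
  se <- SummarizedExperiment(assays = list(exprs = exprs), colData = cd)
  out <- new("PseudobulkSet", se)
  metadata(out)$mode <- mode
  out
}

## ---- independent oracles -------------------------------------------------

# Closed-form ridge under the documented lambda scaling of fitElasticNet
# (fixed lambda, alpha = 0, standardize = FALSE).
ridgeOracle <- function(X, y, lambda) {
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sdn <- sqrt(mean((y - mean(y))^2))
  beta <- solve(crossprod(Xc) + n * lambda / sdn * diag(ncol(X)),
                crossprod(Xc, y))
  list(coefficients = as.numeric(beta),
       intercept = as.numeric(mean(y) - colMeans(X) %*% beta))
}

# Brute-force Spearman rank correlation (no ties assumed in callers).
bfSpearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Brute-force Benjamini-Hochberg step-up: adjusted p-values.
bfBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Vectorized approximate Spearman p-values (t approximation), for
# genome-wide null-calibration checks.
spearmanPApprox <- function(E, age) {
  n <- length(age)
  ra <- rank(age)
  rE <- t(apply(E, 1, rank))
  rho <- as.numeric(stats::cor(t(rE), ra))
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), df = n - 2))
}
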