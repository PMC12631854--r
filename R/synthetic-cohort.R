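#' Specify a synthetic snRNA-seq aging cohort
#'
#' Describes a cohort of donors with ages drawn uniformly over
#' \code{ageRange}, six (by default) cell types with per-donor
#' negative-binomial cell counts, and a gene program in which a subset of
#' genes drift monotonically with age on the log scale while the rest are
#' age-independent. A fraction of the null genes is flagged mitochondrial /
#' sex-related so that gene-removal steps can be exercised. Optionally a
#' fraction of donors is labelled diseased; their expression is sampled at
#' an effective age of \code{age + ageShift} years, which makes
#' age-acceleration recovery a well-defined ground truth.
#'
#' @param nDonors Number of donors.
#' @param ageRange Numeric length-2, minimum and maximum age in years.
#' @param cellTypes Named numeric vector: expected cells per donor for each
#'   cell type.
#' @param cellCountDispersion Negative-binomial dispersion of per-donor cell
#'   counts (variance = mu + dispersion * mu^2).
#' @param nGenes Total genes simulated.
#' @param nAgeGenesPos,nAgeGenesNeg Number of genes with positive / negative
#'   age trends.
#' @param ageEffect Slope of log-mean expression per year for age genes
#'   (scalar, or vector over the age genes).
#' @param ageEffectCellTypes Optional character vector restricting the age
#'   effect to some cell types; \code{NULL} applies it in all types.
#' @param baseExpression Median per-gene mean count per cell; per-gene base
#'   means are log-normal around it.
#' @param countDispersion Negative-binomial dispersion of UMI counts.
#' @param mitoGeneFraction,sexGeneFraction Fractions of (null) genes flagged
#'   mitochondrial / sex-related.
#' @param diseaseFraction Fraction of donors labelled diseased.
#' @param ageShift Years added to a diseased donor's effective age when
#'   sampling expression.
#' @param seed Integer root seed. Gene-level parameters (base means, age
#'   effects, flags) are derived from a dedicated gene stream of this seed,
#'   so cohorts drawn with different donor seeds (see
#'   \code{\link{makeExternalVariant}}) share the same gene program.
#' @return A validated list of class \code{CohortSpec}.
#' @export
#' @examples
#' spec <- cohortSpec(nDonors = 8, nGenes = 50, cellTypes = c(astrocyte = 20))
cohortSpec <- function(nDonors = 31,
                       ageRange = c(18, 94),
                       cellTypes = c(oligodendrocyte = 400, astrocyte = 120,
                                     microglia = 100, OPC = 80,
                                     excitatory_neuron = 250,
                                     inhibitory_neuron = 150),
                       cellCountDispersion = 0.1,
                       nGenes = 2000,
                       nAgeGenesPos = 50, nAgeGenesNeg = 50,
                       ageEffect = 0.02,
                       ageEffectCellTypes = NULL,
                       baseExpression = 0.3,
                       countDispersion = 0.8,
                       mitoGeneFraction = 0.02,
                       sexGeneFraction = 0.01,
                       diseaseFraction = 0,
                       ageShift = 0,
                       seed = 1L) {
  bad <- function(field, why)
    stop("invalid CohortSpec: '", field, "' ", why, call. = FALSE)
  if (!is.numeric(nDonors) || length(nDonors) != 1L || nDonors < 1)
    bad("nDonors", "must be a positive count")
  if (!is.numeric(ageRange) || length(ageRange) != 2L ||
      ageRange[1] >= ageRange[2] || ageRange[1] <= 0)
    bad("ageRange", "must be positive (min, max) with min < max")
  if (is.null(names(cellTypes)) || any(!nzchar(names(cellTypes))) ||
      any(cellTypes <= 0))
    bad("cellTypes", "must be a named vector of positive mean cell counts")
  if (cellCountDispersion < 0) bad("cellCountDispersion", "must be >= 0")
  if (nGenes < 1) bad("nGenes", "must be a positive count")
  if (nAgeGenesPos < 0 || nAgeGenesNeg < 0)
    bad("nAgeGenesPos/nAgeGenesNeg", "must be non-negative")
  if (nAgeGenesPos + nAgeGenesNeg > nGenes)
    bad("nAgeGenesPos", "+ nAgeGenesNeg must not exceed nGenes")
  nAge <- nAgeGenesPos + nAgeGenesNeg
  if (length(ageEffect) != 1L && length(ageEffect) != nAge && nAge > 0)
    bad("ageEffect", "must be scalar or one value per age gene")
  if (baseExpression <= 0) bad("baseExpression", "must be positive")
  if (countDispersion < 0) bad("countDispersion", "must be >= 0")
  if (mitoGeneFraction < 0 || mitoGeneFraction > 1)
    bad("mitoGeneFraction", "must lie in [0, 1]")
  if (sexGeneFraction < 0 || sexGeneFraction > 1)
    bad("sexGeneFraction", "must lie in [0, 1]")
  nFlag <- round(mitoGeneFraction * nGenes) + round(sexGeneFraction * nGenes)
  if (nAge + nFlag > nGenes)
    bad("mitoGeneFraction", "+ sexGeneFraction leaves too few null genes")
  if (diseaseFraction < 0 || diseaseFraction > 1)
    bad("diseaseFraction", "must lie in [0, 1]")
  if (!is.numeric(ageShift) || length(ageShift) != 1L)
    bad("ageShift", "must be a single number of years")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    bad("seed", "must be a single integer")
  structure(list(
    nDonors = as.integer(nDonors), ageRange = as.numeric(ageRange),
    cellTypes = cellTypes, cellCountDispersion = cellCountDispersion,
    nGenes = as.integer(nGenes),
    nAgeGenesPos = as.integer(nAgeGenesPos),
    nAgeGenesNeg = as.integer(nAgeGenesNeg),
    ageEffect = ageEffect, ageEffectCellTypes = ageEffectCellTypes,
    baseExpression = baseExpression, countDispersion = countDispersion,
    mitoGeneFraction = mitoGeneFraction, sexGeneFraction = sexGeneFraction,
    diseaseFraction = diseaseFraction, ageShift = ageShift,
    seed = as.integer(seed)), class = "CohortSpec")
}

# Gene program shared across donor redraws of the same spec: base means,
# true age effects, mito/sex flags.
geneProgram <- function(spec) {
  set.seed(seedStream(spec$seed, 101L))
  nG <- spec$nGenes
  nPos <- spec$nAgeGenesPos; nNeg <- spec$nAgeGenesNeg
  effect <- numeric(nG)
  eff <- rep_len(abs(spec$ageEffect), nPos + nNeg)
  if (nPos > 0) effect[seq_len(nPos)] <- eff[seq_len(nPos)]
  if (nNeg > 0) effect[nPos + seq_len(nNeg)] <- -eff[nPos + seq_len(nNeg)]
  baseMean <- stats::rlnorm(nG, meanlog = log(spec$baseExpression), sdlog = 1)
  nullIdx <- which(effect == 0)
  nMito <- round(spec$mitoGeneFraction * nG)
  nSex <- round(spec$sexGeneFraction * nG)
  flagged <- if (nMito + nSex > 0) sample(nullIdx, nMito + nSex) else integer()
  mito <- sex <- logical(nG)
  if (nMito > 0) mito[flagged[seq_len(nMito)]] <- TRUE
  if (nSex > 0) sex[flagged[nMito + seq_len(nSex)]] <- TRUE
  ids <- sprintf("G%05d", seq_len(nG))
  ids[mito] <- sub("^G", "MT-", ids[mito])
  list(ids = ids, baseMean = baseMean, effect = effect,
       mito = mito, sex = sex)
}

#' Generate a synthetic snRNA-seq aging cohort
#'
#' Draws donor ages uniformly over the spec's age range, per-donor cell
#' counts per cell type from a negative binomial, and raw UMI counts from a
#' negative binomial whose log-mean for age gene g in a cell of donor d is
#' \code{log(base_g) + effect_g * (effectiveAge_d - midAge)}, where
#' \code{effectiveAge = age + ageShift} for diseased donors and midAge is
#' the centre of the age range. Null genes have age-independent means.
#' Cell-to-cell depth varies through a log-normal size factor. The result
#' is fully reproducible from the spec's seed: all randomness is drawn from
#' sub-seeds derived with \code{\link{seedStream}} per donor and cell type.
#'
#' @param spec A \code{\link{cohortSpec}}.
#' @param donorSeed Seed for the donor-level draw (ages, conditions, cell
#'   counts, UMI counts). Defaults to \code{spec$seed}; pass a different
#'   value to redraw donors under the same gene program.
#' @return A \linkS4class{CellCohort} with a raw \code{"counts"} assay,
#'   per-cell \code{donor_id}/\code{cell_type}, per-gene truth columns
#'   (\code{mito}, \code{sex}, \code{age_effect}, \code{base_mean}) and a
#'   donor table (age, sex, PMI, condition, brain_ph).
#' @export
#' @examples
#' co <- simulateCohort(cohortSpec(nDonors = 6, nGenes = 40,
#'                                 cellTypes = c(astrocyte = 15), seed = 1))
#' co
simulateCohort <- function(spec, donorSeed = spec$seed) {
  stopifnot(inherits(spec, "CohortSpec"))
  genes <- geneProgram(spec)
  midAge <- mean(spec$ageRange)

  set.seed(seedStream(donorSeed, 202L))
  n <- spec$nDonors
  donorIds <- sprintf("D%03d", seq_len(n))
  age <- stats::runif(n, spec$ageRange[1], spec$ageRange[2])
  sexD <- sample(c("F", "M"), n, replace = TRUE)
  pmi <- stats::runif(n, 2, 24)
  brainPh <- stats::runif(n, 6.0, 7.2)
  condition <- rep("control", n)
  nDis <- round(spec$diseaseFraction * n)
  if (nDis > 0) condition[sample(n, nDis)] <- "disease"
  effAge <- age + ifelse(condition == "disease", spec$ageShift, 0)

  types <- names(spec$cellTypes)
  sizeCells <- if (spec$cellCountDispersion > 0)
    1 / spec$cellCountDispersion else Inf
  nCells <- matrix(0L, n, length(types), dimnames = list(donorIds, types))
  for (i in seq_len(n)) for (j in seq_along(types)) {
    nCells[i, j] <- max(1L, if (is.finite(sizeCells))
      stats::rnbinom(1, mu = spec$cellTypes[j], size = sizeCells)
      else as.integer(round(spec$cellTypes[j])))
  }

  sizeCounts <- if (spec$countDispersion > 0) 1 / spec$countDispersion else Inf
  restrict <- spec$ageEffectCellTypes
  blocks <- vector("list", n * length(types))
  cellDonor <- cellType <- cellId <- vector("list", n * length(types))
  b <- 0L
  for (i in seq_len(n)) for (j in seq_along(types)) {
    b <- b + 1L
    nc <- nCells[i, j]
    set.seed(seedStream(donorSeed, 303L, i, j))
    sf <- stats::rlnorm(nc, 0, 0.3)
    eff <- genes$effect
    if (!is.null(restrict) && !(types[j] %in% restrict)) eff <- 0 * eff
    mu_g <- genes$baseMean * exp(eff * (effAge[i] - midAge))
    mu <- outer(mu_g, sf)
    cnt <- if (is.finite(sizeCounts))
      stats::rnbinom(length(mu), mu = mu, size = sizeCounts)
      else stats::rpois(length(mu), mu)
    blocks[[b]] <- methods::as(
      matrix(cnt, nrow = spec$nGenes, ncol = nc), "CsparseMatrix")
    cellDonor[[b]] <- rep(donorIds[i], nc)
    cellType[[b]] <- rep(types[j], nc)
    cellId[[b]] <- sprintf("%s_%s_c%04d", donorIds[i], types[j], seq_len(nc))
  }
  counts <- do.call(cbind, blocks)
  rownames(counts) <- genes$ids
  colnames(counts) <- unlist(cellId)

  dd <- DataFrame(donor_id = donorIds, age = age, sex = sexD, PMI = pmi,
                  condition = condition, brain_ph = brainPh,
                  effective_age = effAge, row.names = donorIds)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = DataFrame(donor_id = unlist(cellDonor),
                        cell_type = unlist(cellType),
                        row.names = colnames(counts)),
    rowData = DataFrame(mito = genes$mito, sex = genes$sex,
                        age_effect = genes$effect,
                        base_mean = genes$baseMean,
                        row.names = genes$ids))
  out <- methods::new("CellCohort", sce, donorData = dd)
  metadata(out)$cohortSpec <- spec
  methods::validObject(out)
  out
}

#' Simulate an external validation cohort
#'
#' Redraws an independent set of donors under the same gene program as
#' \code{cohort} (same base means, age effects and flags), then removes a
#' fixed fraction of genes entirely, emulating external datasets in which
#' part of a clock's gene universe was never measured. The removed gene
#' list is recorded in \code{metadata(x)$removedGenes}.
#'
#' @param cohort A \linkS4class{CellCohort} produced by
#'   \code{\link{simulateCohort}}.
#' @param geneDropoutFraction Fraction of genes to remove, in [0, 1).
#' @param seed Seed for the independent donor draw and the gene dropout.
#' @return A \linkS4class{CellCohort} with \code{round(fraction * nGenes)}
#'   genes removed.
#' @export
makeExternalVariant <- function(cohort, geneDropoutFraction = 0, seed = 1L) {
  stopifnot(methods::is(cohort, "CellCohort"))
  if (!is.numeric(geneDropoutFraction) || geneDropoutFraction < 0 ||
      geneDropoutFraction >= 1)
    stop("geneDropoutFraction must lie in [0, 1)", call. = FALSE)
  spec <- metadata(cohort)$cohortSpec
  if (is.null(spec))
    stop("cohort carries no CohortSpec; makeExternalVariant needs a ",
         "simulated cohort", call. = FALSE)
  ext <- simulateCohort(spec, donorSeed = seed)
  nDrop <- round(geneDropoutFraction * nrow(ext))
  removed <- character()
  if (nDrop > 0) {
    set.seed(seedStream(seed, 404L))
    removed <- sort(sample(rownames(ext), nDrop))
    ext <- ext[setdiff(rownames(ext), removed), ]
  }
  metadata(ext)$removedGenes <- removed
  ext
}
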