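#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData colData<- rowData<- assay<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

#' CellCohort: a single-nucleus expression cohort with donor metadata
#'
#' A \code{CellCohort} extends \linkS4class{SingleCellExperiment}. The
#' \code{"counts"} assay holds raw UMI counts (genes x cells); after
#' \code{\link{logNormalize}} a \code{"logcounts"} assay is added. Per-cell
#' annotation lives in \code{colData} (\code{donor_id}, \code{cell_type} and,
#' once computed, \code{total_counts}, \code{n_genes_detected},
#' \code{mito_fraction}); per-gene flags (\code{mito}, \code{sex}) live in
#' \code{rowData}; per-donor covariates (age in years, sex, PMI in hours,
#' condition, optional brain pH / hemisphere) live in the \code{donorData}
#' slot.
#'
#' @slot donorData A \link[S4Vectors]{DataFrame} with one row per donor;
#'   must contain unique \code{donor_id} and positive \code{age}.
#'
#' @seealso \code{\link{simulateCohort}}, \code{\link{readCohort}},
#'   \code{\link{qcFilter}}, \code{\link{logNormalize}}
#' @export
setClass("CellCohort",
  contains = "SingleCellExperiment",
  slots = c(donorData = "DataFrame"))

setValidity("CellCohort", function(object) {
  msgs <- character()
  cd <- colData(object)
  dd <- object@donorData
  if (!all(c("donor_id", "cell_type") %in% colnames(cd)))
    msgs <- c(msgs, "colData must contain 'donor_id' and 'cell_type'")
  if (!all(c("donor_id", "age") %in% colnames(dd)))
    msgs <- c(msgs, "donorData must contain 'donor_id' and 'age'")
  if ("donor_id" %in% colnames(dd)) {
    if (anyDuplicated(dd$donor_id))
      msgs <- c(msgs, "donorData donor_id values must be unique")
    if ("donor_id" %in% colnames(cd) &&
        !all(unique(cd$donor_id) %in% dd$donor_id))
      msgs <- c(msgs, "every cell's donor_id must appear in donorData")
  }
  if ("age" %in% colnames(dd) && any(dd$age <= 0))
    msgs <- c(msgs, "donor ages must be positive (years)")
  if (!is.null(colnames(object)) && anyDuplicated(colnames(object)))
    msgs <- c(msgs, "cell ids must be unique")
  if (!is.null(rownames(object)) && anyDuplicated(rownames(object)))
    msgs <- c(msgs, "gene ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' PseudobulkSet: aggregated expression samples
#'
#' A \code{PseudobulkSet} extends \linkS4class{SummarizedExperiment}. The
#' \code{"exprs"} assay holds mean log-normalized expression (genes x
#' samples). \code{colData} records, per sample: \code{donor_id},
#' \code{unit} (a cell type or one of \code{"glia"}, \code{"neuron"},
#' \code{"all_cells"}), \code{replicate} (0 for simple pseudobulk),
#' \code{n_cells_used}, \code{sampled_with_replacement}, and \code{age}.
#' \code{metadata(x)$mode} is \code{"simple"} or \code{"bootstrap"}.
#'
#' @seealso \code{\link{simplePseudobulk}}, \code{\link{bootstrapPseudobulk}}
#' @export
setClass("PseudobulkSet", contains = "SummarizedExperiment")

setValidity("PseudobulkSet", function(object) {
  msgs <- character()
  need <- c("donor_id", "unit", "replicate", "n_cells_used",
            "sampled_with_replacement", "age")
  if (!"exprs" %in% assayNames(object))
    msgs <- c(msgs, "assay 'exprs' is required")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msgs <- c(msgs, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  if ("n_cells_used" %in% colnames(colData(object)) &&
      ncol(object) > 0 && any(colData(object)$n_cells_used < 1))
    msgs <- c(msgs, "n_cells_used must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' ClockModel: a cross-validated elastic-net aging clock
#'
#' Holds the five per-fold elastic-net models from donor-level 5-fold
#' cross-validation, together with the gene universe, per-gene training
#' means (used to impute genes missing from external data), the donor fold
#' assignment, and the pooled out-of-fold (\code{cv_test}) predictions.
#'
#' @slot unit Cell type or level the clock was trained on.
#' @slot mode One of \code{"single_cell"}, \code{"simple_pseudobulk"},
#'   \code{"bootstrapped_pseudobulk"}.
#' @slot alpha Elastic-net mixing parameter (0 = ridge, 1 = lasso).
#' @slot folds List of 5 fold models, each with \code{coefficients} (named
#'   numeric over the gene universe), \code{intercept}, \code{lambda}, and
#'   \code{trainDonors}.
#' @slot geneUniverse Ordered gene identifiers the clock expects.
#' @slot trainingGeneMeans Per-gene mean expression over the samples the
#'   clock was trained on.
#' @slot donorFolds Named integer vector mapping donor to fold.
#' @slot cvPredictions data.frame of pooled cross-validation test
#'   predictions (sample_id, donor_id, unit, fold, chronological_age,
#'   predicted_age, source).
#' @slot seed Integer seed used for fold assignment and penalty selection.
#'
#' @seealso \code{\link{trainClock}}, \code{\link{extractFeatureGenes}},
#'   \code{\link{applyClockExternal}}
#' @export
setClass("ClockModel",
  slots = c(unit = "character", mode = "character", alpha = "numeric",
            folds = "list", geneUniverse = "character",
            trainingGeneMeans = "numeric", donorFolds = "integer",
            cvPredictions = "data.frame", seed = "integer"))

setValidity("ClockModel", function(object) {
  msgs <- character()
  if (length(object@folds) != 5L)
    msgs <- c(msgs, "a ClockModel holds exactly 5 folds")
  p <- length(object@geneUniverse)
  for (f in object@folds) {
    if (!all(c("coefficients", "intercept", "lambda", "trainDonors") %in%
             names(f)))
      msgs <- c(msgs, "each fold needs coefficients/intercept/lambda/trainDonors")
    else if (length(f$coefficients) != p)
      msgs <- c(msgs, "fold coefficients must span the gene universe")
  }
  if (length(object@trainingGeneMeans) != p)
    msgs <- c(msgs, "trainingGeneMeans must span the gene universe")
  if (!object@alpha >= 0 || !object@alpha <= 1)
    msgs <- c(msgs, "alpha must lie in [0, 1]")
  if (length(msgs)) unique(msgs) else TRUE
})

#' AgeAcceleration: residuals from the predicted-vs-chronological age line
#'
#' Produced by \code{\link{computeAgeAcceleration}}. \code{samples} holds one
#' row per prediction with its acceleration (years); \code{slope} and
#' \code{intercept} describe the least-squares line of predicted age on
#' chronological age that the accelerations are residuals of.
#'
#' @slot samples data.frame with sample_id, donor_id, chronological_age,
#'   predicted_age, acceleration (and condition when available).
#' @slot slope,intercept Coefficients of the fitted reference line.
#' @slot fitOn Which samples the line was fitted on ("all" or "control").
#' @export
setClass("AgeAcceleration",
  slots = c(samples = "data.frame", slope = "numeric",
            intercept = "numeric", fitOn = "character"))

setMethod("show", "CellCohort", function(object) {
  callNextMethod()
  cat(sprintf("donorData: %d donors (age %s-%s years)\n",
              nrow(object@donorData),
              format(min(object@donorData$age), digits = 3),
              format(max(object@donorData$age), digits = 3)))
})

setMethod("show", "PseudobulkSet", function(object) {
  cd <- colData(object)
  cat(sprintf(
    "PseudobulkSet: %d genes x %d samples (%s, unit(s): %s, %d donors)\n",
    nrow(object), ncol(object),
    if (is.null(metadata(object)$mode)) "?" else metadata(object)$mode,
    paste(unique(cd$unit), collapse = ","),
    length(unique(cd$donor_id))))
})

setMethod("show", "ClockModel", function(object) {
  fg <- tryCatch(nrow(extractFeatureGenes(object)), error = function(e) NA)
  cat(sprintf("ClockModel (%s, %s, alpha = %g)\n",
              object@unit, object@mode, object@alpha))
  cat(sprintf("  gene universe: %d genes; %d donors in %d folds\n",
              length(object@geneUniverse), length(object@donorFolds),
              length(object@folds)))
  cat(sprintf("  feature genes (non-zero in all folds): %s\n",
              ifelse(is.na(fg), "?", fg)))
  cat(sprintf("  cv_test predictions: %d rows\n", nrow(object@cvPredictions)))
})

setMethod("show", "AgeAcceleration", function(object) {
  cat(sprintf(
    "AgeAcceleration: %d samples; reference line predicted = %.3f + %.3f * age (fit on %s)\n",
    nrow(object@samples), object@intercept, object@slope, object@fitOn))
})
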