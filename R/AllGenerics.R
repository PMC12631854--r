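#' Access per-donor covariates
#'
#' @param x A \linkS4class{CellCohort}.
#' @return A \link[S4Vectors]{DataFrame} with one row per donor.
#' @export
setGeneric("donorData", function(x) standardGeneric("donorData"))

#' @rdname donorData
#' @export
setMethod("donorData", "CellCohort", function(x) x@donorData)

#' Pooled cross-validation test predictions of a clock
#'
#' @param x A \linkS4class{ClockModel}.
#' @return data.frame with one row per held-out sample prediction.
#' @export
setGeneric("cvPredictions", function(x) standardGeneric("cvPredictions"))

#' @rdname cvPredictions
#' @export
setMethod("cvPredictions", "ClockModel", function(x) x@cvPredictions)

#' Gene universe of a clock model
#'
#' @param x A \linkS4class{ClockModel}.
#' @return Character vector of ordered gene identifiers.
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname geneUniverse
#' @export
setMethod("geneUniverse", "ClockModel", function(x) x@geneUniverse)

#' Per-fold models of a clock
#'
#' @param x A \linkS4class{ClockModel}.
#' @return List of 5 fold models (coefficients, intercept, lambda,
#'   trainDonors).
#' @export
setGeneric("foldModels", function(x) standardGeneric("foldModels"))

#' @rdname foldModels
#' @export
setMethod("foldModels", "ClockModel", function(x) x@folds)

#' Donor-to-fold assignment of a clock
#'
#' @param x A \linkS4class{ClockModel}.
#' @return Named integer vector mapping donor_id to fold index.
#' @export
setGeneric("donorFolds", function(x) standardGeneric("donorFolds"))

#' @rdname donorFolds
#' @export
setMethod("donorFolds", "ClockModel", function(x) x@donorFolds)

#' Training-sample gene means of a clock
#'
#' Means are computed over the exact samples the clock was trained on and
#' are the values used to impute genes missing from external data.
#'
#' @param x A \linkS4class{ClockModel}.
#' @return Named numeric vector over the gene universe.
#' @export
setGeneric("trainingGeneMeans", function(x) standardGeneric("trainingGeneMeans"))

#' @rdname trainingGeneMeans
#' @export
setMethod("trainingGeneMeans", "ClockModel", function(x) x@trainingGeneMeans)

#' Per-sample accelerations
#'
#' @param x An \linkS4class{AgeAcceleration}.
#' @return data.frame with one row per sample, including the
#'   \code{acceleration} column (years).
#' @export
setGeneric("accelerations", function(x) standardGeneric("accelerations"))

#' @rdname accelerations
#' @export
setMethod("accelerations", "AgeAcceleration", function(x) x@samples)
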