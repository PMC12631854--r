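#' Serialize a clock model to JSON
#'
#' Writes a plain-text JSON document holding the clock's configuration
#' (unit, mode, alpha, seed), the ordered gene universe, per-gene training
#' means, the donor fold map, and each fold's intercept, penalty, training
#' donors and non-zero coefficients (sparse: gene name to value). The
#' pooled cv predictions are included as a record table.
#'
#' @param model A \linkS4class{ClockModel}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeClockModel <- function(model, path) {
  stopifnot(methods::is(model, "ClockModel"))
  folds <- lapply(model@folds, function(f) {
    nz <- f$coefficients[f$coefficients != 0]
    list(intercept = f$intercept, lambda = f$lambda,
         trainDonors = f$trainDonors, coefficients = as.list(nz))
  })
  doc <- list(format = "snClock/1", unit = model@unit, mode = model@mode,
              alpha = model@alpha, seed = model@seed,
              geneUniverse = model@geneUniverse,
              trainingGeneMeans = as.list(model@trainingGeneMeans),
              donorFolds = as.list(model@donorFolds),
              folds = folds, cvPredictions = model@cvPredictions)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a clock model from JSON
#'
#' @param path File written by \code{\link{writeClockModel}}.
#' @return A \linkS4class{ClockModel}.
#' @export
readClockModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "snClock/1"))
    stop("not a snClock model file: ", path, call. = FALSE)
  universe <- unlist(doc$geneUniverse, use.names = FALSE)
  folds <- lapply(doc$folds, function(f) {
    co <- stats::setNames(numeric(length(universe)), universe)
    nz <- unlist(f$coefficients)
    if (length(nz)) co[names(nz)] <- nz
    list(coefficients = co,
         intercept = as.numeric(f$intercept),
         lambda = as.numeric(f$lambda),
         trainDonors = unlist(f$trainDonors, use.names = FALSE))
  })
  cvp <- do.call(rbind, lapply(doc$cvPredictions, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  methods::new("ClockModel", unit = doc$unit, mode = doc$mode,
               alpha = as.numeric(doc$alpha), folds = folds,
               geneUniverse = universe,
               trainingGeneMeans = stats::setNames(
                 as.numeric(unlist(doc$trainingGeneMeans)), universe),
               donorFolds = stats::setNames(
                 as.integer(unlist(doc$donorFolds)),
                 names(doc$donorFolds)),
               cvPredictions = cvp, seed = as.integer(doc$seed))
}
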