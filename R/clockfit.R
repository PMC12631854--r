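#' Assign donors to cross-validation folds
#'
#' Seeded partition of donors into folds of as-equal-as-possible size
#' (sizes differ by at most one). All samples of a donor inherit its fold,
#' which is what prevents donor-level information leakage between training
#' and test data.
#'
#' @param donorIds Character vector of unique donor identifiers.
#' @param nFolds Number of folds (default 5).
#' @param seed Integer seed.
#' @return Named integer vector mapping each donor to a fold in
#'   \code{1:nFolds}.
#' @export
assignDonorFolds <- function(donorIds, nFolds = 5L, seed = 1L) {
  donorIds <- as.character(donorIds)
  stopifnot(!anyDuplicated(donorIds))
  if (length(donorIds) < nFolds)
    stop("need at least ", nFolds, " donors for ", nFolds,
         "-fold cross-validation (got ", length(donorIds), ")",
         call. = FALSE)
  set.seed(seedStream(seed, 11L))
  perm <- sample(donorIds)
  folds <- stats::setNames(rep_len(seq_len(nFolds), length(perm)), perm)
  folds[donorIds]
}

#' Fit one elastic-net regression of age on expression
#'
#' Minimizes squared error plus the elastic-net penalty
#' \code{lambda * ((1 - alpha)/2 * ||b||_2^2 + alpha * ||b||_1)} (glmnet's
#' 1/(2n) loss scaling). When \code{lambda} is \code{NULL} the penalty is
#' selected by inner cross-validation over a log-spaced path (minimum-MSE
#' lambda); pass \code{foldid} to group the inner folds by donor. A fixed
#' \code{lambda} bypasses the inner CV (used for oracle checks and
#' shrinkage limits). Features are standardized internally and
#' coefficients are reported on the original scale (set
#' \code{standardize = FALSE} to fit on raw features). A constant response
#' yields the intercept-only model rather than an error.
#'
#' Lambda scaling: glmnet standardizes the response internally, so at a
#' fixed \code{lambda} with \code{alpha = 0} and \code{standardize =
#' FALSE} the returned coefficients solve the normal equations
#' \code{(Xc'Xc + n * lambda / sd_n(y) * I) b = Xc' y}, where \code{Xc} is
#' the column-centered design and \code{sd_n} the standard deviation with
#' denominator n; the intercept is \code{mean(y) - colMeans(X) \%*\% b}.
#'
#' @param X Numeric matrix, samples x genes.
#' @param y Numeric response (ages in years).
#' @param alpha Elastic-net mixing parameter in [0, 1].
#' @param lambda Optional fixed penalty value.
#' @param foldid Optional integer vector of inner-CV fold ids per sample.
#' @param nlambda Length of the inner-CV lambda path.
#' @param standardize Standardize features before fitting.
#' @param seed Seed for the inner CV when \code{foldid} is not given.
#' @return List with \code{coefficients} (named, over the columns of X),
#'   \code{intercept} and \code{lambda}.
#' @export
fitElasticNet <- function(X, y, alpha = 0.5, lambda = NULL, foldid = NULL,
                          nlambda = 50, standardize = TRUE, seed = 1L) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in the design matrix or response", call. = FALSE)
  stopifnot(nrow(X) == length(y), alpha >= 0, alpha <= 1)
  zero <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (stats::var(y) == 0)
    return(list(coefficients = zero, intercept = y[1], lambda = Inf))
  if (!is.null(lambda)) {
    path <- lambda * c(16, 8, 4, 2, 1)
    fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = path,
                          standardize = standardize, thresh = 1e-12,
                          maxit = 1e6)
    b <- as.numeric(glmnet::coef.glmnet(fit, s = lambda))
  } else {
    if (is.null(foldid)) {
      set.seed(seedStream(seed, 17L))
      foldid <- sample(rep_len(seq_len(min(5L, nrow(X))), nrow(X)))
    }
    cv <- withCallingHandlers(
      glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                        nlambda = nlambda, standardize = standardize),
      warning = function(w) {
        # small training folds trip cv.glmnet's grouped-CV notice; the
        # per-observation fallback it switches to is what we want anyway
        if (grepl("grouped=FALSE", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    lambda <- cv$lambda.min
    b <- as.numeric(glmnet::coef.glmnet(cv$glmnet.fit, s = lambda))
  }
  list(coefficients = stats::setNames(b[-1], colnames(X)),
       intercept = b[1], lambda = lambda)
}

modeName <- function(mode)
  switch(mode, simple = "simple_pseudobulk",
         bootstrap = "bootstrapped_pseudobulk", single_cell = "single_cell",
         mode)

#' Train an aging clock with donor-level 5-fold cross-validation
#'
#' In each of five rounds, an elastic-net regression of age on gene
#' expression is fitted on the samples of 80\% of the donors and predicts
#' the ages of the held-out donors' samples. The five fold models are kept
#' verbatim (external application ensembles them); the pooled out-of-fold
#' predictions (\code{cv_test}) estimate generalization to unseen donors.
#' The penalty of each fold is selected by inner cross-validation grouped
#' by donor, unless a fixed \code{lambda} is supplied.
#'
#' @param samples A \linkS4class{PseudobulkSet} (from
#'   \code{\link{simplePseudobulk}}, \code{\link{bootstrapPseudobulk}} or
#'   \code{\link{cellSamples}}) carrying \code{age} per sample.
#' @param alpha Elastic-net mixing parameter (default 0.5; 0 and 1 complete
#'   the usual sensitivity grid).
#' @param seed Seed governing fold assignment and penalty selection.
#' @param lambda Optional fixed penalty forwarded to
#'   \code{\link{fitElasticNet}}.
#' @param nlambda,standardize Forwarded to \code{\link{fitElasticNet}}.
#' @return A \linkS4class{ClockModel}; its \code{\link{cvPredictions}}
#'   hold the pooled test-round predictions.
#' @export
trainClock <- function(samples, alpha = 0.5, seed = 1L, lambda = NULL,
                       nlambda = 50, standardize = TRUE) {
  stopifnot(methods::is(samples, "PseudobulkSet"))
  cd <- colData(samples)
  X <- t(assay(samples, "exprs"))
  y <- as.numeric(cd$age)
  donor <- as.character(cd$donor_id)
  donors <- unique(donor)
  folds <- assignDonorFolds(donors, 5L, seed)
  foldOf <- folds[donor]
  foldModels <- vector("list", 5L)
  pred <- numeric(length(y))
  for (f in 1:5) {
    test <- which(foldOf == f)
    train <- which(foldOf != f)
    trainDonors <- unique(donor[train])
    if (length(trainDonors) < 2)
      stop("fold ", f, " has fewer than 2 training donors", call. = FALSE)
    innerId <- NULL
    if (is.null(lambda)) {
      inner <- assignDonorFolds(trainDonors, min(5L, length(trainDonors)),
                                seedStream(seed, 13L, f))
      innerId <- as.integer(inner[donor[train]])
    }
    fit <- fitElasticNet(X[train, , drop = FALSE], y[train], alpha = alpha,
                         lambda = lambda, foldid = innerId,
                         nlambda = nlambda, standardize = standardize)
    fit$trainDonors <- trainDonors
    foldModels[[f]] <- fit
    pred[test] <- fit$intercept +
      as.numeric(X[test, , drop = FALSE] %*% fit$coefficients)
  }
  cvp <- data.frame(sample_id = colnames(samples), donor_id = donor,
                    unit = as.character(cd$unit), fold = as.integer(foldOf),
                    chronological_age = y, predicted_age = pred,
                    source = "cv_test", stringsAsFactors = FALSE)
  methods::new("ClockModel",
    unit = as.character(cd$unit[1] %||% "unknown"),
    mode = modeName(metadata(samples)$mode %||% "unknown"),
    alpha = alpha, folds = foldModels,
    geneUniverse = colnames(X),
    trainingGeneMeans = stats::setNames(colMeans(X), colnames(X)),
    donorFolds = folds, cvPredictions = cvp, seed = as.integer(seed))
}

# Ensemble prediction: mean of the five fold models applied to samples x
# genes (already in the model's gene universe and order).
ensemblePredict <- function(model, X) {
  per <- vapply(model@folds, function(f)
    f$intercept + as.numeric(X %*% f$coefficients), numeric(nrow(X)))
  per <- matrix(per, nrow = nrow(X))
  list(mean = rowMeans(per), perFold = per)
}

#' Predict donor ages from samples already in the clock's gene universe
#'
#' Applies the five fold models and averages them per sample; with
#' \code{aggregate = TRUE}, replicate predictions of a donor are averaged
#' into a single donor-level predicted age (the rule used for
#' bootstrapped-pseudobulk clocks: a donor's prediction is the mean over
#' its replicate samples). Samples whose genes do not match the model's
#' universe must first go through \code{\link{alignGenes}}.
#'
#' @param model A \linkS4class{ClockModel}.
#' @param samples A \linkS4class{PseudobulkSet} over the same gene
#'   universe.
#' @param aggregate Average replicate predictions per donor.
#' @return data.frame of predictions (\code{source =
#'   "external_ensemble"}).
#' @export
predictDonorAge <- function(model, samples, aggregate = TRUE) {
  stopifnot(methods::is(model, "ClockModel"),
            methods::is(samples, "PseudobulkSet"))
  if (!identical(rownames(samples), model@geneUniverse)) {
    if (setequal(rownames(samples), model@geneUniverse))
      samples <- samples[model@geneUniverse, ]
    else
      stop("sample genes do not match the model's gene universe; ",
           "run alignGenes() first", call. = FALSE)
  }
  cd <- colData(samples)
  X <- t(assay(samples, "exprs"))
  pred <- ensemblePredict(model, X)$mean
  out <- data.frame(sample_id = colnames(samples),
                    donor_id = as.character(cd$donor_id),
                    unit = as.character(cd$unit),
                    chronological_age = as.numeric(cd$age),
                    predicted_age = pred, source = "external_ensemble",
                    stringsAsFactors = FALSE)
  if (aggregate) aggregateByDonor(out) else out
}

#' Aggregate replicate predictions to one row per donor
#'
#' A donor's predicted age is the mean of the predictions of its replicate
#' samples (the donor-level rule for bootstrapped-pseudobulk clocks).
#' Works on any prediction table, e.g. \code{\link{cvPredictions}} output.
#'
#' @param predictions data.frame with \code{donor_id},
#'   \code{chronological_age}, \code{predicted_age}.
#' @return data.frame with exactly one row per donor.
#' @export
aggregateByDonor <- function(predictions) {
  sp <- split(predictions, predictions$donor_id)
  out <- do.call(rbind, lapply(sp, function(p)
    data.frame(sample_id = p$donor_id[1], donor_id = p$donor_id[1],
               unit = p$unit[1],
               chronological_age = p$chronological_age[1],
               predicted_age = mean(p$predicted_age), source = p$source[1],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Evaluate predictions: Pearson correlation and mean absolute error
#'
#' @param predictions data.frame with \code{chronological_age} and
#'   \code{predicted_age} (e.g. from \code{\link{cvPredictions}} or
#'   \code{\link{predictDonorAge}}).
#' @return data.frame with \code{pearson_r}, \code{r_p_value}, \code{mae}
#'   (years) and \code{n_points}. When either variable has zero variance
#'   the correlation is undefined and reported as \code{NA}, not 0.
#' @export
evaluateClock <- function(predictions) {
  stopifnot(all(c("chronological_age", "predicted_age") %in%
                colnames(predictions)))
  x <- predictions$chronological_age
  y <- predictions$predicted_age
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  mae <- mean(abs(y - x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(data.frame(pearson_r = NA_real_, r_p_value = NA_real_,
                      mae = mae, n_points = length(x)))
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(pearson_r = unname(ct$estimate), r_p_value = ct$p.value,
             mae = mae, n_points = length(x))
}

#' Naive mean-prediction baseline under the same fold structure
#'
#' In each cross-validation round the mean age of the training samples is
#' assigned as the predicted age of every test sample. Run with the fold
#' assignment of a trained clock (\code{\link{donorFolds}}) to get the
#' baseline the clock must beat.
#'
#' @param samples The \linkS4class{PseudobulkSet} the clock was trained
#'   on.
#' @param folds Named integer donor-to-fold map (e.g.
#'   \code{donorFolds(model)}).
#' @return data.frame of baseline predictions (\code{source =
#'   "baseline"}).
#' @export
naiveMeanBaseline <- function(samples, folds) {
  stopifnot(methods::is(samples, "PseudobulkSet"))
  cd <- colData(samples)
  donor <- as.character(cd$donor_id)
  stopifnot(all(donor %in% names(folds)))
  foldOf <- folds[donor]
  y <- as.numeric(cd$age)
  pred <- numeric(length(y))
  for (f in sort(unique(foldOf))) {
    test <- foldOf == f
    pred[test] <- mean(y[!test])
  }
  data.frame(sample_id = colnames(samples), donor_id = donor,
             unit = as.character(cd$unit), fold = as.integer(foldOf),
             chronological_age = y, predicted_age = pred,
             source = "baseline", stringsAsFactors = FALSE)
}

#' Extract a clock's feature genes
#'
#' Feature genes are the genes with a non-zero coefficient in every one of
#' the five training rounds; each is reported with its coefficient
#' averaged across folds and the sign of that average (the modeled age
#' trend). The average is interpretive only — predictions always use the
#' per-fold models.
#'
#' @param model A \linkS4class{ClockModel}.
#' @return data.frame with \code{gene}, \code{average_coefficient},
#'   \code{sign}, ordered by decreasing absolute average coefficient.
#' @export
extractFeatureGenes <- function(model) {
  stopifnot(methods::is(model, "ClockModel"))
  coefMat <- vapply(model@folds, `[[`, numeric(length(model@geneUniverse)),
                    "coefficients")
  coefMat <- matrix(coefMat, nrow = length(model@geneUniverse),
                    dimnames = list(model@geneUniverse, NULL))
  keep <- rowSums(coefMat != 0) == length(model@folds)
  avg <- rowMeans(coefMat)[keep]
  out <- data.frame(gene = model@geneUniverse[keep],
                    average_coefficient = unname(avg),
                    sign = ifelse(avg > 0, 1L, ifelse(avg < 0, -1L, 0L)),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$average_coefficient)), , drop = FALSE]
}

#' Feature-gene overlap across clocks
#'
#' @param models Named list of \linkS4class{ClockModel}s.
#' @return List with \code{membership} (gene x model logical matrix),
#'   \code{nUnique} (genes in exactly one model's feature set),
#'   \code{nShared} (genes in two or more), and \code{commonToAll}.
#' @export
featureOverlap <- function(models) {
  stopifnot(length(models) >= 2)
  if (is.null(names(models)))
    names(models) <- paste0("model", seq_along(models))
  sets <- lapply(models, function(m) extractFeatureGenes(m)$gene)
  genes <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) genes %in% s,
                       logical(length(genes)))
  membership <- matrix(membership, nrow = length(genes),
                       dimnames = list(genes, names(models)))
  counts <- rowSums(membership)
  list(membership = membership,
       nUnique = sum(counts == 1),
       nShared = sum(counts >= 2),
       commonToAll = genes[counts == length(models)])
}
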