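#' Residual-based age acceleration
#'
#' Fits an ordinary least-squares line of predicted age on chronological
#' age and defines each sample's age acceleration as its residual:
#' predicted minus the line. Positive values mark samples that look
#' transcriptomically older than expected for their chronological age. By
#' default the line is fitted on all provided samples (controls and
#' disease pooled, which keeps the two groups' accelerations on one
#' scale); \code{fitOn = "control"} fits the reference line on control
#' samples only and evaluates residuals for everyone against it.
#'
#' @param predictions data.frame with \code{sample_id}, \code{donor_id},
#'   \code{chronological_age}, \code{predicted_age}, and (for
#'   \code{fitOn = "control"} or downstream group tests) a
#'   \code{condition} column or a \code{donors} table to pull it from.
#' @param donors Optional \linkS4class{CellCohort} donor table
#'   (data.frame/DataFrame with \code{donor_id}, \code{condition}, ...)
#'   merged in by donor.
#' @param fitOn \code{"all"} (default) or \code{"control"}.
#' @return An \linkS4class{AgeAcceleration} object.
#' @export
computeAgeAcceleration <- function(predictions, donors = NULL,
                                   fitOn = c("all", "control")) {
  fitOn <- match.arg(fitOn)
  stopifnot(all(c("chronological_age", "predicted_age") %in%
                colnames(predictions)))
  df <- as.data.frame(predictions)
  if (!is.null(donors)) {
    donors <- as.data.frame(donors)
    keep <- setdiff(intersect(c("condition", "sex", "PMI", "brain_ph",
                                "hemisphere"), colnames(donors)),
                    colnames(df))
    df[keep] <- donors[match(df$donor_id, donors$donor_id), keep]
  }
  if (nrow(df) < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::var(df$chronological_age) == 0)
    stop("zero variance in chronological age; the reference line is ",
         "undefined", call. = FALSE)
  fitRows <- if (fitOn == "control") {
    if (is.null(df$condition))
      stop("fitOn = 'control' needs a condition column", call. = FALSE)
    df$condition == "control"
  } else rep(TRUE, nrow(df))
  fit <- stats::lm(predicted_age ~ chronological_age, data = df[fitRows, ])
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  df$acceleration <- df$predicted_age -
    (intercept + slope * df$chronological_age)
  methods::new("AgeAcceleration", samples = df, slope = slope,
               intercept = intercept, fitOn = fitOn)
}

#' Compare age acceleration between disease and control groups
#'
#' Regresses acceleration on a disease indicator (0 = control, 1 =
#' diseased) plus covariates. With \code{perCell = FALSE} a Gaussian GLM
#' is fitted on donor-level accelerations (replicate accelerations of a
#' donor are first averaged); with \code{perCell = TRUE} a linear mixed
#' model with a random intercept per donor is fitted on the sample-level
#' accelerations. Significance is the p-value of the disease coefficient.
#' Covariates absent from the donor table, or constant, are dropped with a
#' message. A non-convergent mixed fit is reported as such with a GLM
#' fallback suggested.
#'
#' @param accel An \linkS4class{AgeAcceleration}.
#' @param donors Donor table (data.frame/DataFrame) with \code{donor_id},
#'   \code{condition} and the covariates.
#' @param perCell Use the mixed model on sample-level accelerations.
#' @param covariates Covariate names to adjust for (defaults: age, sex,
#'   PMI, brain_ph).
#' @return List with \code{model_kind}, \code{disease_coefficient}
#'   (years), \code{std_error}, \code{p_value}, \code{covariates_used},
#'   \code{converged}, \code{n}.
#' @export
compareGroups <- function(accel, donors, perCell = FALSE,
                          covariates = c("age", "sex", "PMI", "brain_ph")) {
  stopifnot(methods::is(accel, "AgeAcceleration"))
  donors <- as.data.frame(donors)
  stopifnot(all(c("donor_id", "condition") %in% colnames(donors)))
  df <- accel@samples
  df$condition <- donors$condition[match(df$donor_id, donors$donor_id)]
  if (length(unique(df$condition)) < 2)
    stop("both a control and a disease group are required", call. = FALSE)
  df$disease <- as.integer(df$condition == "disease")
  dropped <- setdiff(covariates, colnames(donors))
  if (length(dropped))
    message("compareGroups: covariate(s) not in donor table, dropped: ",
            paste(dropped, collapse = ", "))
  covariates <- intersect(covariates, colnames(donors))
  for (cv in covariates) {
    df[[cv]] <- donors[[cv]][match(df$donor_id, donors$donor_id)]
    if (length(unique(df[[cv]])) < 2 || anyNA(df[[cv]])) {
      message("compareGroups: covariate '", cv,
              "' is constant or incomplete, dropped")
      covariates <- setdiff(covariates, cv)
    }
  }
  rhs <- paste(c("disease", covariates), collapse = " + ")
  if (!perCell) {
    agg <- stats::aggregate(acceleration ~ donor_id, df, mean)
    m <- match(agg$donor_id, df$donor_id)
    for (v in c("disease", covariates)) agg[[v]] <- df[[v]][m]
    fit <- stats::glm(stats::as.formula(paste("acceleration ~", rhs)),
                      family = stats::gaussian(), data = agg)
    cf <- summary(fit)$coefficients
    list(model_kind = "glm",
         disease_coefficient = cf["disease", "Estimate"],
         std_error = cf["disease", "Std. Error"],
         p_value = cf["disease", "Pr(>|t|)"],
         covariates_used = covariates, converged = fit$converged,
         n = nrow(agg))
  } else {
    converged <- TRUE
    fit <- withCallingHandlers(
      lmerTest::lmer(
        stats::as.formula(paste("acceleration ~", rhs, "+ (1 | donor_id)")),
        data = df),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w)))
          converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    cf <- stats::coef(summary(fit))
    if (!converged)
      message("compareGroups: mixed model did not converge; consider the ",
              "GLM path (perCell = FALSE)")
    list(model_kind = "mixed",
         disease_coefficient = cf["disease", "Estimate"],
         std_error = cf["disease", "Std. Error"],
         p_value = cf["disease", "Pr(>|t|)"],
         covariates_used = covariates, converged = converged,
         n = nrow(df))
  }
}
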