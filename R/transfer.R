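## Applying trained clocks to external datasets: gene-universe alignment
## with training-mean imputation, 5-fold-model ensembling, and feature-gene
## diagnostics (expression fraction, age-trend concordance).

exprsOf <- function(x, prefer = c("logcounts", "exprs", "counts")) {
  if (is.matrix(x) || methods::is(x, "Matrix")) return(x)
  if (methods::is(x, "SummarizedExperiment")) {
    for (a in prefer) if (a %in% assayNames(x)) return(assay(x, a))
  }
  stop("cannot extract an expression matrix from a ", class(x)[1],
       call. = FALSE)
}

#' Align external samples to a clock's gene universe
#'
#' Reorders external expression to the model's gene universe. Genes the
#' external data never measured are filled with the model's training-sample
#' means (so they contribute exactly their average training signal to the
#' linear predictor); extra external genes are dropped and counted. When
#' more than half the universe is missing the alignment proceeds with a
#' prominent warning — the degraded regime in which transferred clocks lose
#' accuracy.
#'
#' @param model A \linkS4class{ClockModel}.
#' @param external A \linkS4class{PseudobulkSet} (or
#'   \linkS4class{CellCohort} samples routed through
#'   \code{\link{simplePseudobulk}} / \code{\link{cellSamples}}),
#'   log-normalized with the same transform as the training data.
#' @return List with \code{samples} (a \linkS4class{PseudobulkSet} over
#'   the model's universe) and \code{report} (n_genes_matched,
#'   n_genes_imputed, imputed_genes, n_extra_dropped).
#' @export
alignGenes <- function(model, external) {
  stopifnot(methods::is(model, "ClockModel"),
            methods::is(external, "PseudobulkSet"))
  E <- as.matrix(exprsOf(external, prefer = "exprs"))
  universe <- model@geneUniverse
  matched <- intersect(universe, rownames(E))
  imputed <- setdiff(universe, rownames(E))
  extra <- setdiff(rownames(E), universe)
  if (length(imputed) > 0.5 * length(universe))
    warning(sprintf(
      "%d/%d (%.0f%%) of the clock's gene universe is missing from the external data; predictions will be unreliable",
      length(imputed), length(universe),
      100 * length(imputed) / length(universe)), call. = FALSE)
  A <- matrix(rep(model@trainingGeneMeans, ncol(E)),
              nrow = length(universe),
              dimnames = list(universe, colnames(E)))
  A[matched, ] <- E[matched, , drop = FALSE]
  se <- SummarizedExperiment(assays = list(exprs = A),
                             colData = colData(external))
  out <- methods::new("PseudobulkSet", se)
  metadata(out) <- metadata(external)
  report <- list(n_genes_matched = length(matched),
                 n_genes_imputed = length(imputed),
                 imputed_genes = imputed,
                 n_extra_dropped = length(extra))
  metadata(out)$transferReport <- report
  list(samples = out, report = report)
}

#' Apply a clock to aligned external samples
#'
#' Each sample's prediction is the mean of the five cross-validation fold
#' models. Per-fold predictions are kept in the \code{"perFold"} attribute
#' for audit. With \code{aggregateByDonor}, replicate predictions are
#' averaged into one predicted age per donor.
#'
#' @param model A \linkS4class{ClockModel}.
#' @param aligned A \linkS4class{PseudobulkSet} over the model's gene
#'   universe (from \code{\link{alignGenes}}).
#' @param aggregateByDonor Average replicate predictions per donor.
#' @return data.frame of predictions (\code{source =
#'   "external_ensemble"}), with per-fold predictions as an attribute.
#' @export
applyClockExternal <- function(model, aligned, aggregateByDonor = FALSE) {
  stopifnot(methods::is(model, "ClockModel"),
            methods::is(aligned, "PseudobulkSet"))
  if (!identical(rownames(aligned), model@geneUniverse))
    stop("samples are not aligned to the model's gene universe; ",
         "run alignGenes() first", call. = FALSE)
  cd <- colData(aligned)
  X <- t(assay(aligned, "exprs"))
  ep <- ensemblePredict(model, X)
  out <- data.frame(sample_id = colnames(aligned),
                    donor_id = as.character(cd$donor_id),
                    unit = as.character(cd$unit),
                    chronological_age = as.numeric(cd$age %||% NA),
                    predicted_age = ep$mean, source = "external_ensemble",
                    stringsAsFactors = FALSE)
  if (aggregateByDonor) out <- aggregateByDonor(out)
  attr(out, "perFold") <- ep$perFold
  out
}

#' Fraction of a clock's feature genes expressed in a dataset
#'
#' A feature gene counts as expressed when it is present in the external
#' data and exceeds \code{threshold} in at least one cell or sample
#' (default: non-zero anywhere).
#'
#' @param model A \linkS4class{ClockModel}.
#' @param external A \linkS4class{CellCohort},
#'   \linkS4class{PseudobulkSet} or matrix (genes x cells/samples).
#' @param threshold Expression value a gene must exceed somewhere.
#' @return Fraction in [0, 1].
#' @export
featureGeneExpressionFraction <- function(model, external, threshold = 0) {
  fg <- extractFeatureGenes(model)$gene
  if (!length(fg)) return(NA_real_)
  E <- exprsOf(external, prefer = c("counts", "logcounts", "exprs"))
  present <- intersect(fg, rownames(E))
  expressed <- present[Matrix::rowSums(
    E[present, , drop = FALSE] > threshold) > 0]
  length(expressed) / length(fg)
}

#' Age-trend concordance of a clock's feature genes in a dataset
#'
#' For each feature gene, tests the Spearman correlation between its
#' expression and donor age, adjusts the p-values with Benjamini-Hochberg,
#' and calls a gene concordant when the adjusted p-value is below
#' \code{alpha} and the correlation carries the same sign as the gene's
#' average clock coefficient. Single-cell clocks are tested on per-cell
#' expression; pseudobulk clocks on per-donor cell-type (or level) means.
#' Constant or absent genes have undefined correlation and count as
#' non-concordant.
#'
#' @param model A \linkS4class{ClockModel}.
#' @param cohort A log-normalized \linkS4class{CellCohort}.
#' @param alpha Adjusted-p significance level (default 0.05).
#' @return List with \code{table} (gene, rho, p, p_adj, concordant),
#'   \code{n_feature_genes}, \code{n_significant_same_sign},
#'   \code{proportion_same_sign}.
#' @export
featureGeneTrendConcordance <- function(model, cohort, alpha = 0.05) {
  stopifnot(methods::is(model, "ClockModel"),
            methods::is(cohort, "CellCohort"))
  fg <- extractFeatureGenes(model)
  if (!nrow(fg))
    return(list(table = data.frame(), n_feature_genes = 0L,
                n_significant_same_sign = 0L,
                proportion_same_sign = NA_real_))
  samples <- if (model@mode == "single_cell")
    cellSamples(cohort, model@unit)
  else simplePseudobulk(cohort, model@unit)
  ages <- as.numeric(colData(samples)$age)
  if (length(unique(ages[!is.na(ages)])) < 4)
    stop("need at least 4 age-distinct donors for trend testing",
         call. = FALSE)
  E <- assay(samples, "exprs")
  rho <- p <- rep(NA_real_, nrow(fg))
  for (i in seq_len(nrow(fg))) {
    g <- fg$gene[i]
    if (!g %in% rownames(E)) next
    x <- as.numeric(E[g, ])
    if (stats::sd(x) == 0) next
    ct <- suppressWarnings(
      stats::cor.test(x, ages, method = "spearman"))
    rho[i] <- unname(ct$estimate)
    p[i] <- ct$p.value
  }
  padj <- stats::p.adjust(p, method = "BH")
  concordant <- !is.na(rho) & !is.na(padj) & padj < alpha &
    sign(rho) == fg$sign
  tab <- data.frame(gene = fg$gene,
                    average_coefficient = fg$average_coefficient,
                    rho = rho, p = p, p_adj = padj,
                    concordant = concordant, stringsAsFactors = FALSE)
  list(table = tab, n_feature_genes = nrow(fg),
       n_significant_same_sign = sum(concordant),
       proportion_same_sign = mean(concordant))
}
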