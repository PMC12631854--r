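## Internal helpers shared across modules.

# The six major cortical cell types and the pooling levels built on them.
MAJOR_CELL_TYPES <- c("oligodendrocyte", "astrocyte", "microglia", "OPC",
                      "excitatory_neuron", "inhibitory_neuron")
LEVELS <- list(
  glia      = c("oligodendrocyte", "astrocyte", "OPC"),
  neuron    = c("excitatory_neuron", "inhibitory_neuron"),
  all_cells = MAJOR_CELL_TYPES)

#' Derive a reproducible sub-seed from a root seed
#'
#' All randomness in the package flows from one root seed; independent
#' random streams (per donor, per bootstrap replicate, per fold) are keyed
#' by hashing the root seed together with small integer indices. The hash
#' is a multiplicative congruential mix kept below 2^31 - 1 so it is exact
#' in double precision and valid as an R seed.
#'
#' @param root Integer root seed.
#' @param ... Further integer keys (e.g. donor index, replicate index).
#' @return A single integer in [0, 2147483628], usable with
#'   \code{set.seed}.
#' @export
#' @examples
#' seedStream(1, 3, 7)
seedStream <- function(root, ...) {
  key <- c(as.numeric(root), as.numeric(unlist(list(...))))
  s <- 0
  for (k in key) s <- (s * 69069 + abs(k) + 1) %% 2147483629
  as.integer(s)
}

# Map a unit name to the cell types it pools. A plain cell type maps to
# itself; "glia"/"neuron"/"all_cells" map to their constituent types.
resolveUnit <- function(unit, available = NULL) {
  stopifnot(is.character(unit), length(unit) == 1L)
  types <- if (unit %in% names(LEVELS)) LEVELS[[unit]] else unit
  if (!is.null(available)) {
    missing <- setdiff(types, available)
    if (length(missing) == length(types))
      warning("no cells of unit '", unit, "' present (",
              paste(missing, collapse = ", "), ")")
  }
  types
}

# Log-normalized assay, with a clear error when normalization hasn't run.
logcountsAssay <- function(cohort) {
  if (!"logcounts" %in% assayNames(cohort))
    stop("cohort is not log-normalized; run logNormalize() first",
         call. = FALSE)
  assay(cohort, "logcounts")
}

countsAssay <- function(cohort) {
  if (!"counts" %in% assayNames(cohort))
    stop("cohort has no 'counts' assay", call. = FALSE)
  assay(cohort, "counts")
}

# Donor ages as a named vector.
donorAges <- function(cohort) {
  dd <- donorData(cohort)
  stats::setNames(as.numeric(dd$age), as.character(dd$donor_id))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
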