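# internal helpers shared across modules

#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame
NULL

# Accept either a plain genes x samples matrix or a SummarizedExperiment
# (first assay). Always returns a base matrix with dimnames.
.asExprMatrix <- function(x, requireSamples = TRUE) {
  if (is(x, "SummarizedExperiment")) x <- SummarizedExperiment::assay(x, 1L)
  x <- as.matrix(x)
  if (is.null(rownames(x)))
    stop("expression matrix must carry gene (row) names")
  if (requireSamples && is.null(colnames(x)))
    stop("expression matrix must carry sample (column) names")
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains missing or non-finite values")
  if (anyDuplicated(rownames(x)))
    stop("gene identifiers must be unique")
  x
}

.assertScalar <- function(x, name, positive = FALSE) {
  if (length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}

# logistic and its inverse on the natural scale
.logistic <- function(x) plogis(x)

# adjusted Rand index between two label vectors (used by tests and examples)
#' Adjusted Rand index
#'
#' Agreement between two partitions of the same samples, corrected for
#' chance; 1 for identical partitions (up to relabelling), ~0 for independent
#' ones. Used to measure recovery of planted subgroups by clustering.
#'
#' @param a,b label vectors of equal length (any types coercible to factor).
#' @return numeric(1), the adjusted Rand index.
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- ai * bj / nn
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}
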