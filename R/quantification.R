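#' Relative expression by the delta-delta-Ct method
#'
#' For every sample and non-reference gene: the triplicate Ct values are
#' averaged; the reference level is the arithmetic mean, over the reference
#' genes, of their per-gene mean Cts (equivalent to the geometric mean of
#' the linear reference quantities); `delta_ct = mean target Ct - reference
#' level`; `delta_delta_ct = delta_ct - calibrator(gene)`; and
#' `rel_expr = 2^(-delta_delta_ct)`. Because target and reference shift
#' together, the result is invariant to adding a constant to all Ct values
#' of a sample (a plate shift).
#'
#' The calibrator defaults to 0 for every gene (pure delta-Ct): any fixed
#' calibrator is a per-gene constant that downstream classifiers absorb into
#' their coefficients and intercept.
#'
#' @param ct long-format data.frame `sample_id`, `gene`, `replicate`, `ct`.
#' @param referenceGenes character; must be measured for every sample.
#' @param calibratorDeltaCt optional named numeric of per-gene calibrator
#'   delta-Ct constants; genes absent from it use 0.
#' @param sdQcMax replicate-SD QC bound in cycles (default 0.5); triplicates
#'   above it are flagged.
#' @param excludeFlagged if TRUE, flagged target triplicates are dropped
#'   from the output. Reference-gene triplicates are never dropped (the
#'   reference level must stay defined); their flags surface only through
#'   the QC bound on targets.
#' @return data.frame `sample_id`, `gene`, `delta_ct`, `delta_delta_ct`,
#'   `rel_expr`, `flagged` with one row per sample x target gene.
#' @examples
#' ct <- simulateQpcr(matrix(c(7, 8), 2, 1, dimnames = list(c("A", "REF1"), "S1")),
#'                    panel = "A", referenceGenes = "REF1", plateNoiseSd = 0)
#' deltaDeltaCt(ct, "REF1")
#' @export
deltaDeltaCt <- function(ct, referenceGenes, calibratorDeltaCt = NULL,
                         sdQcMax = 0.5, excludeFlagged = FALSE) {
  stopifnot(all(c("sample_id", "gene", "replicate", "ct") %in% names(ct)))
  if (length(referenceGenes) == 0) stop("at least one reference gene needed")
  if (any(ct$ct <= 0 | ct$ct > 45))
    stop("Ct values must lie in (0, 45]")
  agg <- stats::aggregate(ct$ct, by = list(sample_id = ct$sample_id,
                                           gene = ct$gene),
                          FUN = function(v) c(mean = mean(v), sd = sd(v),
                                              n = length(v)))
  agg <- data.frame(sample_id = agg$sample_id, gene = agg$gene,
                    mean_ct = agg$x[, "mean"], sd_ct = agg$x[, "sd"],
                    stringsAsFactors = FALSE)
  agg$sd_ct[is.na(agg$sd_ct)] <- 0
  agg$flagged <- agg$sd_ct > sdQcMax

  samples <- unique(ct$sample_id)
  isRef <- agg$gene %in% referenceGenes
  for (s in samples) {
    present <- agg$gene[isRef & agg$sample_id == s]
    miss <- setdiff(referenceGenes, present)
    if (length(miss))
      stop(sprintf("sample '%s' is missing reference gene(s): %s", s,
                   paste(miss, collapse = ", ")))
  }
  refLevel <- tapply(agg$mean_ct[isRef], agg$sample_id[isRef], mean)

  out <- agg[!isRef, , drop = FALSE]
  if (excludeFlagged) out <- out[!out$flagged, , drop = FALSE]
  cal <- numeric(nrow(out))
  if (!is.null(calibratorDeltaCt)) {
    hit <- out$gene %in% names(calibratorDeltaCt)
    cal[hit] <- calibratorDeltaCt[out$gene[hit]]
  }
  deltaCt <- out$mean_ct - as.numeric(refLevel[as.character(out$sample_id)])
  ddct <- deltaCt - cal
  res <- data.frame(sample_id = out$sample_id, gene = out$gene,
                    delta_ct = deltaCt, delta_delta_ct = ddct,
                    rel_expr = 2^(-ddct), flagged = out$flagged,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Convert a relative-expression table to a samples x genes delta-Ct matrix
#'
#' Classifier-facing reshape of the [deltaDeltaCt()] output: one row per
#' sample, one column per gene, entries `delta_ct`.
#'
#' @param relExpr output of [deltaDeltaCt()].
#' @return numeric matrix, samples x genes.
#' @export
deltaCtMatrix <- function(relExpr) {
  samples <- unique(relExpr$sample_id)
  genes <- unique(relExpr$gene)
  m <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  m[cbind(match(relExpr$sample_id, samples), match(relExpr$gene, genes))] <-
    relExpr$delta_ct
  if (anyNA(m)) stop("delta-Ct table is not complete over samples x genes")
  m
}

#' Feature standardisation
#'
#' Centres and scales each gene row to mean 0 and sample standard deviation
#' 1 (n-1 denominator). The per-gene centre and scale are stored as
#' attributes `center` and `scale` so the transform is invertible (see
#' [unstandardizeFeatures()]) and so held-out samples can be transformed with
#' training-set parameters.
#'
#' @param x genes x samples matrix or SummarizedExperiment.
#' @return standardised matrix with attributes `center` and `scale`.
#' @export
standardizeFeatures <- function(x) {
  m <- .asExprMatrix(x, requireSamples = FALSE)
  ctr <- rowMeans(m)
  scl <- apply(m, 1L, sd)
  bad <- scl == 0
  if (any(bad))
    stop("zero-variance gene(s): ", paste(rownames(m)[bad], collapse = ", "))
  z <- (m - ctr) / scl
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  z
}

#' @rdname standardizeFeatures
#' @param z a matrix produced by `standardizeFeatures`.
#' @export
unstandardizeFeatures <- function(z) {
  ctr <- attr(z, "center")
  scl <- attr(z, "scale")
  if (is.null(ctr) || is.null(scl))
    stop("matrix carries no center/scale attributes")
  out <- z * scl + ctr
  attr(out, "center") <- NULL
  attr(out, "scale") <- NULL
  out
}

#' Microarray vs qPCR correlation filter
#'
#' For each candidate gene, the Pearson correlation between its microarray
#' log2 values and its qPCR `-delta_ct` (= log2 relative expression up to a
#' per-gene constant) is computed over the shared samples; genes with
#' Pearson r at or above `rMin` are retained, in input order. Genes with zero variance on
#' either platform are excluded with reason `"undefined correlation"`.
#'
#' @param microarray genes x samples log2 matrix or SummarizedExperiment.
#' @param qpcr output of [deltaDeltaCt()].
#' @param candidates character; genes to test (order preserved).
#' @param rMin retention threshold on Pearson r (default 0.5).
#' @return list with `retained` (character) and `report` (data.frame
#'   `gene`, `r`, `retained`, `reason`).
#' @export
correlationFilter <- function(microarray, qpcr, candidates, rMin = 0.5) {
  m <- .asExprMatrix(microarray)
  missing <- setdiff(candidates, rownames(m))
  if (length(missing))
    stop("candidate genes absent from microarray: ",
         paste(missing, collapse = ", "))
  rep <- data.frame(gene = candidates, r = NA_real_, retained = FALSE,
                    reason = "", stringsAsFactors = FALSE)
  for (i in seq_along(candidates)) {
    g <- candidates[i]
    sub <- qpcr[qpcr$gene == g, , drop = FALSE]
    if (nrow(sub) == 0) {
      rep$reason[i] <- "not measured by qPCR"
      next
    }
    shared <- intersect(colnames(m), sub$sample_id)
    x <- m[g, shared]
    y <- -sub$delta_ct[match(shared, sub$sample_id)]
    if (sd(x) == 0 || sd(y) == 0) {
      rep$reason[i] <- "undefined correlation"
      next
    }
    r <- cor(x, y)
    rep$r[i] <- r
    if (r >= rMin) {
      rep$retained[i] <- TRUE
    } else {
      rep$reason[i] <- sprintf("r below threshold %g", rMin)
    }
  }
  list(retained = rep$gene[rep$retained], report = rep)
}
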