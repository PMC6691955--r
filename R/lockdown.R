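#' Select the qPCR candidate gene panel
#'
#' Assembles the panel taken forward to qPCR optimisation from three
#' sources, in order: (1) every nonzero gene of the optimal model; (2) genes
#' highly correlated (|r| >= `rCorrMin`) with an optimal-model gene on the
#' microarray, best-first; (3) the most frequently nonzero genes among the
#' lower-ranked candidate models, best-first, until the total quota is met.
#' A shortfall in one category rolls into the next with a warning. The
#' selection is fully deterministic (correlation ties break by gene order in
#' the matrix, frequency ties likewise).
#'
#' @param models list of [CandidateModel-class] from the grid.
#' @param optimal the selected optimal [CandidateModel-class].
#' @param microarray genes x samples log2 matrix or SummarizedExperiment.
#' @param quotas integer(3): targets for the optimal / correlated /
#'   lower-ranked categories (default `c(12, 6, 21)`, a 39-gene panel).
#' @param rCorrMin |r| threshold for "highly correlated" (default 0.8).
#' @param referenceGenes character; reference genes carried alongside.
#' @param convention BIC convention used to rank models, see [bicScore()].
#' @return list of class `"CandidatePanel"` with elements `fromOptimal`,
#'   `correlatedAdditions`, `fromSuboptimalModels`, `referenceGenes` and
#'   `informative` (the ordered union of the first three, which are
#'   disjoint).
#' @export
selectCandidatePanel <- function(models, optimal, microarray,
                                 quotas = c(12L, 6L, 21L), rCorrMin = 0.8,
                                 referenceGenes = character(),
                                 convention = c("standard", "paper-literal")) {
  convention <- match.arg(convention)
  m <- .asExprMatrix(microarray)
  if (length(quotas) != 3L || any(quotas < 0))
    stop("quotas must be three non-negative counts")
  total <- sum(quotas)

  fromOptimal <- names(modelCoef(optimal))[modelCoef(optimal) != 0]
  if (length(fromOptimal) > total)
    stop("optimal model has more nonzero genes than the whole panel quota")

  # category 2: highest |r| with any optimal-model gene
  pool <- setdiff(rownames(m), c(fromOptimal, referenceGenes))
  corAdd <- character(0)
  if (length(fromOptimal) > 0 && length(pool) > 0) {
    cc <- suppressWarnings(
      cor(t(m[pool, , drop = FALSE]), t(m[fromOptimal, , drop = FALSE])))
    maxAbs <- apply(abs(cc), 1L, max)
    maxAbs[is.na(maxAbs)] <- -Inf
    eligible <- pool[maxAbs >= rCorrMin]
    eligible <- eligible[order(-maxAbs[match(eligible, pool)],
                               match(eligible, rownames(m)))]
    want2 <- quotas[2] + max(0L, quotas[1] - length(fromOptimal))
    corAdd <- head(eligible, want2)
  }

  # category 3: nonzero frequency among models ranked below the optimal
  score <- vapply(models, function(x)
    bicScore(x@logLik, x@k, x@n, convention), numeric(1))
  if (convention == "paper-literal") score <- -score
  optScore <- local({
    s <- bicScore(optimal@logLik, optimal@k, optimal@n, convention)
    if (convention == "paper-literal") -s else s
  })
  lower <- models[score > optScore]
  freq <- integer(nrow(m))
  names(freq) <- rownames(m)
  for (x in lower) {
    nz <- names(modelCoef(x))[modelCoef(x) != 0]
    nz <- intersect(nz, names(freq))
    freq[nz] <- freq[nz] + 1L
  }
  pool3 <- setdiff(names(freq)[freq > 0], c(fromOptimal, corAdd, referenceGenes))
  pool3 <- pool3[order(-freq[pool3], match(pool3, rownames(m)))]
  remaining <- total - length(fromOptimal) - length(corAdd)
  fromSub <- head(pool3, max(0L, remaining))
  if (length(fromSub) < remaining)
    warning(sprintf("panel shortfall: %d of %d genes selected",
                    length(fromOptimal) + length(corAdd) + length(fromSub),
                    total))

  structure(list(fromOptimal = fromOptimal, correlatedAdditions = corAdd,
                 fromSuboptimalModels = fromSub,
                 referenceGenes = referenceGenes,
                 informative = c(fromOptimal, corAdd, fromSub)),
            class = "CandidatePanel")
}

#' @export
print.CandidatePanel <- function(x, ...) {
  cat(sprintf("CandidatePanel: %d informative (+%d reference) genes\n",
              length(x$informative), length(x$referenceGenes)))
  cat(sprintf("  optimal-model members : %d\n", length(x$fromOptimal)))
  cat(sprintf("  correlated additions  : %d\n", length(x$correlatedAdditions)))
  cat(sprintf("  from lower-ranked fits: %d\n", length(x$fromSuboptimalModels)))
  invisible(x)
}

#' Refit the adaptive Elastic-Net pipeline on standardised qPCR features
#'
#' The identical penalised regression strategy used on the microarray is
#' applied to the qPCR-scale data: classic Elastic-Net stage, adaptive
#' re-weighting, grid fit, BIC selection.
#'
#' @param qpcrFeatures samples x genes matrix of standardised delta-Ct
#'   features (see [standardizeFeatures()], [deltaCtMatrix()]).
#' @param labels binary subgroup labels.
#' @param grid hyperparameter triples; defaults to [makeModelGrid()] on the
#'   given data.
#' @param convention BIC convention.
#' @param ... solver controls passed to [fitAdaptiveGrid()].
#' @return the selected [CandidateModel-class] (k, logLik and BIC included
#'   for audit).
#' @export
refitOnQpcr <- function(qpcrFeatures, labels, grid = NULL,
                        convention = c("standard", "paper-literal"), ...) {
  convention <- match.arg(convention)
  y <- .asBinary(labels)
  if (is.null(grid)) grid <- makeModelGrid(qpcrFeatures, y)
  models <- fitAdaptiveGrid(qpcrFeatures, y, grid, ...)
  selectBestModel(models, convention)
}

# canonical md5 of all numeric and naming content (excluding the checksum
# slot itself); no external digest dependency.
.checksumFromParts <- function(informativeGenes, referenceGenes, beta,
                               intercept, threshold, labelHi, labelLo,
                               version) {
  s <- paste(c(informativeGenes, referenceGenes, sprintf("%.17g", beta),
               sprintf("%.17g", intercept), sprintf("%.17g", threshold),
               labelHi, labelLo, version),
             collapse = "|")
  f <- tempfile("clfsum")
  on.exit(unlink(f))
  writeChar(s, f, eos = NULL)
  unname(tools::md5sum(f))
}

.classifierChecksum <- function(object) {
  .checksumFromParts(object@informativeGenes, object@referenceGenes,
                     object@beta, object@intercept, object@threshold,
                     object@labelHi, object@labelLo, object@version)
}

.newLockedClassifier <- function(informativeGenes, referenceGenes, beta,
                                 intercept, labelHi = "IBDhi",
                                 labelLo = "IBDlo", version = "1.0") {
  beta <- setNames(as.numeric(beta), informativeGenes)
  sum <- .checksumFromParts(informativeGenes, referenceGenes, beta,
                            as.numeric(intercept), 0.5, labelHi, labelLo,
                            version)
  new("LockedClassifier", informativeGenes = informativeGenes,
      referenceGenes = referenceGenes, beta = beta,
      intercept = as.numeric(intercept), threshold = 0.5,
      labelHi = labelHi, labelLo = labelLo,
      checksum = sum, version = version)
}

#' Cross-validated re-regularisation on unscaled delta-Ct features and
#' classifier lock-down
#'
#' Final translation step: penalised logistic regression over a lambda path
#' on the \emph{unscaled} delta-Ct features (a prerequisite for scoring one
#' clinical sample at a time), with k-fold cross-validated misclassification
#' error. The most-regularised model whose mean CV error is within one
#' standard error of the minimum (the 1-SE rule) is refitted on all data and
#' locked: genes, coefficients, intercept and the 0.5 threshold are frozen
#' under an md5 checksum, and any later modification is detectable. The
#' cross-validation engine is `glmnet::cv.glmnet` with deterministic
#' stratified folds derived from `seed`.
#'
#' @param features samples x genes matrix of unscaled delta-Ct values.
#' @param labels binary labels (1 / second factor level = the poor-prognosis
#'   subgroup mapped to `labelHi`).
#' @param referenceGenes character; reference genes recorded in the locked
#'   panel.
#' @param nFolds folds (default 10, stratified).
#' @param alpha Elastic-Net mixing parameter for the path (default 1,
#'   lasso).
#' @param seed integer; fixes the fold assignment.
#' @param labelHi,labelLo call names (defaults "IBDhi"/"IBDlo").
#' @return a [LockedClassifier-class]; attribute `"cv"` carries the CV curve
#'   (lambda, mean error, SE, nonzero counts, lambda.min, lambda.1se) for
#'   audit.
#' @export
regularizeUnscaled <- function(features, labels, referenceGenes = character(),
                               nFolds = 10L, alpha = 1, seed = 1L,
                               labelHi = "IBDhi", labelLo = "IBDlo") {
  X <- as.matrix(features)
  y <- .asBinary(labels)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  n <- length(y)
  if (nFolds < 3L || nFolds > n) stop("degenerate cross-validation folds")
  set.seed(seed)
  foldid <- integer(n)
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
  }
  if (any(tabulate(foldid, nFolds) == 0L))
    stop("degenerate cross-validation folds (an empty fold)")
  cv <- glmnet::cv.glmnet(X, y, family = "binomial",
                          type.measure = "class", foldid = foldid,
                          alpha = alpha)
  cf <- as.matrix(coef(cv, s = "lambda.1se"))
  beta <- cf[-1L, 1L]
  nz <- names(beta)[beta != 0]
  clf <- .newLockedClassifier(informativeGenes = nz,
                              referenceGenes = referenceGenes,
                              beta = beta[nz], intercept = cf[1L, 1L],
                              labelHi = labelHi, labelLo = labelLo)
  attr(clf, "cv") <- list(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
                          nzero = as.integer(cv$nzero),
                          lambda.min = cv$lambda.min,
                          lambda.1se = cv$lambda.1se)
  clf
}

#' Score samples with a locked classifier
#'
#' Computes delta-Ct features from a triplicate Ct table via
#' [deltaDeltaCt()] with the classifier's reference genes, applies the
#' locked linear model, and calls `labelHi` iff the logistic probability is
#' at or above the 0.5 threshold (the boundary is assigned to the high-risk
#' side). A sample missing any required gene yields a no-call naming the
#' gene -- never a silent default. Calls are invariant to a constant Ct
#' shift applied to all genes of a sample. The classifier's checksum is
#' verified before any scoring.
#'
#' @param clf a [LockedClassifier-class].
#' @param ct long-format Ct table for one or more samples.
#' @param sdQcMax replicate QC bound passed to [deltaDeltaCt()].
#' @return data.frame `sample_id`, `probability`, `label`, `no_call_reason`.
#' @export
classifySample <- function(clf, ct, sdQcMax = 0.5) {
  stopifnot(is(clf, "LockedClassifier"))
  validObject(clf)  # checksum verification
  samples <- unique(ct$sample_id)
  out <- data.frame(sample_id = samples, probability = NA_real_,
                    label = NA_character_, no_call_reason = NA_character_,
                    stringsAsFactors = FALSE)
  need <- c(clf@informativeGenes, clf@referenceGenes)
  for (i in seq_along(samples)) {
    s <- samples[i]
    sub <- ct[ct$sample_id == s, , drop = FALSE]
    miss <- setdiff(need, unique(sub$gene))
    if (length(miss)) {
      out$no_call_reason[i] <- paste("missing gene(s):",
                                     paste(miss, collapse = ", "))
      next
    }
    res <- tryCatch(
      deltaDeltaCt(sub, clf@referenceGenes, sdQcMax = sdQcMax),
      error = function(e) e)
    if (inherits(res, "error")) {
      out$no_call_reason[i] <- conditionMessage(res)
      next
    }
    dct <- setNames(res$delta_ct, res$gene)[clf@informativeGenes]
    if (anyNA(dct)) {
      out$no_call_reason[i] <- paste("missing delta-Ct for:",
        paste(clf@informativeGenes[is.na(dct)], collapse = ", "))
      next
    }
    p <- .logistic(clf@intercept + sum(clf@beta * dct))
    out$probability[i] <- p
    out$label[i] <- if (p >= clf@threshold) clf@labelHi else clf@labelLo
  }
  out
}

#' Serialise / load a locked classifier
#'
#' The locked classifier is stored as a human-readable JSON document with
#' genes, coefficients, intercept, threshold, labels, version and checksum.
#' On load the checksum is recomputed and verified; a tampered document is
#' rejected.
#'
#' @param clf a [LockedClassifier-class].
#' @param path JSON file path.
#' @return `writeLockedClassifier` returns `path` invisibly;
#'   `readLockedClassifier` returns the verified classifier.
#' @export
writeLockedClassifier <- function(clf, path) {
  stopifnot(is(clf, "LockedClassifier"))
  doc <- list(informative_genes = clf@informativeGenes,
              reference_genes = clf@referenceGenes,
              beta = as.list(setNames(as.numeric(clf@beta), names(clf@beta))),
              intercept = clf@intercept, threshold = clf@threshold,
              label_hi = clf@labelHi, label_lo = clf@labelLo,
              version = clf@version, checksum = clf@checksum)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeLockedClassifier
#' @export
readLockedClassifier <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj <- new("LockedClassifier",
             informativeGenes = as.character(doc$informative_genes),
             referenceGenes = as.character(doc$reference_genes),
             beta = setNames(as.numeric(unlist(doc$beta)),
                             as.character(doc$informative_genes)),
             intercept = doc$intercept, threshold = doc$threshold,
             labelHi = doc$label_hi, labelLo = doc$label_lo,
             checksum = doc$checksum, version = doc$version)
  if (!identical(obj@checksum, .classifierChecksum(obj)))
    stop("checksum mismatch: classifier document has been altered since lock-down")
  validObject(obj)
  obj
}
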