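#' @import methods
#' @importFrom stats sd cor rexp rpois rbinom rnorm runif quantile coef
#'   predict binom.test fisher.test wilcox.test dbinom plogis qlogis
#'   pchisq kmeans hclust cutree as.dist dist var setNames pnorm aggregate
#' @importFrom utils head write.csv read.csv
#' @importFrom Rcpp sourceCpp
#' @useDynLib ibdProg, .registration = TRUE
NULL

setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' Synthetic IBD cohort
#'
#' Container for one simulated cohort: CD8 T cell and whole-blood expression
#' (as [SummarizedExperiment::SummarizedExperiment] objects, genes x samples,
#' log2 scale), a long-format triplicate qPCR Ct table, a clinical follow-up
#' table and the planted subgroup labels. All components share the same
#' ordered sample identifiers.
#'
#' @slot cd8 SummarizedExperiment of CD8 T cell log2 expression.
#' @slot wholeBlood SummarizedExperiment of whole-blood log2 expression, with
#'   the planted subgroup effect attenuated relative to CD8.
#' @slot ctTable data.frame with columns `sample_id`, `gene`, `replicate`,
#'   `ct` (triplicate qPCR cycle thresholds).
#' @slot clinical data.frame of per-patient follow-up (see
#'   [simulateEscalations()]).
#' @slot trueLabels factor with two levels (`IBD1`, `IBD2`), one per sample.
#' @slot config list; the [simConfig()] used to generate the cohort.
#'
#' @seealso [simulateCohort()]
#' @export
setClass("SyntheticCohort",
  slots = c(cd8 = "ANY", wholeBlood = "ANY", ctTable = "data.frame",
            clinical = "data.frame", trueLabels = "factor", config = "list"))

setValidity("SyntheticCohort", function(object) {
  ids <- colnames(object@cd8)
  if (!identical(ids, colnames(object@wholeBlood)))
    return("cd8 and wholeBlood sample identifiers differ")
  if (!identical(ids, names(object@trueLabels)))
    return("trueLabels names do not match sample identifiers")
  if (nlevels(droplevels(object@trueLabels)) != 2L)
    return("trueLabels must have exactly two levels")
  if (!identical(sort(unique(object@clinical$sample_id)), sort(ids)))
    return("clinical table sample identifiers do not match expression")
  if (!all(object@ctTable$sample_id %in% ids))
    return("ctTable contains unknown sample identifiers")
  TRUE
})

#' Consensus clustering result
#'
#' Result of Monti-style resampling consensus clustering: the consensus
#' matrix at the chosen number of clusters, the chosen k, the final sample
#' labels (hierarchical clustering of 1 - consensus, average linkage), and
#' the PAC (proportion of ambiguous clustering) score for every k tried.
#'
#' @slot consensusMatrix symmetric n x n matrix in \[0,1\] with unit diagonal.
#' @slot chosenK integer; k minimising PAC.
#' @slot labels integer vector in 1..chosenK, one per sample, named.
#' @slot kScores data.frame with columns `k` and `pac`.
#'
#' @seealso [consensusCluster()]
#' @export
setClass("ConsensusResult",
  slots = c(consensusMatrix = "matrix", chosenK = "integer",
            labels = "integer", kScores = "data.frame"))

setValidity("ConsensusResult", function(object) {
  cm <- object@consensusMatrix
  if (nrow(cm) != ncol(cm)) return("consensus matrix must be square")
  if (max(abs(cm - t(cm))) > 1e-12) return("consensus matrix must be symmetric")
  if (any(cm < -1e-12) || any(cm > 1 + 1e-12))
    return("consensus entries must lie in [0,1]")
  if (max(abs(diag(cm) - 1)) > 1e-12) return("consensus diagonal must be 1")
  if (length(object@labels) != nrow(cm))
    return("labels length must equal the number of samples")
  if (!all(object@labels %in% seq_len(object@chosenK)))
    return("labels must lie in 1..chosenK")
  TRUE
})

#' One candidate penalised logistic model
#'
#' A single fit of logistic regression with an (optionally adaptive)
#' Elastic-Net penalty, together with the quantities needed for BIC model
#' selection: the nonzero-coefficient count k ("degrees of freedom", the
#' number of genes incorporated), the natural-log likelihood at the optimum,
#' and the BIC itself.
#'
#' @slot beta named numeric; coefficients on the (standardised) features.
#' @slot intercept numeric(1), unpenalised.
#' @slot lambda1 numeric(1); L1 penalty weight.
#' @slot lambda2 numeric(1); L2 (ridge) penalty weight.
#' @slot gamma numeric(1); adaptive exponent (NA for a classic fit).
#' @slot adaptiveWeights named numeric; per-feature positive L1 multipliers.
#' @slot k integer(1); number of nonzero coefficients.
#' @slot logLik numeric(1); natural-log likelihood (<= 0).
#' @slot bic numeric(1); standard BIC, -2*logLik + k*log(n).
#' @slot n integer(1); sample count.
#'
#' @seealso [fitElasticNetLogistic()], [fitAdaptiveGrid()], [selectBestModel()]
#' @export
setClass("CandidateModel",
  slots = c(beta = "numeric", intercept = "numeric", lambda1 = "numeric",
            lambda2 = "numeric", gamma = "numeric",
            adaptiveWeights = "numeric", k = "integer", logLik = "numeric",
            bic = "numeric", n = "integer"))

setValidity("CandidateModel", function(object) {
  if (object@k != sum(object@beta != 0))
    return("k must equal the number of nonzero coefficients")
  if (any(!is.finite(object@adaptiveWeights)) || any(object@adaptiveWeights <= 0))
    return("adaptive weights must be finite and positive")
  if (object@logLik > 1e-8) return("log-likelihood must be <= 0")
  TRUE
})

#' Locked qPCR classifier
#'
#' An immutable final classifier operating on unscaled delta-Ct features:
#' ordered informative and reference gene panels, coefficients, intercept,
#' the fixed 0.5 probability threshold, and an md5 checksum over all numeric
#' content that makes any post-lock modification detectable.
#'
#' @slot informativeGenes character; ordered informative panel.
#' @slot referenceGenes character; ordered reference panel.
#' @slot beta named numeric; coefficients on unscaled delta-Ct features
#'   (one per informative gene; zero entries allowed).
#' @slot intercept numeric(1).
#' @slot threshold numeric(1); always 0.5.
#' @slot labelHi,labelLo character(1); subgroup names for calls at or above /
#'   below the threshold (defaults "IBDhi"/"IBDlo").
#' @slot checksum character(1); md5 of the canonical serialisation.
#' @slot version character(1).
#'
#' @seealso [regularizeUnscaled()], [classifySample()],
#'   [writeLockedClassifier()]
#' @export
setClass("LockedClassifier",
  slots = c(informativeGenes = "character", referenceGenes = "character",
            beta = "numeric", intercept = "numeric", threshold = "numeric",
            labelHi = "character", labelLo = "character",
            checksum = "character", version = "character"))

setValidity("LockedClassifier", function(object) {
  if (!identical(object@threshold, 0.5)) return("threshold must be 0.5")
  if (!identical(names(object@beta), object@informativeGenes))
    return("beta must be named by informativeGenes, in order")
  if (!identical(object@checksum, .classifierChecksum(object)))
    return("checksum does not verify: classifier content has been altered")
  TRUE
})

#' Nested LOOCV report
#'
#' Generalisation-error estimate from nested leave-one-out cross-validation:
#' held-out accuracy with an exact (Clopper-Pearson) 95\% binomial confidence
#' interval and the per-sample held-out probabilities and calls.
#'
#' @slot n,nCorrect integer(1).
#' @slot accuracy,ciLow,ciHigh numeric(1).
#' @slot predictions data.frame with columns `sample`, `truth`, `probability`,
#'   `call`, `correct`.
#'
#' @seealso [nestedLoocv()]
#' @export
setClass("LoocvReport",
  slots = c(n = "integer", nCorrect = "integer", accuracy = "numeric",
            ciLow = "numeric", ciHigh = "numeric", predictions = "data.frame"))

setValidity("LoocvReport", function(object) {
  if (abs(object@accuracy - object@nCorrect / object@n) > 1e-12)
    return("accuracy must equal nCorrect/n")
  if (!(object@ciLow <= object@accuracy + 1e-12 &&
        object@accuracy <= object@ciHigh + 1e-12))
    return("confidence interval must contain the point estimate")
  TRUE
})
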