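#' @name accessors
#' @title Accessors for ibdProg S4 classes
#'
#' @description Accessor generics: slot access is never done directly.
#' `cd8Expression()` / `wholeBloodExpression()` return the expression
#' SummarizedExperiments of a cohort, `ctTable()` its qPCR table,
#' `clinicalCourse()` its follow-up table and `trueLabels()` the planted
#' subgroup labels. `consensusMatrix()`, `chosenK()`, `subgroupLabels()` and
#' `pacScores()` read a [ConsensusResult-class]; `modelCoef()`,
#' `modelIntercept()` and `modelBIC()` read a [CandidateModel-class].
#'
#' @param object an ibdProg S4 object.
#' @return The corresponding component.
NULL

#' @rdname accessors
#' @export
setGeneric("cd8Expression", function(object) standardGeneric("cd8Expression"))
#' @rdname accessors
#' @export
setGeneric("wholeBloodExpression",
           function(object) standardGeneric("wholeBloodExpression"))
#' @rdname accessors
#' @export
setGeneric("ctTable", function(object) standardGeneric("ctTable"))
#' @rdname accessors
#' @export
setGeneric("clinicalCourse", function(object) standardGeneric("clinicalCourse"))
#' @rdname accessors
#' @export
setGeneric("trueLabels", function(object) standardGeneric("trueLabels"))
#' @rdname accessors
#' @export
setGeneric("consensusMatrix", function(object) standardGeneric("consensusMatrix"))
#' @rdname accessors
#' @export
setGeneric("chosenK", function(object) standardGeneric("chosenK"))
#' @rdname accessors
#' @export
setGeneric("subgroupLabels", function(object) standardGeneric("subgroupLabels"))
#' @rdname accessors
#' @export
setGeneric("pacScores", function(object) standardGeneric("pacScores"))
#' @rdname accessors
#' @export
setGeneric("modelCoef", function(object) standardGeneric("modelCoef"))
#' @rdname accessors
#' @export
setGeneric("modelIntercept", function(object) standardGeneric("modelIntercept"))
#' @rdname accessors
#' @export
setGeneric("modelBIC", function(object) standardGeneric("modelBIC"))

#' @rdname accessors
#' @export
setMethod("cd8Expression", "SyntheticCohort", function(object) object@cd8)
#' @rdname accessors
#' @export
setMethod("wholeBloodExpression", "SyntheticCohort",
          function(object) object@wholeBlood)
#' @rdname accessors
#' @export
setMethod("ctTable", "SyntheticCohort", function(object) object@ctTable)
#' @rdname accessors
#' @export
setMethod("clinicalCourse", "SyntheticCohort", function(object) object@clinical)
#' @rdname accessors
#' @export
setMethod("trueLabels", "SyntheticCohort", function(object) object@trueLabels)

#' @rdname accessors
#' @export
setMethod("consensusMatrix", "ConsensusResult",
          function(object) object@consensusMatrix)
#' @rdname accessors
#' @export
setMethod("chosenK", "ConsensusResult", function(object) object@chosenK)
#' @rdname accessors
#' @export
setMethod("subgroupLabels", "ConsensusResult", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("pacScores", "ConsensusResult", function(object) object@kScores)

#' @rdname accessors
#' @export
setMethod("modelCoef", "CandidateModel", function(object) object@beta)
#' @rdname accessors
#' @export
setMethod("modelIntercept", "CandidateModel", function(object) object@intercept)
#' @rdname accessors
#' @export
setMethod("modelBIC", "CandidateModel", function(object) object@bic)

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", ncol(object@cd8), "samples\n")
  cat("  cd8        :", nrow(object@cd8), "genes\n")
  cat("  wholeBlood :", nrow(object@wholeBlood), "genes\n")
  cat("  ctTable    :", nrow(object@ctTable), "Ct records,",
      length(unique(object@ctTable$gene)), "genes\n")
  cat("  subgroups  :",
      paste(sprintf("%s=%d", levels(object@trueLabels),
                    tabulate(object@trueLabels)), collapse = ", "), "\n")
})

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult: n =", nrow(object@consensusMatrix),
      " chosen k =", object@chosenK, "\n")
  pac <- object@kScores
  cat("  PAC:", paste(sprintf("k=%d %.3f", pac$k, pac$pac), collapse = "  "),
      "\n")
  cat("  cluster sizes:", paste(tabulate(object@labels), collapse = ", "), "\n")
})

setMethod("show", "CandidateModel", function(object) {
  cat(sprintf(
    "CandidateModel: k=%d nonzero of %d features | lambda1=%.4g lambda2=%.4g gamma=%s\n",
    object@k, length(object@beta), object@lambda1, object@lambda2,
    ifelse(is.na(object@gamma), "none (classic)", format(object@gamma))))
  cat(sprintf("  logLik=%.4f  BIC=%.4f  n=%d\n",
              object@logLik, object@bic, object@n))
})

setMethod("show", "LockedClassifier", function(object) {
  cat(sprintf("LockedClassifier (version %s, locked)\n", object@version))
  cat(sprintf("  %d informative + %d reference genes; threshold %.2f (>= -> %s)\n",
              length(object@informativeGenes), length(object@referenceGenes),
              object@threshold, object@labelHi))
  cat("  checksum:", object@checksum, "\n")
})

setMethod("show", "LoocvReport", function(object) {
  cat(sprintf("Nested LOOCV: accuracy %.3f (%d/%d), 95%% CI %.3f-%.3f\n",
              object@accuracy, object@nCorrect, object@n,
              object@ciLow, object@ciHigh))
})
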