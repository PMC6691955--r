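#' Run the full biomarker development pipeline on a synthetic cohort
#'
#' End-to-end orchestration of every stage on one cohort:
#' \enumerate{
#'   \item subgroup discovery: consensus clustering of the CD8 expression,
#'     oriented into IBD1/IBD2 by a marker gene set (by default the planted
#'     up-regulated genes, standing in for biological marker knowledge);
#'   \item whole-blood training: feature standardisation, adaptive
#'     Elastic-Net grid, BIC selection;
#'   \item translation: candidate panel assembly (optimal + correlated +
#'     lower-ranked model genes), simulated qPCR of that panel, delta-delta-Ct
#'     quantification, microarray/qPCR correlation filter, re-fit of the
#'     identical penalised strategy on standardised delta-Ct features;
#'   \item lock-down: cross-validated 1-SE re-regularisation on unscaled
#'     delta-Ct features of the refit model's genes, md5-checksummed;
#'   \item classification and prognostic validation: locked-classifier calls
#'     for all samples, agreement with the planted labels, log-rank test,
#'     Cox hazard ratio and the 18-month confusion matrix against the
#'     simulated clinical course.
#' }
#' Deterministic for fixed (config, seed).
#'
#' @param config a [simConfig()]; its `seed` drives the cohort.
#' @param seed integer seed for the analysis randomness (consensus
#'   resampling, panel qPCR simulation, CV folds).
#' @param kRange,nResamples,topVarGenes consensus-clustering controls
#'   (reduced defaults relative to [consensusCluster()] to keep a full run
#'   interactive; see the methods vignette).
#' @param nLambda1,lambda2,gamma grid controls (see [makeModelGrid()]).
#' @param quotas,rCorrMin panel-selection controls.
#' @param rMin correlation-filter threshold.
#' @param nFolds folds for the unscaled 1-SE step.
#' @return list with components `cohort`, `consensus`, `discoveredLabels`,
#'   `models`, `optimalModel`, `panel`, `correlationReport`, `qpcrModel`,
#'   `classifier`, `calls`, `agreement`, `logrank`, `cox`, `confusion`.
#' @export
runPipeline <- function(config = simConfig(), seed = 1L,
                        kRange = 2:4, nResamples = 100L, topVarGenes = 500L,
                        nLambda1 = 30L,
                        lambda2 = c(0.01, 0.1, 1), gamma = c(0.5, 1, 2),
                        quotas = c(12L, 6L, 21L), rCorrMin = 0.8,
                        rMin = 0.5, nFolds = 10L) {
  cohort <- simulateCohort(config)
  cd8 <- .asExprMatrix(cd8Expression(cohort))
  wb <- .asExprMatrix(wholeBloodExpression(cohort))
  refs <- cohort@config$referenceGenes
  informativeUp <- with(as.data.frame(
    SummarizedExperiment::rowData(cd8Expression(cohort))),
    gene_id[informative & direction > 0])

  # 1. subgroup discovery on CD8 T cell expression
  cons <- consensusCluster(cd8[setdiff(rownames(cd8), refs), , drop = FALSE],
                           kRange = kRange, nResamples = nResamples,
                           topVarGenes = topVarGenes, seed = seed)
  if (chosenK(cons) != 2L)
    stop("consensus clustering did not choose two subgroups (k = ",
         chosenK(cons), ")")
  lab <- assignSubgroupNames(cons, cd8, informativeUp)
  y <- as.integer(lab == "IBD1")

  # 2. whole-blood classifier training
  Xwb <- t(wb[setdiff(rownames(wb), refs), , drop = FALSE])
  z <- standardizeFeatures(t(Xwb))
  Xs <- t(z)
  grid <- makeModelGrid(Xs, y, nLambda1 = nLambda1, lambda2 = lambda2,
                        gamma = gamma)
  models <- fitAdaptiveGrid(Xs, y, grid)
  optimal <- selectBestModel(models)

  # 3. translation to qPCR scale
  panel <- selectCandidatePanel(models, optimal, wb, quotas = quotas,
                                rCorrMin = rCorrMin, referenceGenes = refs)
  ct <- simulateQpcr(wholeBloodExpression(cohort), panel$informative,
                     referenceGenes = refs,
                     plateNoiseSd = config$plateNoiseSd,
                     slope = config$ctSlope, offset = config$ctOffset,
                     seed = seed + 1L)
  rel <- deltaDeltaCt(ct, refs)
  filt <- correlationFilter(wb, rel, panel$informative, rMin = rMin)
  retained <- filt$retained
  if (length(retained) < 2L)
    stop("correlation filter retained fewer than two genes")
  dct <- deltaCtMatrix(rel)[, retained, drop = FALSE]
  zq <- standardizeFeatures(t(dct))
  qpcrModel <- refitOnQpcr(t(zq), y)

  # 4. lock-down on unscaled delta-Ct features
  lockedGenes <- names(modelCoef(qpcrModel))[modelCoef(qpcrModel) != 0]
  if (length(lockedGenes) < 1L) lockedGenes <- retained
  clf <- regularizeUnscaled(dct[, lockedGenes, drop = FALSE], y,
                            referenceGenes = refs, nFolds = nFolds,
                            seed = seed + 2L)

  # 5. classify and validate against the simulated clinical course
  calls <- classifySample(clf, ct)
  truth <- trueLabels(cohort)[calls$sample_id]
  agreement <- mean((calls$label == clf@labelHi) == (truth == "IBD1"),
                    na.rm = TRUE)
  clin <- clinicalCourse(cohort)
  grp <- calls$label[match(clin$sample_id, calls$sample_id)]
  lr <- logrankTest(clin$time_years, clin$event, grp)
  cox <- tryCatch(
    coxHr(clin$time_years, clin$event,
          factor(grp, levels = c(clf@labelLo, clf@labelHi))),
    error = function(e) NULL)
  conf <- confusionAtHorizon(calls, clin, labelHi = clf@labelHi)

  list(cohort = cohort, consensus = cons, discoveredLabels = lab,
       models = models, optimalModel = optimal, panel = panel,
       correlationReport = filt$report, qpcrModel = qpcrModel,
       classifier = clf, calls = calls, agreement = agreement,
       logrank = lr, cox = cox, confusion = conf)
}
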