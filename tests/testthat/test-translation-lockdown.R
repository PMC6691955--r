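# build a deterministic model list + microarray for panel-selection tests:
# 12 optimal genes, 6 near-duplicates of them, 30 extra genes that appear in
# lower-ranked models, plus noise genes
panelFixture <- function(seed = 1) {
  set.seed(seed)
  n <- 50
  optGenes <- sprintf("OPT%02d", 1:12)
  corGenes <- sprintf("COR%02d", 1:6)
  subGenes <- sprintf("SUB%02d", 1:30)
  noise <- sprintf("NSE%02d", 1:20)
  m <- matrix(rnorm((12 + 30 + 20) * n), ncol = n,
              dimnames = list(c(optGenes, subGenes, noise), NULL))
  colnames(m) <- sprintf("s%02d", 1:n)
  corRows <- m[1:6, ] + rnorm(6 * n, 0, 0.05)  # |r| ~ 0.999 with OPT01..06
  rownames(corRows) <- corGenes
  m <- rbind(m, corRows)
  genes <- rownames(m)
  mk <- function(nz, loglik) {
    beta <- setNames(numeric(length(genes)), genes)
    beta[nz] <- 1
    new("CandidateModel", beta = beta, intercept = 0, lambda1 = 0.1,
        lambda2 = 0.1, gamma = 1,
        adaptiveWeights = setNames(rep(1, length(genes)), genes),
        k = length(nz), logLik = loglik,
        bic = bicScore(loglik, length(nz), n), n = as.integer(n))
  }
  optimal <- mk(optGenes, -5)
  lower <- lapply(1:25, function(i)
    mk(sample(subGenes, 8), -20 - i))  # all rank below the optimal
  list(m = m, optimal = optimal, models = c(list(optimal), lower),
       optGenes = optGenes, corGenes = corGenes, subGenes = subGenes)
}

test_that("candidate panel partitions into the configured quotas", {
  fx <- panelFixture()
  p <- selectCandidatePanel(fx$models, fx$optimal, fx$m,
                            quotas = c(12L, 6L, 21L), rCorrMin = 0.8,
                            referenceGenes = c("REF1", "REF2", "REF3"))
  expect_identical(p$fromOptimal, fx$optGenes)
  expect_identical(sort(p$correlatedAdditions), fx$corGenes)
  expect_identical(length(p$fromSuboptimalModels), 21L)
  expect_true(all(p$fromSuboptimalModels %in% fx$subGenes))
  expect_identical(length(p$informative), 39L)
  # the three informative lists are disjoint
  expect_identical(anyDuplicated(p$informative), 0L)
  # determinism: identical inputs give an identical ordered panel
  p2 <- selectCandidatePanel(fx$models, fx$optimal, fx$m,
                             quotas = c(12L, 6L, 21L), rCorrMin = 0.8,
                             referenceGenes = c("REF1", "REF2", "REF3"))
  expect_identical(p, p2)
})

test_that("an unattainable correlation threshold rolls the quota forward", {
  fx <- panelFixture()
  p <- expect_no_error(
    selectCandidatePanel(fx$models, fx$optimal, fx$m,
                         quotas = c(12L, 6L, 21L), rCorrMin = 1.0))
  expect_identical(p$correlatedAdditions, character(0))
  expect_identical(length(p$fromSuboptimalModels), 27L)
  expect_identical(length(p$informative), 39L)
})

test_that("qPCR refit keeps audit fields and nulls out without signal", {
  set.seed(2)
  n <- 40
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("g", 1:8)))
  y <- rep(c(0, 1), each = 20)
  grid <- data.frame(lambda1 = c(0.3, 0.1, 0.03), lambda2 = 0.1, gamma = 1)
  m <- refitOnQpcr(X, y, grid)
  expect_s4_class(m, "CandidateModel")
  expect_true(is.finite(m@logLik) && is.finite(m@bic))
  expect_identical(m@k, 0L)  # pure noise: standard BIC keeps the null model
  # with signal the planted feature is recovered
  X2 <- X; X2[, 1] <- X2[, 1] + 3 * y
  X2 <- t(standardizeFeatures(t(X2)))
  m2 <- refitOnQpcr(X2, y, grid)
  expect_true(modelCoef(m2)[["g1"]] != 0)
})

test_that("the 1-SE lock-down is at least as sparse as the CV minimum", {
  set.seed(5)
  n <- 60
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("g", 1:10)))
  y <- rbinom(n, 1, plogis(2 * X[, 1] - 2 * X[, 2]))
  clf <- regularizeUnscaled(X, y, referenceGenes = c("R1", "R2"), seed = 3)
  cv <- attr(clf, "cv")
  expect_gte(cv$lambda.1se, cv$lambda.min)
  expect_lte(cv$nzero[which(cv$lambda == cv$lambda.1se)],
             cv$nzero[which(cv$lambda == cv$lambda.min)])
  expect_lte(length(clf@informativeGenes), 10L)
  expect_gt(length(clf@informativeGenes), 0L)
  # same seed, same data -> identical locked classifier
  clf2 <- regularizeUnscaled(X, y, referenceGenes = c("R1", "R2"), seed = 3)
  expect_identical(clf@checksum, clf2@checksum)
})

test_that("classification matches hand-computed logistic scores", {
  clf <- ibdProg:::.newLockedClassifier(
    informativeGenes = c("A", "B", "C"), referenceGenes = "R1",
    beta = c(0.5, -1, 2), intercept = 0.25)
  ct <- ctFrom(list(S1 = list(A = rep(27, 3), B = rep(26, 3),
                              C = rep(25.5, 3), R1 = rep(25, 3))))
  out <- classifySample(clf, ct)
  dct <- c(2, 1, 0.5)
  pHand <- plogis(0.25 + sum(c(0.5, -1, 2) * dct))
  expect_equal(out$probability, pHand, tolerance = 1e-12)
  expect_identical(out$label, "IBDhi")

  # constant Ct shift of the whole sample leaves the call unchanged
  ct2 <- ct; ct2$ct <- ct2$ct + 4.2
  expect_equal(classifySample(clf, ct2)$probability, out$probability,
               tolerance = 1e-12)
})

test_that("classification boundary and degenerate cases are deterministic", {
  clf0 <- ibdProg:::.newLockedClassifier(
    informativeGenes = c("A", "B"), referenceGenes = "R1",
    beta = c(0, 0), intercept = 0)
  ct <- ctFrom(list(S1 = list(A = rep(26, 3), B = rep(27, 3),
                              R1 = rep(25, 3))))
  out <- classifySample(clf0, ct)
  expect_identical(out$probability, 0.5)
  expect_identical(out$label, "IBDhi")  # boundary goes to the high-risk side

  # intercept-only classifier scores every sample at logistic(intercept)
  clfI <- ibdProg:::.newLockedClassifier(
    informativeGenes = c("A", "B"), referenceGenes = "R1",
    beta = c(0, 0), intercept = -1.2)
  expect_equal(classifySample(clfI, ct)$probability, plogis(-1.2))

  # a missing gene yields a named no-call, never a silent default
  ctMiss <- ctFrom(list(S1 = list(A = rep(26, 3), R1 = rep(25, 3))))
  miss <- classifySample(clf0, ctMiss)
  expect_true(is.na(miss$probability))
  expect_match(miss$no_call_reason, "B")
})

test_that("lock-down is tamper-evident in memory and on disk", {
  clf <- ibdProg:::.newLockedClassifier(
    informativeGenes = c("A", "B"), referenceGenes = "R1",
    beta = c(1.5, -0.75), intercept = 0.1)
  expect_true(validObject(clf))
  hacked <- clf
  hacked@beta[1] <- 2
  expect_error(validObject(hacked), "checksum")

  path <- withr::local_tempfile(fileext = ".json")
  writeLockedClassifier(clf, path)
  back <- readLockedClassifier(path)
  expect_identical(back@checksum, clf@checksum)
  expect_equal(back@beta, clf@beta)
  expect_identical(back@intercept, clf@intercept)

  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$beta$A <- doc$beta$A + 1e-9
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(readLockedClassifier(path), "checksum")
})

test_that("the full pipeline runs deterministically and recovers the subgroups", {
  res1 <- runPipeline(simConfig(seed = 21), seed = 21)
  expect_gte(res1$agreement, 0.75)
  expect_identical(chosenK(res1$consensus), 2L)
  expect_identical(length(res1$panel$informative), 39L)
  expect_gt(length(res1$classifier@informativeGenes), 0L)
  res2 <- runPipeline(simConfig(seed = 21), seed = 21)
  expect_identical(res1$classifier@checksum, res2$classifier@checksum)
  expect_identical(res1$calls, res2$calls)
  expect_identical(res1$agreement, res2$agreement)
})
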