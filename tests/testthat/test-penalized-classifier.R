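test_that("full shrinkage leaves only the prevalence intercept", {
  set.seed(1)
  inst <- randomLogisticInstance(40, 6)
  m <- fitElasticNetLogistic(inst$X, inst$y, lambda1 = 10, lambda2 = 0)
  expect_identical(m@k, 0L)
  expect_true(all(modelCoef(m) == 0))
  expect_equal(modelIntercept(m), qlogis(mean(inst$y)), tolerance = 1e-5)
})

test_that("solver matches the independent convex oracle on random instances", {
  set.seed(10)
  for (i in 1:10) {
    inst <- randomLogisticInstance()
    l1 <- runif(1, 0.01, 0.3); l2 <- runif(1, 0.001, 0.5)
    w <- runif(5, 0.5, 2)
    m <- fitElasticNetLogistic(inst$X, inst$y, l1, l2, weights = w)
    fOracle <- glmnetOracleObjective(inst$X, inst$y, l1, l2, w)
    expect_lte(penalizedObjective(m, inst$X, inst$y), fOracle + 1e-6)
  }
})

test_that("the solver objective never increases across sweeps", {
  set.seed(3)
  inst <- randomLogisticInstance(30, 8)
  w <- rep(1, 8)
  objAt <- function(it) {
    f <- ibdProg:::.enetLogisticCd(inst$X, inst$y, 0.05, 0.01, w,
                                   numeric(8), 0, 0, as.integer(it))
    f$objective
  }
  objs <- vapply(1:15, objAt, numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("with ridge regularisation the optimum is initialisation-independent", {
  set.seed(4)
  inst <- randomLogisticInstance(25, 6)
  m1 <- fitElasticNetLogistic(inst$X, inst$y, 0.05, 0.1)
  m2 <- fitElasticNetLogistic(inst$X, inst$y, 0.05, 0.1,
                              init = list(beta = rnorm(6), intercept = 2))
  expect_lt(abs(penalizedObjective(m1, inst$X, inst$y) -
                  penalizedObjective(m2, inst$X, inst$y)), 1e-6)
  expect_equal(modelCoef(m1), modelCoef(m2), tolerance = 1e-4)
})

test_that("degenerate solver inputs error", {
  inst <- randomLogisticInstance()
  expect_error(fitElasticNetLogistic(inst$X, rep(1, 20), 0.1, 0.1), "classes")
  bad <- inst$X; bad[1, 1] <- NA
  expect_error(fitElasticNetLogistic(bad, inst$y, 0.1, 0.1), "finite")
  expect_error(fitElasticNetLogistic(inst$X, inst$y, 0.1, 0.1,
                                     weights = c(-1, rep(1, 4))), "weights")
})

test_that("adaptive weights follow the guarded power formula", {
  expect_equal(adaptiveWeights(c(0.3, -2, 0), gamma = 0, n = 50), rep(1, 3))
  w <- adaptiveWeights(c(0.5, 0), gamma = 1, n = 100)
  expect_equal(w, c(1 / 0.51, 100))
  expect_equal(w[1], 1.960784, tolerance = 1e-6)
  # finite even at zero initial coefficients, any gamma
  expect_true(all(is.finite(adaptiveWeights(rep(0, 4), gamma = 2, n = 10))))
  expect_error(adaptiveWeights(c(1, 2), gamma = -1, n = 10), "gamma")
})

test_that("unit weights reduce the adaptive fit to the classic fit", {
  set.seed(6)
  inst <- randomLogisticInstance(30, 5)
  classic <- fitElasticNetLogistic(inst$X, inst$y, 0.05, 0.1)
  viaWeights <- fitElasticNetLogistic(inst$X, inst$y, 0.05, 0.1,
                                      weights = rep(1, 5))
  expect_equal(modelCoef(classic), modelCoef(viaWeights), tolerance = 1e-10)
  # gamma = 0 in the grid pipeline gives the same solution
  grid <- data.frame(lambda1 = 0.05, lambda2 = 0.1, gamma = 0)
  m <- fitAdaptiveGrid(inst$X, inst$y, grid)[[1]]
  expect_equal(modelCoef(m), modelCoef(classic), tolerance = 1e-4)
})

test_that("BIC matches hand arithmetic under both conventions", {
  expect_identical(bicScore(0, 0, 10), 0)
  expect_equal(bicScore(-10, 3, 69), 20 + 3 * log(69))
  expect_equal(bicScore(-10, 3, 69), 32.70237, tolerance = 1e-5)
  expect_equal(bicScore(-10, 3, 69, "paper-literal"), 10 - 3 * log(69))
  # for fixed fit quality more genes always worsens the selected direction
  expect_gt(bicScore(-10, 4, 69), bicScore(-10, 3, 69))
  expect_lt(bicScore(-10, 4, 69, "paper-literal"),
            bicScore(-10, 3, 69, "paper-literal"))
  expect_error(bicScore(-10, 3, 69, "mystery"))
})

test_that("model selection agrees with exhaustive enumeration and tie rules", {
  mk <- function(loglik, k, l1) {
    beta <- setNames(c(rep(0.5, k), rep(0, 10 - k)), paste0("g", 1:10))
    new("CandidateModel", beta = beta, intercept = 0, lambda1 = l1,
        lambda2 = 0.1, gamma = 1,
        adaptiveWeights = setNames(rep(1, 10), paste0("g", 1:10)),
        k = as.integer(k), logLik = loglik, bic = bicScore(loglik, k, 69),
        n = 69L)
  }
  set.seed(8)
  for (rep in 1:20) {
    models <- lapply(1:10, function(i)
      mk(-runif(1, 5, 40), sample(0:8, 1), runif(1)))
    for (conv in c("standard", "paper-literal")) {
      sel <- selectBestModel(models, conv)
      sc <- vapply(models, function(m) bicScore(m@logLik, m@k, m@n, conv),
                   numeric(1))
      best <- if (conv == "standard") min(sc) else max(sc)
      expect_equal(bicScore(sel@logLik, sel@k, sel@n, conv), best)
    }
  }
  # singleton list returns that model
  one <- mk(-10, 2, 0.5)
  expect_identical(selectBestModel(list(one)), one)
  # equal score and k: the larger-lambda1 model wins
  a <- mk(-10, 2, 0.2); b <- mk(-10, 2, 0.7)
  expect_identical(selectBestModel(list(a, b))@lambda1, 0.7)
  expect_error(selectBestModel(list()), "nonempty")
})

test_that("the default grid factorisation yields 2100 candidate triples", {
  inst <- randomLogisticInstance(20, 4)
  grid <- makeModelGrid(inst$X, inst$y)
  expect_identical(nrow(grid), 2100L)
  expect_identical(attr(grid, "size"), 2100L)
  expect_identical(anyDuplicated(grid), 0L)
  # lambda1 spans three decades below the null-model threshold
  l1 <- sort(unique(grid$lambda1))
  expect_equal(min(l1) / max(l1), 1e-3, tolerance = 1e-10)
})

test_that("grid fitting is deterministic and shrinks to the null on noise", {
  set.seed(12)
  inst <- randomLogisticInstance(25, 6)
  grid <- data.frame(lambda1 = c(5, 5, 0.05), lambda2 = 0.1,
                     gamma = c(0.5, 1, 1))
  m1 <- fitAdaptiveGrid(inst$X, inst$y, grid)
  m2 <- fitAdaptiveGrid(inst$X, inst$y, grid)
  expect_equal(lapply(m1, modelCoef), lapply(m2, modelCoef))
  expect_identical(length(fitAdaptiveGrid(inst$X, inst$y, grid[1, ])), 1L)
  # large-lambda rows are fully shrunk
  expect_identical(m1[[1]]@k, 0L)
  expect_identical(m1[[2]]@k, 0L)
})

test_that("selected models are enriched for planted informative genes", {
  fracs <- vapply(1:5, function(s) {
    coh <- simulateCohort(simConfig(seed = s, wholeBloodAttenuation = 1))
    wb <- SummarizedExperiment::assay(wholeBloodExpression(coh))[1:500, ]
    y <- as.integer(trueLabels(coh) == "IBD1")
    Xs <- t(standardizeFeatures(wb))
    grid <- makeModelGrid(Xs, y, nLambda1 = 20, lambda2 = c(0.01, 0.1, 1),
                          gamma = c(0.5, 1, 2))
    best <- selectBestModel(fitAdaptiveGrid(Xs, y, grid))
    nz <- names(modelCoef(best))[modelCoef(best) != 0]
    expect_gt(length(nz), 0)
    mean(nz %in% sprintf("G%03d", 1:50))
  }, numeric(1))
  expect_gte(mean(fracs), 0.8)
})

test_that("sparsity is monotone along the lambda1 path on average", {
  set.seed(15)
  sizes <- replicate(10, {
    inst <- randomLogisticInstance(30, 10)
    grid <- data.frame(lambda1 = c(0.2, 0.05, 0.01), lambda2 = 0.05,
                       gamma = 1)
    vapply(fitAdaptiveGrid(inst$X, inst$y, grid), function(m) m@k, integer(1))
  })
  means <- rowMeans(sizes)
  expect_true(all(diff(means) >= 0))
})
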