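#' Hyperparameter grid for adaptive Elastic-Net training
#'
#' Builds the (lambda1, lambda2, gamma) triples over which candidate models
#' are fitted. lambda1 is log-spaced from the smallest value that shrinks
#' every coefficient to zero in the unit-weight problem
#' (`max_j |x_j'(y - mean(y))| / n`) down to `lambda1MinRatio` times it.
#' The default factorisation 70 x 10 x 3 yields 2100 candidate models.
#'
#' @param X,y training data (used only to locate the lambda1 path).
#' @param nLambda1 number of lambda1 values (default 70).
#' @param lambda1MinRatio smallest lambda1 as a fraction of the null-model
#'   threshold (default 1e-3).
#' @param lambda2 ridge penalty values (default 10 log-spaced values over
#'   `[1e-3, 10]`).
#' @param gamma adaptive exponents (default `c(0.5, 1, 2)`).
#' @return data.frame of unique triples with columns `lambda1`, `lambda2`,
#'   `gamma`; attribute `size` holds the row count.
#' @export
makeModelGrid <- function(X, y, nLambda1 = 70L, lambda1MinRatio = 1e-3,
                          lambda2 = 10^seq(-3, 1, length.out = 10),
                          gamma = c(0.5, 1, 2)) {
  y <- .asBinary(y)
  n <- nrow(X)
  l1max <- max(abs(crossprod(X, y - mean(y)))) / n
  l1 <- exp(seq(log(l1max), log(l1max * lambda1MinRatio),
                length.out = nLambda1))
  grid <- expand.grid(lambda1 = l1, lambda2 = lambda2, gamma = gamma,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- unique(grid)
  if (nrow(grid) < 1L) stop("grid must contain at least one triple")
  attr(grid, "size") <- nrow(grid)
  grid
}

#' Fit the full candidate-model grid
#'
#' For every (lambda1, lambda2, gamma) triple: a stage-1 classic Elastic-Net
#' fit at (lambda1, lambda2) provides initial coefficients; adaptive weights
#' \eqn{(|\hat\beta_j| + 1/n)^{-\gamma}} re-weight the L1 penalty; and the
#' stage-2 weighted fit at the same (lambda1, lambda2) is the candidate
#' model, carrying its BIC. Stage-1 fits are shared across gamma values and
#' warm-started down each lambda1 path. Deterministic given (X, y, grid).
#'
#' @param X samples x features matrix, column-standardised.
#' @param y binary labels.
#' @param grid data.frame from [makeModelGrid()] (columns `lambda1`,
#'   `lambda2`, `gamma`).
#' @param tol,maxit solver controls, see [fitElasticNetLogistic()].
#' @return list of [CandidateModel-class], one per grid row, in grid order.
#' @export
fitAdaptiveGrid <- function(X, y, grid, tol = 1e-8, maxit = 1e5L) {
  if (is.null(grid) || nrow(grid) < 1L) stop("grid must be nonempty")
  stopifnot(all(c("lambda1", "lambda2", "gamma") %in% names(grid)))
  X <- as.matrix(X)
  p <- ncol(X)
  unit <- rep(1, p)

  models <- vector("list", nrow(grid))
  pairs <- unique(grid[, c("lambda1", "lambda2")])
  # order each lambda2 path by decreasing lambda1 for warm starts
  for (l2 in unique(pairs$lambda2)) {
    l1s <- sort(unique(pairs$lambda1[pairs$lambda2 == l2]), decreasing = TRUE)
    warm <- NULL
    for (l1 in l1s) {
      stage1 <- tryCatch(
        fitElasticNetLogistic(X, y, l1, l2, weights = unit, tol = tol,
                              maxit = maxit, init = warm),
        error = function(e)
          stop(sprintf("solver failed at lambda1=%g lambda2=%g (stage 1): %s",
                       l1, l2, conditionMessage(e)), call. = FALSE))
      warm <- list(beta = modelCoef(stage1),
                   intercept = modelIntercept(stage1))
      rows <- which(grid$lambda1 == l1 & grid$lambda2 == l2)
      for (r in rows) {
        g <- grid$gamma[r]
        w <- adaptiveWeights(stage1, gamma = g)
        models[[r]] <- tryCatch(
          fitElasticNetLogistic(X, y, l1, l2, weights = w, gamma = g,
                                tol = tol, maxit = maxit, init = warm),
          error = function(e)
            stop(sprintf(
              "solver failed at lambda1=%g lambda2=%g gamma=%g (stage 2): %s",
              l1, l2, g, conditionMessage(e)), call. = FALSE))
      }
    }
  }
  models
}

#' Bayesian Information Criterion for a fitted candidate model
#'
#' `convention = "standard"` (default) computes
#' \eqn{-2\ell + k\,\ln n}, lower is better. `convention = "paper-literal"`
#' computes \eqn{-\ell - k\,\ln n} with higher declared better; it is kept
#' behind this flag for auditability, since read literally it rewards larger
#' models only through the likelihood term's sign (see the methods
#' vignette). [selectBestModel()] consumes the convention consistently.
#'
#' @param loglik natural-log likelihood at the optimum.
#' @param k number of genes incorporated (nonzero coefficients).
#' @param n sample count.
#' @param convention `"standard"` or `"paper-literal"`.
#' @return numeric(1).
#' @examples
#' bicScore(-10, 3, 69)  # 20 + 3*log(69)
#' @export
bicScore <- function(loglik, k, n,
                     convention = c("standard", "paper-literal")) {
  convention <- match.arg(convention)
  if (n < 1) stop("n must be >= 1")
  if (k < 0) stop("k must be >= 0")
  switch(convention,
         "standard" = -2 * loglik + k * log(n),
         "paper-literal" = -loglik - k * log(n))
}

#' Select the best candidate model by BIC
#'
#' Under `"standard"` the smallest BIC wins; under `"paper-literal"` the
#' largest score wins. Ties break by smaller k, then larger lambda1; the
#' result is deterministic.
#'
#' @param models nonempty list of [CandidateModel-class].
#' @param convention see [bicScore()].
#' @return the selected [CandidateModel-class].
#' @export
selectBestModel <- function(models,
                            convention = c("standard", "paper-literal")) {
  convention <- match.arg(convention)
  if (length(models) == 0) stop("model list must be nonempty")
  score <- vapply(models, function(m)
    bicScore(m@logLik, m@k, m@n, convention), numeric(1))
  if (convention == "paper-literal") score <- -score  # minimise uniformly
  k <- vapply(models, function(m) as.numeric(m@k), numeric(1))
  l1 <- vapply(models, function(m) m@lambda1, numeric(1))
  ord <- order(score, k, -l1)
  models[[ord[1L]]]
}
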