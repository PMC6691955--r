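#' Nested leave-one-out cross-validation of the model-selection pipeline
#'
#' For every held-out sample, the entire training pipeline is re-run on the
#' remaining n-1 samples: per-feature standardisation parameters are
#' re-estimated, the full candidate grid is re-fitted, and BIC selection is
#' repeated. The held-out sample is transformed with the training fold's
#' centre/scale and scored by the fold's selected model at the 0.5
#' threshold. Because nothing from the held-out sample enters the fold, the
#' resulting accuracy is an honest generalisation estimate of the whole
#' procedure, not of a single fit. The 95\% CI is exact (Clopper-Pearson).
#'
#' @param X samples x features matrix on the raw (unstandardised) scale.
#' @param y binary labels (0/1 or two-level factor).
#' @param grid data.frame of hyperparameter triples (see [makeModelGrid()]);
#'   held fixed across folds.
#' @param convention BIC convention, see [bicScore()].
#' @param returnFoldDetails if TRUE, attach per-fold standardisation
#'   parameters and selected models (used to audit leakage).
#' @param tol,maxit solver controls.
#' @return a [LoocvReport-class]; with `returnFoldDetails = TRUE` the
#'   report's `predictions` carries an attribute `folds`.
#' @export
nestedLoocv <- function(X, y, grid,
                        convention = c("standard", "paper-literal"),
                        returnFoldDetails = FALSE, tol = 1e-8, maxit = 1e5L) {
  convention <- match.arg(convention)
  X <- as.matrix(X)
  y <- .asBinary(y)
  n <- nrow(X)
  if (n < 10) stop("nested LOOCV requires n >= 10")
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("obs%03d", seq_len(n))
  rownames(X) <- ids
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))

  prob <- numeric(n)
  folds <- if (returnFoldDetails) vector("list", n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L)
      stop(sprintf("fold %d (holding out '%s') has a single class", i, ids[i]))
    Xtr <- X[-i, , drop = FALSE]
    ztr <- standardizeFeatures(t(Xtr))      # genes x samples convention
    ctr <- attr(ztr, "center"); scl <- attr(ztr, "scale")
    Xs <- t(ztr)
    models <- fitAdaptiveGrid(Xs, ytr, grid, tol = tol, maxit = maxit)
    best <- selectBestModel(models, convention)
    xh <- (X[i, ] - ctr) / scl
    prob[i] <- predictProbability(best, matrix(xh, 1L,
                                               dimnames = list(NULL, names(xh))))
    if (returnFoldDetails)
      folds[[i]] <- list(center = ctr, scale = scl, model = best)
  }
  call <- as.integer(prob >= 0.5)
  correct <- call == y
  nc <- sum(correct)
  ci <- binom.test(nc, n)$conf.int
  preds <- data.frame(sample = ids, truth = y, probability = prob,
                      call = call, correct = correct,
                      stringsAsFactors = FALSE)
  if (returnFoldDetails) attr(preds, "folds") <- folds
  new("LoocvReport", n = as.integer(n), nCorrect = as.integer(nc),
      accuracy = nc / n, ciLow = ci[1], ciHigh = ci[2], predictions = preds)
}

#' One-sided exact binomial comparison against a dummy classifier
#'
#' Upper-tail probability \eqn{P(X \ge n_{correct})} for
#' \eqn{X \sim Binomial(n, p_0)}, computed by direct summation of the
#' binomial mass. `p0 = 0.5` corresponds to a coin-flip dummy; passing the
#' class prevalence is the alternative comparison.
#'
#' @param nCorrect,n observed correct calls out of n.
#' @param p0 dummy success probability in (0,1) (default 0.5).
#' @return one-sided p-value.
#' @examples
#' binomialTestVsDummy(69, 69)  # 0.5^69
#' @export
binomialTestVsDummy <- function(nCorrect, n, p0 = 0.5) {
  if (n < 1 || nCorrect < 0 || nCorrect > n)
    stop("need 0 <= nCorrect <= n with n >= 1")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  min(1, sum(dbinom(seq(nCorrect, n), n, p0)))
}
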