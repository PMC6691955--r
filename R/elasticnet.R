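#' Penalised logistic regression (classic / adaptive Elastic-Net)
#'
#' Minimises
#' \deqn{-\frac{1}{n}\ell(\beta_0,\beta) +
#'   \lambda_1 \sum_j w_j |\beta_j| + \frac{\lambda_2}{2}\sum_j \beta_j^2}
#' where \eqn{\ell} is the binomial log-likelihood and the intercept is
#' unpenalised. With unit weights this is the classic Elastic-Net; with
#' weights from [adaptiveWeights()] it is the second, adaptively weighted
#' stage. The solver is cyclic coordinate descent on a quadratic majoriser
#' of the logistic loss, so the objective is non-increasing across
#' iterations; with `lambda2 > 0` the optimum is unique.
#'
#' @param X samples x features numeric matrix (column-standardised for the
#'   grid pipeline; any finite matrix is accepted).
#' @param y binary response in \{0,1\} (or a two-level factor, first level
#'   coded 0); both classes must be present.
#' @param lambda1 L1 penalty weight (>= 0).
#' @param lambda2 L2 penalty weight (>= 0).
#' @param weights per-feature positive L1 multipliers (default all 1).
#' @param gamma adaptive exponent recorded in the result (NA for classic).
#' @param tol convergence tolerance on the relative objective change
#'   (default 1e-8).
#' @param maxit maximum coordinate-descent sweeps (default 1e5).
#' @param init optional warm start, a list with `beta` and `intercept`.
#' @return a [CandidateModel-class] carrying coefficients, k, the natural-log
#'   likelihood and standard BIC.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("g1", "g2")))
#' y <- rbinom(20, 1, plogis(X[, 1]))
#' fitElasticNetLogistic(X, y, lambda1 = 0.05, lambda2 = 0.01)
#' @export
fitElasticNetLogistic <- function(X, y, lambda1, lambda2,
                                  weights = rep(1, ncol(X)), gamma = NA_real_,
                                  tol = 1e-8, maxit = 1e5L, init = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("feature matrix contains non-finite values")
  y <- .asBinary(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  if (length(weights) != ncol(X) || any(!is.finite(weights)) ||
      any(weights <= 0))
    stop("weights must be positive and finite, one per feature")
  .assertScalar(lambda1, "lambda1")
  .assertScalar(lambda2, "lambda2")
  if (lambda1 < 0 || lambda2 < 0) stop("penalties must be >= 0")

  if (is.null(init)) {
    prev <- mean(y)
    init <- list(beta = numeric(ncol(X)), intercept = qlogis(prev))
  }
  fit <- .enetLogisticCd(X, y, lambda1, lambda2, weights,
                         init$beta, init$intercept, tol, as.integer(maxit))
  beta <- as.numeric(fit$beta)
  names(beta) <- colnames(X)
  w <- as.numeric(weights)
  names(w) <- colnames(X)
  n <- nrow(X)
  k <- sum(beta != 0)
  new("CandidateModel", beta = beta, intercept = fit$intercept,
      lambda1 = lambda1, lambda2 = lambda2, gamma = gamma,
      adaptiveWeights = w, k = as.integer(k),
      logLik = min(fit$loglik, 0), bic = bicScore(fit$loglik, k, n),
      n = as.integer(n))
}

.asBinary <- function(y) {
  if (is.factor(y)) return(as.integer(y) - 1L)
  if (is.logical(y)) return(as.integer(y))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  y
}

#' Penalised-model objective value
#'
#' The objective minimised by [fitElasticNetLogistic()], evaluated for a
#' fitted model on its training data; used to compare against independent
#' convex-optimisation solutions.
#'
#' @param model a [CandidateModel-class].
#' @param X,y the training data.
#' @return numeric(1).
#' @export
penalizedObjective <- function(model, X, y) {
  y <- .asBinary(y)
  eta <- modelIntercept(model) + as.numeric(X %*% modelCoef(model))
  loss <- mean(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) -
                 y * eta)
  b <- modelCoef(model)
  loss + model@lambda1 * sum(model@adaptiveWeights * abs(b)) +
    model@lambda2 / 2 * sum(b^2)
}

#' Adaptive L1 weights from an initial fit
#'
#' Second-stage weights of the adaptive Elastic-Net:
#' \deqn{w_j = (|\hat\beta_j| + 1/n)^{-\gamma}} where \eqn{\hat\beta} is the
#' initial (classic Elastic-Net) coefficient vector. The `1/n` guard keeps
#' weights finite when an initial coefficient is exactly zero; `gamma = 0`
#' gives unit weights (classic fit).
#'
#' @param initial a [CandidateModel-class] (or bare numeric coefficient
#'   vector) from the first stage.
#' @param gamma adaptive exponent, >= 0.
#' @param n sample count, >= 1 (defaults to the model's own n).
#' @return positive, finite per-feature weights.
#' @examples
#' adaptiveWeights(c(0.5, 0), gamma = 1, n = 100)  # 1/0.51, 1/0.01
#' @export
adaptiveWeights <- function(initial, gamma, n = NULL) {
  beta <- if (is(initial, "CandidateModel")) modelCoef(initial) else
    as.numeric(initial)
  if (is.null(n)) {
    if (!is(initial, "CandidateModel"))
      stop("n must be given when 'initial' is a bare coefficient vector")
    n <- initial@n
  }
  if (gamma < 0) stop("gamma must be >= 0")
  if (n < 1) stop("n must be >= 1")
  w <- (abs(beta) + 1 / n)^(-gamma)
  stopifnot(all(is.finite(w)), all(w > 0))
  w
}

#' Predicted class-1 probabilities from a candidate model
#'
#' @param model a [CandidateModel-class].
#' @param X samples x features matrix on the same scale the model was
#'   fitted on (columns matched by name when both are named).
#' @return numeric vector of probabilities.
#' @export
predictProbability <- function(model, X) {
  X <- as.matrix(X)
  b <- modelCoef(model)
  if (!is.null(colnames(X)) && !is.null(names(b))) {
    if (!all(names(b) %in% colnames(X)))
      stop("X lacks model features: ",
           paste(setdiff(names(b), colnames(X)), collapse = ", "))
    X <- X[, names(b), drop = FALSE]
  }
  .logistic(modelIntercept(model) + as.numeric(X %*% b))
}
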