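# shared fixtures; everything is generated in code at test time

smallConfig <- function(seed = 1L, ...) {
  simConfig(nSamples = 30L, nGenes = 80L, nInformative = 16L, nBlocks = 4L,
            seed = seed, ...)
}

# long-format Ct table from a named list sample -> named list gene -> 3 cts
ctFrom <- function(spec) {
  do.call(rbind, lapply(names(spec), function(s) {
    do.call(rbind, lapply(names(spec[[s]]), function(g) {
      data.frame(sample_id = s, gene = g, replicate = 1:3,
                 ct = spec[[s]][[g]], stringsAsFactors = FALSE)
    }))
  }))
}

# random solver instance with both classes guaranteed
randomLogisticInstance <- function(n = 20, p = 5) {
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", seq_len(p))))
  repeat {
    y <- rbinom(n, 1, plogis(X[, 1] - X[, 2]))
    if (length(unique(y)) == 2) break
  }
  list(X = X, y = y)
}

# independent oracle: the same penalised objective solved by glmnet
# (penalty.factor is rescaled internally to sum to p, hence the mapping)
glmnetOracleObjective <- function(X, y, lambda1, lambda2, w) {
  p <- ncol(X)
  lam <- lambda1 * sum(w) / p + lambda2
  alpha <- (lambda1 * sum(w) / p) / lam
  g <- suppressWarnings(
    glmnet::glmnet(X, y, family = "binomial", lambda = lam, alpha = alpha,
                   penalty.factor = w, standardize = FALSE, thresh = 1e-14,
                   maxit = 1e6))
  b <- as.numeric(glmnet::coef.glmnet(g))
  eta <- b[1] + as.numeric(X %*% b[-1])
  loss <- mean(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) -
                 y * eta)
  loss + lambda1 * sum(w * abs(b[-1])) + lambda2 / 2 * sum(b[-1]^2)
}

# Efron log partial likelihood for a single binary covariate (test oracle)
efronLogPartialLik <- function(beta, time, status, x) {
  ll <- 0
  for (t in unique(time[status == 1])) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    sR <- sum(exp(beta * x[R]))
    sD <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sR - (l / d) * sD)
  }
  ll
}
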