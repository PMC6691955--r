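#' Resampling-based consensus clustering
#'
#' Monti-style consensus clustering to derive patient subgroups from
#' expression data. For each of `nResamples` resamples, a fraction
#' `subsampleFraction` of samples is drawn without replacement and the base
#' clustering is run for every k in `kRange` on the `topVarGenes`
#' most-variable genes. The consensus entry for a sample pair is the number
#' of times the pair co-clustered divided by the number of times it was
#' co-sampled. k is chosen to minimise PAC, the proportion of ambiguous
#' consensus entries falling inside `pacWindow`; ties go to the smaller k.
#' Final labels come from hierarchical clustering of `1 - consensus`
#' (average linkage) cut at the chosen k -- not from any single base run.
#'
#' @param x genes x samples matrix or SummarizedExperiment (log2 scale).
#' @param kRange integer vector of candidate cluster numbers (default 2:6).
#' @param nResamples number of resamples (default 250; at least 50).
#' @param subsampleFraction fraction of samples per resample, in (0.5, 1)
#'   (default 0.8).
#' @param baseMethod `"kmeans"` (Lloyd-type k-means on samples, 5 random
#'   starts per resample) or `"hclust"` (Euclidean average-linkage).
#' @param topVarGenes number of most-variable genes used (default 5000;
#'   capped at the number available).
#' @param pacWindow ambiguity window for PAC (default `c(0.1, 0.9)`).
#' @param seed integer RNG seed; a run is fully reproducible from
#'   (data, configuration, seed).
#' @return a [ConsensusResult-class].
#' @examples
#' coh <- simulateCohort(simConfig(nSamples = 40, nGenes = 100, seed = 3))
#' res <- consensusCluster(cd8Expression(coh), kRange = 2:3,
#'                         nResamples = 60, seed = 1)
#' chosenK(res)
#' @export
consensusCluster <- function(x, kRange = 2:6, nResamples = 250,
                             subsampleFraction = 0.8,
                             baseMethod = c("kmeans", "hclust"),
                             topVarGenes = 5000, pacWindow = c(0.1, 0.9),
                             seed = 1L) {
  baseMethod <- match.arg(baseMethod)
  m <- .asExprMatrix(x)
  if (nResamples < 50) stop("nResamples must be >= 50")
  if (subsampleFraction <= 0.5 || subsampleFraction >= 1)
    stop("subsampleFraction must lie in (0.5, 1)")
  n <- ncol(m)
  v <- apply(m, 1L, var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(topVarGenes, nrow(m)))]
  dat <- t(m[keep, , drop = FALSE])  # samples x genes

  set.seed(seed)
  nSub <- floor(subsampleFraction * n)
  ks <- sort(unique(as.integer(kRange)))
  coCluster <- lapply(ks, function(k) matrix(0, n, n))
  names(coCluster) <- as.character(ks)
  coSample <- matrix(0, n, n)

  for (b in seq_len(nResamples)) {
    idx <- sort(sample.int(n, nSub))
    coSample[idx, idx] <- coSample[idx, idx] + 1
    sub <- dat[idx, , drop = FALSE]
    hc <- if (baseMethod == "hclust") hclust(dist(sub), method = "average")
    for (k in ks) {
      cl <- if (baseMethod == "kmeans") {
        kmeans(sub, centers = k, nstart = 5L, iter.max = 50L)$cluster
      } else {
        cutree(hc, k = k)
      }
      for (g in seq_len(k)) {
        members <- idx[cl == g]
        coCluster[[as.character(k)]][members, members] <-
          coCluster[[as.character(k)]][members, members] + 1
      }
    }
  }

  off <- coSample[upper.tri(coSample)]
  if (any(off == 0))
    stop("some sample pairs were never co-sampled; increase nResamples")

  pac <- numeric(length(ks))
  consByK <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    cons <- coCluster[[i]] / coSample
    diag(cons) <- 1
    consByK[[i]] <- cons
    u <- cons[upper.tri(cons)]
    pac[i] <- mean(u > pacWindow[1] & u < pacWindow[2])
  }
  best <- which.min(pac)  # ties -> smaller k (ks sorted ascending)
  cons <- consByK[[best]]
  dimnames(cons) <- list(colnames(m), colnames(m))
  labels <- cutree(hclust(as.dist(1 - cons), method = "average"),
                   k = ks[best])
  names(labels) <- colnames(m)

  new("ConsensusResult", consensusMatrix = cons, chosenK = ks[best],
      labels = as.integer(labels) |> setNames(colnames(m)),
      kScores = data.frame(k = ks, pac = pac))
}

#' Orient two clusters as IBD1 / IBD2 by marker expression
#'
#' Fixes which of the two discovered clusters is called IBD1 (the
#' poor-prognosis subgroup): the cluster with the higher mean expression of
#' a designated marker gene set gets the `higherName`. With
#' `markerDirection = "low"` the orientation is reversed. Exact ties break
#' deterministically: the cluster containing the smallest sample index is
#' named IBD1.
#'
#' @param result a [ConsensusResult-class] with `chosenK == 2`.
#' @param x the expression matrix the clustering was run on.
#' @param markerGenes character; marker gene identifiers (rows of `x`).
#' @param markerDirection `"high"` (default) if high marker expression
#'   defines IBD1, `"low"` otherwise.
#' @return named factor of `"IBD1"`/`"IBD2"` labels, one per sample.
#' @export
assignSubgroupNames <- function(result, x, markerGenes,
                                markerDirection = c("high", "low")) {
  markerDirection <- match.arg(markerDirection)
  if (chosenK(result) != 2L)
    stop("subgroup naming requires exactly two clusters (chosen k = ",
         chosenK(result), ")")
  m <- .asExprMatrix(x)
  missing <- setdiff(markerGenes, rownames(m))
  if (length(missing))
    stop("marker genes absent from matrix: ", paste(missing, collapse = ", "))
  lab <- subgroupLabels(result)
  mu <- vapply(1:2, function(g)
    mean(m[markerGenes, lab == g, drop = FALSE]), numeric(1))
  if (markerDirection == "low") mu <- -mu
  ibd1 <- if (mu[1] == mu[2]) lab[[1L]] else which.max(mu)
  out <- factor(ifelse(lab == ibd1, "IBD1", "IBD2"),
                levels = c("IBD1", "IBD2"))
  names(out) <- names(lab)
  out
}
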