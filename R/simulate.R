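#' Simulation configuration for a synthetic IBD cohort
#'
#' Bundles and validates every parameter of the synthetic-cohort generator.
#' Defaults describe the training-cohort conditions the pipeline was designed
#' around: 69 patients split 35/34 into two latent subgroups, a correlated
#' block structure among informative genes, a whole-blood signal attenuated
#' relative to CD8 T cells, and subgroup-dependent exponential escalation
#' hazards with a planted hazard ratio of 2.65.
#'
#' @param nSamples number of patients (default 69).
#' @param nGenes total genes simulated (default 500; a desk-scale stand-in
#'   for a genome-wide array).
#' @param nInformative genes carrying the subgroup effect (default 50).
#' @param nBlocks correlated blocks the informative genes are split into
#'   (default 5).
#' @param effectSize log2-units mean separation between subgroups on each
#'   informative gene in CD8 T cells (default 1).
#' @param wholeBloodAttenuation multiplier in \[0,1\] applied to `effectSize`
#'   for the whole-blood matrix (default 0.5): the subgroup signal is
#'   present but weakened in unseparated cells.
#' @param noiseSd residual SD in log2 units (default 1).
#' @param blockCor within-block equicorrelation of informative genes
#'   (default 0.7), giving the multicollinearity the penalised models must
#'   cope with.
#' @param subgroupProportion fraction of samples in the poor-prognosis
#'   subgroup IBD1 (default 35/69).
#' @param hazardRateGood escalation events per year in the good-prognosis
#'   subgroup (default 0.3).
#' @param hazardRatio hazard multiplier for the poor-prognosis subgroup
#'   (default 2.65).
#' @param censorTime administrative censoring time in years (default 3).
#' @param escalationRateGood mean escalation count within 18 months in the
#'   good-prognosis subgroup (default 0.5).
#' @param escalationRateRatio Poisson rate ratio (poor vs good) for
#'   escalation counts (default 3).
#' @param colectomyProbPoor probability of colectomy in the poor-prognosis
#'   subgroup (default 0.12; good-prognosis patients never undergo colectomy,
#'   mirroring the observed 7/56 vs 0/48 imbalance).
#' @param plateNoiseSd qPCR replicate noise SD in cycles (default 0.2).
#' @param ctSlope cycles per log2 expression unit (default 1, ideal
#'   amplification efficiency).
#' @param ctOffset Ct intercept in cycles (default 40).
#' @param seed integer RNG seed.
#' @return a validated list of class `"SimulationConfig"`.
#' @seealso [simulateCohort()]
#' @export
simConfig <- function(nSamples = 69L, nGenes = 500L, nInformative = 50L,
                      nBlocks = 5L, effectSize = 1, wholeBloodAttenuation = 0.5,
                      noiseSd = 1, blockCor = 0.7,
                      subgroupProportion = 35 / 69,
                      hazardRateGood = 0.3, hazardRatio = 2.65,
                      censorTime = 3, escalationRateGood = 0.5,
                      escalationRateRatio = 3, colectomyProbPoor = 0.12,
                      plateNoiseSd = 0.2, ctSlope = 1, ctOffset = 40,
                      seed = 1L) {
  cfg <- list(nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
              nInformative = as.integer(nInformative),
              nBlocks = as.integer(nBlocks), effectSize = effectSize,
              wholeBloodAttenuation = wholeBloodAttenuation,
              noiseSd = noiseSd, blockCor = blockCor,
              subgroupProportion = subgroupProportion,
              hazardRateGood = hazardRateGood, hazardRatio = hazardRatio,
              censorTime = censorTime,
              escalationRateGood = escalationRateGood,
              escalationRateRatio = escalationRateRatio,
              colectomyProbPoor = colectomyProbPoor,
              plateNoiseSd = plateNoiseSd, ctSlope = ctSlope,
              ctOffset = ctOffset, seed = as.integer(seed))
  for (nm in c("effectSize", "wholeBloodAttenuation", "noiseSd", "blockCor",
               "subgroupProportion", "hazardRateGood", "hazardRatio",
               "censorTime", "escalationRateGood", "escalationRateRatio",
               "colectomyProbPoor", "plateNoiseSd", "ctSlope", "ctOffset"))
    .assertScalar(cfg[[nm]], nm)
  if (cfg$nInformative > cfg$nGenes)
    stop("nInformative must not exceed nGenes")
  if (cfg$subgroupProportion <= 0 || cfg$subgroupProportion >= 1)
    stop("subgroupProportion must lie strictly in (0, 1)")
  if (cfg$hazardRatio <= 0) stop("hazardRatio must be > 0")
  if (cfg$hazardRateGood <= 0 || cfg$escalationRateGood <= 0 ||
      cfg$escalationRateRatio <= 0)
    stop("all rates must be > 0")
  if (cfg$wholeBloodAttenuation < 0 || cfg$wholeBloodAttenuation > 1)
    stop("wholeBloodAttenuation must lie in [0, 1]")
  if (cfg$blockCor < 0 || cfg$blockCor >= 1)
    stop("blockCor must lie in [0, 1)")
  if (cfg$effectSize < 0) stop("effectSize must be >= 0")
  if (cfg$censorTime < 0) stop("censorTime must be >= 0")
  class(cfg) <- "SimulationConfig"
  cfg
}

# One tissue matrix: baseline + planted subgroup shift + block-equicorrelated
# Gaussian noise. `effect` is the per-gene shift magnitude for that tissue.
.simTissue <- function(cfg, mu, labels, effect, direction, block) {
  n <- cfg$nSamples
  g <- cfg$nGenes
  m <- matrix(rnorm(g * n, sd = sqrt(1 - ifelse(block > 0, cfg$blockCor, 0))),
              nrow = g)
  if (cfg$nBlocks > 0 && cfg$blockCor > 0) {
    fac <- matrix(rnorm(cfg$nBlocks * n), nrow = cfg$nBlocks)
    inBlock <- which(block > 0)
    m[inBlock, ] <- m[inBlock, , drop = FALSE] +
      sqrt(cfg$blockCor) * fac[block[inBlock], , drop = FALSE]
  }
  m <- mu + cfg$noiseSd * m
  if (effect != 0) {
    shift <- direction * effect
    poor <- labels == "IBD1"
    m[, poor] <- m[, poor, drop = FALSE] + shift
  }
  m
}

#' Simulate a complete synthetic cohort
#'
#' Generates CD8 T cell and whole-blood log2 expression matrices with a
#' planted two-subgroup structure, a triplicate qPCR Ct table for the
#' informative-plus-reference panel, and clinical follow-up with
#' subgroup-dependent escalation hazards. The two subgroup sizes are exact
#' (`round(nSamples * subgroupProportion)` in IBD1), sample membership is
#' randomly permuted. Informative genes are shifted by `effectSize`
#' (alternating sign) in IBD1 and organised into equicorrelated blocks; the
#' whole-blood matrix carries the same planted effects scaled by
#' `wholeBloodAttenuation`. Three near-constant reference genes (REF1-REF3)
#' are appended to both matrices. Fully deterministic for a fixed
#' `config$seed`.
#'
#' @param config a [simConfig()] object.
#' @return a [SyntheticCohort-class].
#' @examples
#' coh <- simulateCohort(simConfig(seed = 7))
#' table(trueLabels(coh))
#' @export
simulateCohort <- function(config) {
  if (!inherits(config, "SimulationConfig"))
    config <- do.call(simConfig, config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$nSamples
  sampleIds <- sprintf("S%03d", seq_len(n))
  geneIds <- sprintf("G%03d", seq_len(cfg$nGenes))

  n1 <- round(n * cfg$subgroupProportion)
  if (n1 < 1 || n1 > n - 1)
    stop("subgroupProportion leaves an empty subgroup at this nSamples")
  labels <- factor(rep("IBD2", n), levels = c("IBD1", "IBD2"))
  labels[sample.int(n, n1)] <- "IBD1"
  names(labels) <- sampleIds

  mu <- runif(cfg$nGenes, 6, 10)
  informative <- seq_len(cfg$nInformative)
  direction <- numeric(cfg$nGenes)
  direction[informative] <- rep_len(c(1, -1), cfg$nInformative)
  block <- integer(cfg$nGenes)
  if (cfg$nInformative > 0 && cfg$nBlocks > 0)
    block[informative] <- rep_len(seq_len(cfg$nBlocks), cfg$nInformative)

  cd8 <- .simTissue(cfg, mu, labels, cfg$effectSize, direction, block)
  wb <- .simTissue(cfg, mu, labels,
                   cfg$effectSize * cfg$wholeBloodAttenuation,
                   direction, block)
  dimnames(cd8) <- dimnames(wb) <- list(geneIds, sampleIds)

  refIds <- c("REF1", "REF2", "REF3")
  refCd8 <- matrix(8 + rnorm(3 * n, sd = 0.05), nrow = 3,
                   dimnames = list(refIds, sampleIds))
  refWb <- matrix(8 + rnorm(3 * n, sd = 0.05), nrow = 3,
                  dimnames = list(refIds, sampleIds))
  cd8 <- rbind(cd8, refCd8)
  wb <- rbind(wb, refWb)

  rowDf <- S4Vectors::DataFrame(
    gene_id = rownames(cd8),
    informative = rownames(cd8) %in% geneIds[informative],
    block = c(block, 0L, 0L, 0L),
    direction = c(direction, 0, 0, 0))
  colDf <- S4Vectors::DataFrame(sample_id = sampleIds, true_label = labels)
  cd8Se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = cd8), rowData = rowDf, colData = colDf)
  wbSe <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = wb), rowData = rowDf, colData = colDf)

  ct <- simulateQpcr(wbSe, panel = geneIds[informative],
                     referenceGenes = refIds,
                     plateNoiseSd = cfg$plateNoiseSd,
                     slope = cfg$ctSlope, offset = cfg$ctOffset)
  clinical <- simulateEscalations(labels, cfg)

  new("SyntheticCohort", cd8 = cd8Se, wholeBlood = wbSe, ctTable = ct,
      clinical = clinical, trueLabels = labels,
      config = c(unclass(cfg),
                 list(informativeGenes = geneIds[informative],
                      referenceGenes = refIds)))
}

#' Simulate clinical follow-up with subgroup-dependent escalation hazards
#'
#' Time to first treatment escalation is exponential with rate
#' `hazardRateGood` in the good-prognosis subgroup and
#' `hazardRateGood * hazardRatio` in the poor-prognosis subgroup,
#' administratively censored at `censorTime` years. Escalation counts within
#' the first 18 months are Poisson with rate ratio `escalationRateRatio`.
#' The maximum therapy tier is derived from the escalation count (none <
#' immunomodulator < anti-TNFa < second-line biological < surgery/colectomy),
#' and colectomy occurs only in the poor-prognosis subgroup.
#'
#' @param labels two-level factor of subgroup membership (optionally named
#'   by sample identifier).
#' @param config a [simConfig()] object supplying the rates.
#' @param poorLevel the label level carrying the elevated hazard
#'   (default `"IBD1"`, falling back to the first level if absent).
#' @param seed optional integer; if given, seeds the RNG (when called from
#'   [simulateCohort()] the surrounding stream is used unchanged).
#' @return data.frame with columns `sample_id`, `time_years`, `event`,
#'   `n_escalations_18m`, `therapy_tier`, `colectomy`, `followup_years`.
#' @export
simulateEscalations <- function(labels, config, poorLevel = "IBD1",
                                seed = NULL) {
  if (length(labels) == 0) stop("label vector must be non-empty")
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("labels must have exactly two levels")
  if (!poorLevel %in% levels(labels)) poorLevel <- levels(labels)[1L]
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  n <- length(labels)
  poor <- labels == poorLevel
  rate <- ifelse(poor, cfg$hazardRateGood * cfg$hazardRatio, cfg$hazardRateGood)
  t <- rexp(n, rate)
  event <- as.integer(t <= cfg$censorTime)
  timeYears <- pmin(t, cfg$censorTime)
  mu <- ifelse(poor, cfg$escalationRateGood * cfg$escalationRateRatio,
               cfg$escalationRateGood)
  nEsc <- rpois(n, mu)
  colectomy <- as.integer(poor & rbinom(n, 1L, cfg$colectomyProbPoor) == 1L)
  tiers <- c("none", "immunomodulator", "anti-TNFa",
             "second-line biological", "surgery/colectomy")
  tierIdx <- pmin(nEsc, 3L) + 1L
  tierIdx[colectomy == 1L] <- 5L
  ids <- names(labels)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  data.frame(sample_id = ids, time_years = timeYears, event = event,
             n_escalations_18m = nEsc,
             therapy_tier = factor(tiers[tierIdx], levels = tiers,
                                   ordered = TRUE),
             colectomy = colectomy, followup_years = cfg$censorTime,
             stringsAsFactors = FALSE)
}

#' Simulate a triplicate qPCR Ct table from log2 expression
#'
#' Instrument model: `Ct = offset - slope * log2(expression) + noise`, three
#' technical replicates per sample x gene. Doubling a gene's linear
#' expression therefore lowers its expected Ct by `slope` cycles. Reference
#' genes must be present in the matrix; the cohort generator provides them
#' with near-constant expression.
#'
#' @param expression genes x samples log2 matrix or SummarizedExperiment.
#' @param panel character; informative genes to measure (must be rows of
#'   `expression`).
#' @param referenceGenes character; reference genes to measure (must also be
#'   rows of `expression`).
#' @param plateNoiseSd replicate noise SD in cycles (default 0.2).
#' @param slope cycles per log2 unit (default 1).
#' @param offset Ct at zero log2 expression (default 40).
#' @param seed optional integer RNG seed.
#' @return long-format data.frame `sample_id`, `gene`, `replicate`, `ct`.
#' @export
simulateQpcr <- function(expression, panel, referenceGenes = character(),
                         plateNoiseSd = 0.2, slope = 1, offset = 40,
                         seed = NULL) {
  m <- .asExprMatrix(expression)
  genes <- unique(c(panel, referenceGenes))
  missing <- setdiff(genes, rownames(m))
  if (length(missing))
    stop("panel genes absent from expression matrix: ",
         paste(missing, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  nS <- ncol(m)
  nG <- length(genes)
  meanCt <- offset - slope * m[genes, , drop = FALSE]
  out <- data.frame(
    sample_id = rep(rep(colnames(m), each = nG), times = 3L),
    gene = rep(rep(genes, times = nS), times = 3L),
    replicate = rep(1:3, each = nG * nS),
    ct = rep(as.vector(meanCt), times = 3L) +
      rnorm(3L * nG * nS, sd = plateNoiseSd),
    stringsAsFactors = FALSE)
  out[order(out$sample_id, out$gene, out$replicate), , drop = FALSE]
}

#' Write a synthetic cohort to plain-text files
#'
#' Exports the standard on-disk dialects: expression as TSV (first column
#' `gene_id`, one column per sample), the clinical table and the long-format
#' Ct table as CSV.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- file.path(dir, c("cd8.tsv", "wholeblood.tsv", "clinical.csv",
                            "ct.csv"))
  writeExpressionTsv(cd8Expression(cohort), files[1])
  writeExpressionTsv(wholeBloodExpression(cohort), files[2])
  write.csv(clinicalCourse(cohort), files[3], row.names = FALSE)
  write.csv(ctTable(cohort), files[4], row.names = FALSE)
  invisible(files)
}
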