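#' Kaplan-Meier product-limit estimate
#'
#' Thin, audited interface over [survival::survfit()]: censored samples
#' reduce the risk set without dropping the curve, and with no censoring the
#' estimate equals the complement of the empirical CDF.
#'
#' @param times non-negative event/censoring times.
#' @param events 0/1 event indicators.
#' @return data.frame step function: `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
#' @importFrom survival Surv survfit survdiff coxph
kaplanMeier <- function(times, events) {
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (any(times < 0)) stop("negative time")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank statistic via
#' [survival::survdiff()], p from the chi-square upper tail.
#'
#' @param times,events as in [kaplanMeier()].
#' @param groups two-level grouping vector, each level nonempty.
#' @return list with `chi2` and `p`.
#' @export
logrankTest <- function(times, events, groups) {
  g <- droplevels(as.factor(groups))
  if (nlevels(g) != 2L) stop("exactly two nonempty groups required")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  list(chi2 = unname(sd$chisq), p = pchisq(sd$chisq, df = 1L,
                                           lower.tail = FALSE))
}

#' Hazard ratio for a binary group indicator
#'
#' Cox proportional-hazards fit with a single binary covariate
#' ([survival::coxph()], Efron tie handling), returning the hazard ratio of
#' the second level versus the first with a Wald 95\% CI on the log scale.
#'
#' @param times,events as in [kaplanMeier()].
#' @param groups binary covariate (0/1 or two-level factor).
#' @return list `hr`, `ciLow`, `ciHigh`, `p`, `logHr`, `se`.
#' @export
coxHr <- function(times, events, groups) {
  g <- droplevels(as.factor(groups))
  if (nlevels(g) != 2L) stop("binary group indicator required")
  if (sum(events) < 1) stop("no events observed")
  if (any(tapply(events, g, sum) < 1))
    stop("each group must contain at least one event")
  fit <- survival::coxph(survival::Surv(times, events) ~ g,
                         ties = "efron")
  b <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  z <- b / se
  list(hr = exp(b), ciLow = exp(b - 1.959963984540054 * se),
       ciHigh = exp(b + 1.959963984540054 * se),
       p = 2 * stats::pnorm(-abs(z)), logHr = b, se = se)
}

#' Confusion matrix for multiple escalations within a horizon
#'
#' Positive call = `labelHi`; condition = at least `minEscalations`
#' escalations within the horizon. Samples are evaluable if their follow-up
#' reaches the horizon or they already met the condition; others are
#' excluded and counted. Proportions are exact ratios of counts; an
#' undefined proportion (zero denominator) is reported as `NaN`.
#'
#' @param calls data.frame with `sample_id`, `label` (e.g. from
#'   [classifySample()]).
#' @param clinical clinical follow-up table (see [simulateEscalations()]).
#' @param horizon years (default 1.5, i.e. 18 months).
#' @param minEscalations count defining the condition (default 2).
#' @param labelHi positive-call label (default "IBDhi").
#' @return list with counts `tp`, `fp`, `tn`, `fn`, `nEvaluable`,
#'   `nExcluded`, and proportions `sensitivity`, `specificity`, `ppv`,
#'   `npv`.
#' @export
confusionAtHorizon <- function(calls, clinical, horizon = 1.5,
                               minEscalations = 2L, labelHi = "IBDhi") {
  d <- merge(calls[, c("sample_id", "label")], clinical, by = "sample_id")
  cond <- d$n_escalations_18m >= minEscalations
  evaluable <- d$followup_years >= horizon | cond
  nExcl <- sum(!evaluable)
  d <- d[evaluable, , drop = FALSE]
  cond <- cond[evaluable]
  if (nrow(d) == 0) stop("no evaluable samples at this horizon")
  pos <- d$label == labelHi
  tp <- sum(pos & cond); fp <- sum(pos & !cond)
  fn <- sum(!pos & cond); tn <- sum(!pos & !cond)
  div <- function(a, b) if (b == 0) NaN else a / b
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       nEvaluable = nrow(d), nExcluded = nExcl,
       sensitivity = div(tp, tp + fn), specificity = div(tn, tn + fp),
       ppv = div(tp, tp + fp), npv = div(tn, tn + fn))
}

#' Relative risk of an outcome between two groups
#'
#' `rr = (a/n1) / (b/n2)` with a 95\% CI from the log-RR normal
#' approximation. When `b = 0` the RR is infinite and the CI undefined
#' (`flagged = TRUE`).
#'
#' @param a,n1 events and size in the index group.
#' @param b,n2 events and size in the comparator group.
#' @return list `rr`, `ciLow`, `ciHigh`, `flagged`.
#' @examples
#' relativeRisk(12, 33, 4, 33)$rr  # 3.0
#' @export
relativeRisk <- function(a, n1, b, n2) {
  if (n1 <= 0 || n2 <= 0 || a < 0 || b < 0 || a > n1 || b > n2)
    stop("invalid counts")
  if (b == 0)
    return(list(rr = Inf, ciLow = NA_real_, ciHigh = NA_real_,
                flagged = TRUE))
  rr <- (a / n1) / (b / n2)
  if (a == 0)
    return(list(rr = 0, ciLow = NA_real_, ciHigh = NA_real_, flagged = TRUE))
  se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n2)
  z <- 1.959963984540054
  list(rr = rr, ciLow = exp(log(rr) - z * se), ciHigh = exp(log(rr) + z * se),
       flagged = FALSE)
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Sum of hypergeometric probabilities, over all tables with the observed
#' margins, whose probability does not exceed the observed table's
#' ([stats::fisher.test()]).
#'
#' @param a,b,c,d non-negative integer cells (first row a, b; second row c,
#'   d).
#' @return two-tailed p-value.
#' @examples
#' fisherExact2x2(7, 49, 0, 48)  # ~0.014
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if ((a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0))
    stop("empty margin")
  fisher.test(matrix(cells, 2L, byrow = TRUE))$p.value
}

#' Mann-Whitney U test
#'
#' Wilcoxon rank-sum comparison of two samples ([stats::wilcox.test()]):
#' exact enumeration when `n1 * n2 <= 400` and the data are tie-free,
#' otherwise the tie-corrected normal approximation. The returned `U` counts
#' pairs `(x_i, y_j)` with `x_i > y_j` (plus half-ties).
#'
#' @param x,y nonempty numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list `U`, `p`.
#' @export
mannWhitney <- function(x, y,
                        alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) * length(y) <= 400) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}
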