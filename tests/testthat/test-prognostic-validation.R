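test_that("Kaplan-Meier matches the hand product-limit computation", {
  # times 1+ (censored), 2, 2, 3+ : S(2) = 1 * (1 - 2/3) = 1/3
  km <- kaplanMeier(c(1, 2, 2, 3), c(0, 1, 1, 0))
  expect_equal(km$survival[km$time == 2], 1 / 3)
  expect_equal(km$survival[km$time == 3], 1 / 3)  # flat thereafter

  # no events: survival stays at 1
  km0 <- kaplanMeier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$survival == 1))

  # all events, distinct times: complement of the empirical CDF
  t <- c(5, 1, 3, 2, 4)
  km1 <- kaplanMeier(t, rep(1, 5))
  expect_equal(km1$survival, 1 - ecdf(t)(km1$time))

  expect_error(kaplanMeier(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank behaves on exchangeable data and matches a permutation null", {
  t <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
  e <- rep(1, 10)
  g <- rep(c("a", "b"), each = 5)
  res <- logrankTest(t, e, g)
  expect_lt(res$chi2, 1e-10)
  expect_gt(res$p, 0.999)
  # invariant to relabelling the groups
  res2 <- logrankTest(t, e, ifelse(g == "a", "b", "a"))
  expect_equal(res$chi2, res2$chi2, tolerance = 1e-12)

  # Monte-Carlo permutation oracle on a small all-events dataset
  set.seed(31)
  tt <- c(rexp(10, 1), rexp(10, 2))
  ee <- rep(1, 20)
  gg <- rep(0:1, each = 10)
  obs <- logrankTest(tt, ee, gg)
  set.seed(1031)
  permChi <- replicate(6000, logrankTest(tt, ee, sample(gg))$chi2)
  expect_lt(abs(mean(permChi >= obs$chi2) - obs$p), 0.02)

  expect_error(logrankTest(tt, ee, rep(1, 20)), "two")
})

test_that("log-rank power against a planted hazard ratio of 3", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    t1 <- rexp(500, 0.3); t2 <- rexp(500, 0.9)
    tm <- pmin(c(t1, t2), 3)
    ev <- as.integer(c(t1, t2) <= 3)
    logrankTest(tm, ev, rep(0:1, each = 500))$p < 0.001
  }, logical(1))
  expect_gte(sum(hits), 19L)
})

test_that("Cox HR matches a direct partial-likelihood oracle and is symmetric", {
  set.seed(7)
  for (i in 1:3) {
    n <- 30
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.3 * exp(0.9 * x))
    ev <- as.integer(t < quantile(t, 0.8))
    tm <- pmin(t, quantile(t, 0.8))
    if (min(tapply(ev, x, sum)) < 1) next
    fit <- coxHr(tm, ev, x)
    # independent oracle: numerically maximise the Efron partial likelihood
    opt <- optimize(function(b) -efronLogPartialLik(b, tm, ev, x), c(-5, 5),
                    tol = 1e-10)
    expect_equal(fit$logHr, opt$minimum, tolerance = 1e-6)
    expect_equal(efronLogPartialLik(fit$logHr, tm, ev, x), -opt$objective,
                 tolerance = 1e-8)
    # swapping the groups inverts the hazard ratio
    swap <- coxHr(tm, ev, 1 - x)
    expect_equal(swap$hr, 1 / fit$hr, tolerance = 1e-8)
  }
  expect_error(coxHr(c(1, 2), c(0, 0), c(0, 1)), "events")
})

test_that("Cox HR is near 1 under identical hazards", {
  set.seed(12)
  t <- rexp(4000, 0.4)
  tm <- pmin(t, 3); ev <- as.integer(t <= 3)
  fit <- coxHr(tm, ev, rep(0:1, 2000))
  expect_gt(fit$hr, 0.8)
  expect_lt(fit$hr, 1.25)
  expect_true(fit$ciLow <= fit$hr && fit$hr <= fit$ciHigh)
})

test_that("horizon confusion matrix handles oracle, degenerate and planted cases", {
  clin <- data.frame(sample_id = sprintf("s%02d", 1:8),
                     time_years = 1, event = 1,
                     n_escalations_18m = c(2, 3, 2, 2, 0, 1, 0, 0),
                     therapy_tier = "none", colectomy = 0,
                     followup_years = 2)
  oracleCalls <- data.frame(sample_id = clin$sample_id,
                            label = ifelse(clin$n_escalations_18m >= 2,
                                           "IBDhi", "IBDlo"))
  cm <- confusionAtHorizon(oracleCalls, clin)
  expect_identical(c(cm$sensitivity, cm$specificity), c(1, 1))
  expect_identical(cm$nExcluded, 0L)

  allHi <- data.frame(sample_id = clin$sample_id, label = "IBDhi")
  cm2 <- confusionAtHorizon(allHi, clin)
  expect_identical(cm2$sensitivity, 1)
  expect_identical(cm2$specificity, 0)
  expect_true(is.nan(cm2$npv))  # zero-denominator note

  # samples censored before the horizon without qualifying events drop out
  clin$followup_years[5] <- 1
  cm3 <- confusionAtHorizon(oracleCalls, clin)
  expect_identical(cm3$nExcluded, 1L)
  expect_identical(cm3$nEvaluable, 7L)

  # planted Bernoulli rates: analytic sensitivity and NPV within 0.05
  set.seed(9)
  n <- 400
  hi <- rep(c(TRUE, FALSE), each = n / 2)
  cond <- rbinom(n, 1, ifelse(hi, 0.7, 0.1))
  clin4 <- data.frame(sample_id = sprintf("p%03d", 1:n), time_years = 1,
                      event = 1, n_escalations_18m = 2L * cond,
                      therapy_tier = "none", colectomy = 0,
                      followup_years = 2)
  calls4 <- data.frame(sample_id = clin4$sample_id,
                       label = ifelse(hi, "IBDhi", "IBDlo"))
  cm4 <- confusionAtHorizon(calls4, clin4)
  sensTrue <- 0.7 / (0.7 + 0.1)   # P(hi | cond) with equal group sizes
  npvTrue <- 0.9                  # P(!cond | lo)
  expect_lt(abs(cm4$sensitivity - sensTrue), 0.05)
  expect_lt(abs(cm4$npv - npvTrue), 0.05)
})

test_that("relative risk reproduces the reported cohort contrasts exactly", {
  expect_equal(relativeRisk(12, 33, 4, 33)$rr, 3.0)
  expect_equal(round(relativeRisk(8, 33, 15, 33)$rr, 2), 0.53)
  expect_equal(round(relativeRisk(7, 24, 2, 28)$rr, 2), 4.08)
  # reciprocal identity when both finite
  f <- relativeRisk(12, 33, 4, 33); g <- relativeRisk(4, 33, 12, 33)
  expect_equal(f$rr * g$rr, 1)
  expect_true(f$ciLow <= f$rr && f$rr <= f$ciHigh)
  # zero comparator events: infinite RR, flagged, CI undefined
  z <- relativeRisk(5, 10, 0, 10)
  expect_identical(z$rr, Inf)
  expect_true(z$flagged && is.na(z$ciLow))
  expect_error(relativeRisk(5, 0, 1, 10), "counts")
})

test_that("Fisher's exact test matches enumeration and the colectomy table", {
  expect_equal(round(fisherExact2x2(7, 49, 0, 48), 2), 0.01)
  expect_equal(fisherExact2x2(5, 5, 5, 5), 1)

  # exhaustive enumeration oracle over all tables with the observed margins
  enumFisher <- function(a, b, c, d) {
    m <- a + c; nn <- b + d; k <- a + b
    lo <- max(0, k - nn); hi <- min(k, m)
    probs <- dhyper(lo:hi, m, nn, k)
    pObs <- dhyper(a, m, nn, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
  }
  set.seed(13)
  for (i in 1:25) {
    tb <- rpois(4, 4)
    if ((tb[1] + tb[2]) == 0 || (tb[3] + tb[4]) == 0 ||
        (tb[1] + tb[3]) == 0 || (tb[2] + tb[4]) == 0) next
    expect_equal(fisherExact2x2(tb[1], tb[2], tb[3], tb[4]),
                 enumFisher(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-12)
  }
  expect_error(fisherExact2x2(0, 0, 1, 2), "margin")
  expect_error(fisherExact2x2(-1, 2, 3, 4), "integers")
})

test_that("Mann-Whitney matches exact enumeration and edge identities", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.4, 2.9)
  y <- c(2.0, 4.4, 6.1, 0.9, 3.3, 5.5, 7.2)
  res <- mannWhitney(x, y, alternative = "less")
  # enumeration over all C(13,6) label assignments
  pool <- c(x, y)
  combs <- combn(13, 6)
  uAll <- apply(combs, 2, function(idx) {
    xs <- pool[idx]; ys <- pool[-idx]
    sum(outer(xs, ys, ">"))
  })
  expect_equal(res$U, sum(outer(x, y, ">")))
  expect_equal(res$p, mean(uAll <= res$U), tolerance = 1e-12)

  # identical multisets: central U, two-sided p near 1
  idres <- mannWhitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(idres$U, 8)  # n1*n2/2
  expect_gt(idres$p, 0.95)

  # complete separation: U = 0
  expect_identical(mannWhitney(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_error(mannWhitney(numeric(0), 1:3), "nonempty")
})
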