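---
title: "Methods: whole-blood prognostic classifier development in ibdProg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-blood prognostic classifier development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`ibdProg` implements a complete prognostic-biomarker development pipeline
for inflammatory bowel disease: discovery of two patient subgroups from CD8
T cell expression, supervised translation of subgroup membership to whole
blood with a sparse penalised classifier, conversion of that signature into
a locked qPCR assay, and survival-based validation. This vignette explains
each model, its assumptions, the tunable parameters, and the design
decisions taken where the procedure admitted genuinely open choices.

# The synthetic cohort generator

No patient-level data are distributed, so every stage is exercised on
synthetic cohorts whose statistical structure matches what the analysis
assumes (`simConfig()` / `simulateCohort()`).

**Expression model.** Gaussian on the log2 scale. Gene g in sample i:

$$x_{gi} = \mu_g + \delta_g\,e\,[i \in \mathrm{IBD1}]
  + \sigma\left(\sqrt{\rho}\, f_{b(g),i} + \sqrt{1-\rho}\,\varepsilon_{gi}\right)$$

with baselines $\mu_g \sim U(6,10)$, per-gene effect direction
$\delta_g \in \{+1,-1\}$ (alternating), effect size $e$ (log2 units,
default 1), noise SD $\sigma$ (default 1), and block factors $f$ giving
within-block equicorrelation $\rho$ (default 0.7) among the informative
genes. The generating model is the simplest structure exhibiting the
multicollinearity the penalised models must handle: co-regulated genes are
strongly correlated, so a good sparse classifier should pick few
representatives per block. The whole-blood matrix uses the same planted
effects multiplied by an attenuation factor in [0,1] (default 0.5): the
subgroup signal survives in unseparated cells but is too weak for
unsupervised detection, which is precisely why the whole-blood stage is
supervised. How much weaker the real whole-blood signal is than the CD8
signal is not quantifiable from published information; attenuation is a
free parameter, not an estimate.

**Cohort composition.** Defaults mirror the training-cohort conditions the
pipeline targets: 69 samples with 35 assigned to the poor-prognosis
subgroup (IBD1). Subgroup sizes are exact — `round(n * proportion)` with a
random permutation of memberships — because the reference configuration is
a fixed 35/34 split; the empirical fraction therefore converges to the
configured proportion trivially (within 1/(2n)). 500 genes with 50
informative in 5 blocks is the desk-scale stand-in for a genome-wide array;
tests and the acceptance script state these sizes explicitly wherever they
are used.

**qPCR instrument model.** Ct = offset − slope · log2(expression) + noise,
three technical replicates per sample × gene (`simulateQpcr()`). Slope
defaults to 1 cycle per doubling (ideal amplification efficiency) and the
offset to 40 cycles, so a doubling of linear expression lowers Ct by
exactly one cycle. Three reference genes (REF1–REF3) with near-constant
expression (SD 0.05 log2 units) are appended to both expression matrices.
Replicate noise defaults to 0.2 cycles.

**Clinical course.** Time to first treatment escalation is exponential:
rate `hazardRateGood` (default 0.3/year) for IBD2 and `hazardRateGood *
hazardRatio` (default ratio 2.65) for IBD1, administratively censored at
`censorTime` (default 3 years). Escalation counts within 18 months are
Poisson with rate ratio `escalationRateRatio` (default 3) and good-arm
mean `escalationRateGood` (default 0.5, the one rate the reference
conditions leave unstated; 0.5 yields the mostly-0/1-escalation pattern
typical of indolent disease). Poisson rather than negative binomial keeps a
closed-form oracle; overdispersion is left as an extension hook. The
maximum therapy tier is a deterministic function of the escalation count
(none < immunomodulator < anti-TNFα < second-line biological <
surgery/colectomy) and colectomy occurs only in the poor-prognosis arm
(probability 0.12), mirroring the observed one-sided colectomy imbalance.

**What the generator does not emulate:** microarray batch and scanner
effects, RNA degradation, multi-centre heterogeneity, amplification
inefficiency, informative censoring. Passing tests demonstrate that the
*procedure* recovers planted structure under its own assumptions; they are
not evidence about robustness to those real-data artefacts.

# Subgroup discovery

`consensusCluster()` is Monti-style consensus clustering: `nResamples`
(default 250, minimum 50) subsamples of a fraction `subsampleFraction`
(default 0.8) of samples are drawn without replacement; the base clustering
(k-means, 5 random starts, on the `topVarGenes` most-variable genes) is run
for each k in `kRange` (default 2–6); the consensus entry for a sample pair
is #co-clustered / #co-sampled. A pair never co-sampled leaves the entry
undefined and raises an error asking for more resamples. k is chosen by
minimising PAC — the proportion of consensus entries in the ambiguity
window (0.1, 0.9) — with ties to the smaller k. Final labels come from
average-linkage hierarchical clustering of 1 − consensus cut at the chosen
k, the standard recommendation, rather than from any single base run. The
orientation of the two clusters (`assignSubgroupNames()`) uses a marker
gene set: the cluster with the higher mean marker expression is IBD1, an
exact tie falling deterministically to the cluster containing the first
sample. In `runPipeline()` the planted up-regulated genes stand in for the
biological marker knowledge a real analysis would use.

The exact algorithm, k-selection statistic and gene pre-filter used in the
original analyses are not recoverable from published text; the defaults
above are stated choices, all exposed in the function signature, and a run
is fully reproducible from (data, configuration, seed).

# The adaptive Elastic-Net classifier

`fitElasticNetLogistic()` minimises

$$-\tfrac{1}{n}\,\ell(\beta_0,\beta) + \lambda_1 \sum_j w_j |\beta_j|
  + \tfrac{\lambda_2}{2} \sum_j \beta_j^2$$

with the intercept unpenalised. The solver is cyclic coordinate descent on
a quadratic majoriser of the logistic loss (per-coordinate curvature bound
$\frac{1}{4n}\sum_i x_{ij}^2$, since the loss is 1/4-smooth), so each
update is a majorise–minimise step and the objective is provably
non-increasing — the property the descent tests check. Convergence is
declared when the relative objective change over a sweep falls below 1e-8
(at most 1e5 sweeps); with $\lambda_2 > 0$ the problem is strictly convex
and the optimum unique. Classes are coded {0,1}; coefficients start at
zero and the intercept at the prevalence logit. An active-set schedule
(full sweep, then iteration on the nonzero set) and warm starts down each
$\lambda_1$ path keep grid fitting fast. glmnet — an independent solver for
the same objective after penalty reparameterisation — serves as the
cross-check oracle in the test suite, never as the implementation.

**Two stages.** Stage 1 fits the classic Elastic-Net ($w \equiv 1$);
stage 2 re-weights the L1 term with $w_j = (|\hat\beta_j| + 1/n)^{-\gamma}$
from the stage-1 coefficients, the adaptive weighting of the original
method with a 1/n guard that keeps weights finite at zero coefficients.
$\gamma = 0$ recovers the classic fit exactly.

**The grid.** Only the total number of candidate models (2100) is anchored
by the reference procedure; its factorisation is a design choice. The
default is 70 $\lambda_1$ values log-spaced from the smallest
all-zero-coefficients penalty down to 1e-3 of it, 10 $\lambda_2$ values
log-spaced over [1e-3, 10], and $\gamma \in \{0.5, 1, 2\}$.

**BIC and its convention.** The printed selection formula in the source
procedure reads "−ln(L̂) − k·ln(n), highest best", which cannot be
reconciled with the standard definition — read literally, a worse fit and
fewer genes *raise* the score, so it rewards exactly the wrong things
through the likelihood term's sign. `bicScore()` therefore defaults to the
standard criterion −2ℓ + k·ln(n), minimised, with the literal variant
available behind `convention = "paper-literal"` for auditability.
`selectBestModel()` consumes the convention consistently and breaks ties by
smaller k, then larger $\lambda_1$. Which exact criterion ranked the
original 2100 models is unknowable; both are implemented and tested.

# Generalisation error

`nestedLoocv()` repeats the *entire* pipeline inside every fold:
standardisation parameters, the full grid, and BIC selection are re-derived
from the n−1 training samples, and the held-out sample is transformed with
the training fold's centre/scale before scoring at the 0.5 threshold (the
same cut-off the final classifier uses). The leakage test mutates a
held-out sample's features and asserts that no training-fold artefact
changes. The 95% CI is Clopper–Pearson exact — consistent with the shape of
reported intervals at n = 69 — and the dummy-classifier comparison is a
one-sided exact binomial tail at p₀ = 0.5 (class prevalence available as an
option).

A note on the permuted-label null: with an exactly balanced cohort,
leave-one-out folds of an intercept-only model always predict the training
majority, which is the *opposite* of the held-out class — the well-known
anti-learning bias of LOOCV with majority-rule predictors. The null
calibration therefore permutes a slightly imbalanced 21/19 label vector
(mirroring the 35/34 cohort), for which the procedure's null accuracy sits
near 0.5, and the acceptance check compares the 20-seed mean against the
95% binomial band.

# Translation to qPCR and lock-down

**ΔΔCt quantification** (`deltaDeltaCt()`): triplicates are averaged; the
reference level per sample is the arithmetic mean of the reference genes'
mean Cts (equivalently the geometric mean of their linear quantities — the
combination rule for multiple reference genes is a stated choice);
ΔCt = target − reference; relative expression is 2^(−ΔΔCt). The calibrator
defaults to 0 (pure ΔCt) because any fixed calibrator is a per-gene
constant absorbed into downstream coefficients and intercepts. Triplicates
with replicate SD above 0.5 cycles (a stated QC bound) are flagged, and
excluded only when requested; reference-gene triplicates are never dropped
because the reference level must remain defined. ΔΔCt is invariant to
per-sample plate shifts since target and reference move together.

**Panel assembly** (`selectCandidatePanel()`): the default 39-gene panel is
quota-partitioned 12/6/21 — all nonzero genes of the optimal model, genes
with |r| ≥ 0.8 to an optimal-model gene (the "highly correlated" threshold
is a stated default), and the most frequently nonzero genes among
lower-ranked models. Shortfalls roll forward with a warning; ties break by
gene order, making the panel deterministic.

**Correlation filter** (`correlationFilter()`): Pearson r between
microarray log2 values and −ΔCt per gene; retain r ≥ 0.5 (no published
cut-off exists — 0.5 is exposed as a parameter), excluding zero-variance
genes as "undefined correlation". Raising the threshold can only remove
genes.

**Standardised refit and unscaled lock-down.** `refitOnQpcr()` applies the
identical grid + BIC machinery to standardised ΔCt features. The final
model must run on *unscaled* ΔCt (one clinical sample at a time, no cohort
statistics), so `regularizeUnscaled()` fits a cross-validated lasso path on
the unscaled features of the refit model's genes — the same engine the
reference procedure used for this step — with misclassification error,
10 stratified folds (fold count is a stated default; the source text does
not give one) derived deterministically from the seed, and selects the
most-regularised model within one standard error of the minimum CV error
(the 1-SE rule), guaranteeing it is no less sparse than the CV-minimum
model. The result is frozen into a `LockedClassifier`: genes, coefficients,
intercept, the 0.5 threshold and labels are checksummed (md5 of a canonical
serialisation), any later mutation fails validation, and the JSON
serialisation is human-readable with the checksum embedded.

**Scoring** (`classifySample()`): probability = logistic(β₀ + β·ΔCt);
calls at or exactly on 0.5 go to IBDhi — the boundary is assigned to the
high-risk side deliberately, since the conservative clinical action is
closer monitoring. A sample missing any panel gene produces a named
no-call, never a silent default.

# Prognostic validation

Standard survival machinery is delegated to the `survival` package behind
the module's interfaces: Kaplan–Meier product-limit curves, the
one-degree-of-freedom log-rank test, and Cox regression on the binary
subgroup indicator with Efron tie handling (escalation times are recorded
coarsely in practice, and Efron is the accurate default under ties), Wald
95% CIs on the log-hazard scale. Fisher's exact test, the Mann–Whitney
test (exact when n₁n₂ ≤ 400 and tie-free, tie-corrected normal otherwise)
and the exact binomial tail come from `stats`. Test oracles are
independent: hand product-limit arithmetic, Monte-Carlo permutation nulls,
direct numerical maximisation of the Efron partial likelihood, and
exhaustive hypergeometric / rank-assignment enumeration.

`confusionAtHorizon()` evaluates the 18-month multiple-escalation endpoint:
positive call = IBDhi, condition = ≥ 2 escalations within 18 months.
Samples are evaluable if follow-up reaches the horizon or the condition was
already met; others are excluded and counted explicitly — the reference
analyses do not state their evaluability rule, so exclusion-with-reporting
was chosen for auditability. Undefined proportions (zero denominators) are
reported as NaN with the zero denominator visible, never silently dropped.
`relativeRisk()` reports (a/n₁)/(b/n₂) with a log-normal CI (reference
analyses print RRs without CIs); b = 0 yields an infinite, flagged RR.

# Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use desk-scale configurations
chosen once: cohorts of 69 samples × 500 genes (50 informative) for
discovery and training checks; consensus clustering with 100 resamples over
k ∈ {2,3,4} inside multi-seed loops (250 resamples, k ∈ 2–6 remain the
single-run defaults); nested LOOCV nulls at n = 40, p = 200 with a 60-model
grid; survival recovery at 1000 patients per arm; and 20-seed end-to-end
pipeline replicates via `runPipeline()`, whose reduced analysis grid
(30 × 3 × 3) is its documented default for interactive use. Every random
step threads an explicit integer seed; identical (data, configuration,
seed) triples reproduce results bit-for-bit.

# Known limitations

* The generator's Gaussian block-equicorrelation model understates the
  heavy tails, batch structure and count nature of real expression data.
* The attenuation of the whole-blood signal is a free parameter; no
  published estimate constrains it.
* The identities and coefficients of the real, proprietary 17-gene panel
  are not public; all gene panels here are synthetic, and printed clinical
  performance figures are reference points for the *shape* of the output,
  not targets the synthetic pipeline should match numerically.
* Multivariable Cox models with clinical covariates and competing-risks
  analyses are out of scope.
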