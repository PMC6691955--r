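# ibdProg

Development and validation of a whole-blood prognostic classifier for
inflammatory bowel disease (IBD), as a tested, reusable R pipeline.

## The problem

The clinical course of Crohn's disease and ulcerative colitis varies widely:
some patients do well on first-line therapy while others need rapid
escalation to immunomodulators, biologics or surgery. Two patient subgroups
with divergent prognosis (IBD1, poor; IBD2, good) can be derived from CD8
T cell transcriptomes by consensus clustering, but a CD8-based assay is
impractical clinically. `ibdProg` implements the full translational recipe
that turns that observation into a deployable whole-blood qPCR test:

1. **Subgroup discovery** — Monti-style resampling consensus clustering
   (k-means base learner, PAC-based choice of k) of CD8 T cell expression
   (`consensusCluster()`, `assignSubgroupNames()`).
2. **Whole-blood classifier training** — logistic regression with an
   adaptive Elastic-Net penalty. For coefficients β, intercept β₀ and
   per-gene weights w:

   minimise  −ℓ(β₀, β)/n + λ₁ Σⱼ wⱼ|βⱼ| + (λ₂/2) Σⱼ βⱼ²

   Stage 1 is the classic Elastic-Net (w ≡ 1); stage 2 re-weights the L1
   term with wⱼ = (|β̂ⱼ| + 1/n)^(−γ) from the stage-1 fit. A hyperparameter
   grid (default 70 × 10 × 3 = 2100 candidate models) is scored by the
   Bayesian Information Criterion, k being the number of genes incorporated
   (`fitAdaptiveGrid()`, `bicScore()`, `selectBestModel()`). Generalisation
   error of the whole selection procedure is estimated by nested
   leave-one-out cross-validation (`nestedLoocv()`), with an exact binomial
   comparison against a dummy classifier (`binomialTestVsDummy()`).
3. **Translation to qPCR** — candidate panel assembly from the optimal and
   lower-ranked models (`selectCandidatePanel()`), ΔΔCt relative
   quantification from triplicate Ct values (`deltaDeltaCt()`),
   microarray/qPCR correlation filtering (`correlationFilter()`), refit of
   the identical penalised strategy on standardised ΔCt features
   (`refitOnQpcr()`), then cross-validated 1-SE re-regularisation on
   *unscaled* ΔCt features and checksummed lock-down
   (`regularizeUnscaled()`). Locked classifiers score new samples one at a
   time at a fixed 0.5 probability threshold (`classifySample()`), calling
   IBDhi (poor prognosis) or IBDlo.
4. **Prognostic validation** — Kaplan-Meier curves, log-rank tests, Cox
   hazard ratios (Efron ties), 18-month multiple-escalation confusion
   matrices, relative risks, Fisher's exact and Mann-Whitney tests
   (`kaplanMeier()`, `logrankTest()`, `coxHr()`, `confusionAtHorizon()`,
   `relativeRisk()`, `fisherExact2x2()`, `mannWhitney()`).

Because the underlying patient-level data are not publicly deposited, the
package ships a first-class synthetic-cohort generator (`simulateCohort()`)
that reproduces the statistical structure the analysis assumes: 69 samples
split 35/34 between latent subgroups, correlated informative gene blocks,
a whole-blood signal attenuated relative to CD8 T cells, triplicate qPCR
Ct values with stable reference genes, and subgroup-dependent exponential
escalation hazards (planted hazard ratio 2.65).

## Worked example

```r
library(ibdProg)
res <- runPipeline(simConfig(seed = 42), seed = 42)
res$classifier
#> LockedClassifier (version 1.0, locked)
#>   9 informative + 3 reference genes; threshold 0.50 (>= -> IBDhi)
#>   checksum: 2d109880f5e97cb75f5f065844b3e527
round(res$agreement, 3)
#> [1] 0.986
res$cox[c("hr", "ciLow", "ciHigh")]
#> $hr 3.04   $ciLow 1.63   $ciHigh 5.70
res$confusion[c("sensitivity", "specificity", "npv")]
#> $sensitivity 0.938   $specificity 0.604   $npv 0.970
```

The pipeline discovered the two planted subgroups by consensus clustering
(ARI 1 on this seed), trained the 2-stage adaptive Elastic-Net on whole
blood, assembled a 39-gene qPCR candidate panel, and locked a 12-gene
(9 informative + 3 reference) ΔCt classifier whose calls agree with the
planted subgroups for 98.6% of samples. On the simulated follow-up the
IBDhi group escalates treatment earlier (hazard ratio 3.04, log-rank
p = 2.6e-4) and the 18-month negative predictive value for multiple
escalations is 0.97 — the shape of result the procedure is designed to
deliver on real cohorts.

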