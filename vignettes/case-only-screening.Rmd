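---
title: "Case-only screening for gene-gene interactions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-only screening for gene-gene interactions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coscreen)
```

## The case-only estimand

For two biallelic SNPs with coded genotypes $c_1(G_1)$ and $c_2(G_2)$ and a
logistic disease model

$$\mathrm{logit}\,P(D) \;=\; \beta_0 + \beta_1 c_1 + \beta_2 c_2 +
\delta\, c_1 c_2,$$

the multiplicative interaction parameter $\delta$ can be estimated from
affected individuals alone. Among cases, the association between the two
genotypes,

$$\mathrm{logit}\,P(G_1 = 1 \mid \text{case}) \;=\; \delta_0 + \delta_1
c_2(G_2),$$

satisfies $\delta_1 \approx \delta$ provided (i) the genotypes are
independent in the source population and (ii) the disease is rare in every
genotype stratum. The case-only (CO) design trades these assumptions for a
substantial gain in power over a case-control (CC) analysis with the same
number of cases: conditioning on case status removes the variance
contribution of the control sample.

`fit_co()` fits the second model per center by maximum-likelihood logistic
regression, with the ME SNP coded dominant or recessive (the response must
be binary) and the partner SNP coded dominant or additive. Inference on
$\delta_1$ is a two-sided Wald test. No age or sex covariates are included:
in a CO regression an added covariate models interaction between that
covariate and $G_1$ rather than adjusting the target interaction, and
confounding of a genotype-genotype association by such variables would
require implausibly large allele-frequency differences for autosomal SNPs.

### Population independence and its two safeguards

Population structure, long-range LD and batch effects can correlate two
genotypes among cases without any interaction. The pipeline mitigates this
threefold:

* **Cross-arm restriction.** Only pairs on different chromosome arms are
  screened (`cross_arm_ok()`, with a bundled GRCh37 centromere gap table;
  SNPs inside a gap are flagged unplaceable and excluded).
* **Center-level PC adjustment.** `center_pcs()` computes principal
  components of the centered, unit-scaled dosage matrix per center, with
  the component sign fixed by its largest-magnitude loading so results are
  deterministic. PCA SNP sets are not LD-pruned; the choice is documented
  rather than inferred from any particular upstream pipeline.
* **Per-center fits + random-effects pooling.** Center-specific artifacts
  surface as heterogeneity rather than silently biasing a pooled fit.

A caveat demonstrated by the simulator's `pair_freq_corr` option: genuine
population-level LD between the pair inflates the CO estimate above the
true interaction OR, so a small reference-panel $r^2$ (see the LD audit
below) remains a caveat on the effect size even when large $r^2$ can be
ruled out.

PC adjustment deserves one desk-scale warning. With a genome-wide panel a
single SNP carries negligible weight in any component; with the 60-SNP
demonstration panel used in this package's tests, PC scores correlate
noticeably (|r| up to about 0.3) with individual test genotypes, and
conditioning on them biases $\delta_1$. The demonstration screens therefore
run without PCs and rely on center stratification plus meta-analysis, while
the PC machinery itself is validated on wider synthetic panels (structure
recovery at 2,000 SNPs; bias reduction in a deliberately confounded
two-subpopulation center with 400 SNPs). Passing demo runs therefore say
nothing about PC behaviour on sparse panels — by design.

## Meta-analysis and the two-stage protocol

`pool_estimates()` pools center log-ORs with DerSimonian-Laird (DL)
random-effects weights:

$$\hat\tau^2 = \max\!\left(0,\;
\frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right), \qquad
w_i = 1/\mathrm{se}_i^2,$$

with Cochran's $Q$, $I^2 = \max(0, (Q - (k-1))/Q)$, and a
normal-approximation Wald test on the pooled estimate. DL was chosen over
REML deliberately: it is closed-form and bit-reproducible, at the cost of a
potential small numerical divergence from REML-based tools on heterogeneous
inputs (the test suite cross-checks against `metafor`'s DL estimator).

Centers with unstable estimates — non-convergence within 100 IRLS
iterations, $|\hat\delta_1| > 15$ (a practical separation marker; no Firth
penalty is applied because the protocol handles instability by exclusion),
or a 95% CI wider than `ci_width_max = 4` on the log-OR scale — are removed
by `stability_filter()` before pooling, iterating to a fixed point. The
width bound is a package default: an OR whose confidence bounds differ by
a factor of $e^4 \approx 55$ carries no screening information; the
protocol it implements never quantified "large".

`two_stage_screen()` then applies the screening protocol: stage 1 pools,
per pair and model combination, only centers with a center-level $p <
0.05$; pairs reaching $p < 5\times10^{-5}$ are re-pooled over **all**
centers in stage 2; final hits must clear the genome-wide level
Bonferroni-corrected for the number of anchor (ME) SNPs,
$5\times10^{-8}/90 = 5.6\times10^{-10}$. No correction is applied for the
number of genetic-model combinations. Stage 1 is intentionally
anti-conservative (it selects favorable centers to cut compute); stage 2
removes that selection before anything is declared significant. The
stage-1 center filter is assumed to use the same model combination that is
reported — the protocol leaves this open. Independently, the 50 lowest-p
pairs per ME SNP per center are re-pooled over all centers and the 5 lowest
pooled associations per ME SNP reported; top-k ties break by
(p, |log-OR| descending, partner SNP id) for determinism.

## The synthetic cohort generator

No individual-level cohort of the kind this pipeline targets can ship with
a package, so `simulate_population()` / `sample_cases()` generate one with
every ingredient the screen must survive:

* **Structure.** Subpopulation allele frequencies drift around ancestral
  values by the Balding-Nichols model, $p_s \sim \mathrm{Beta}(p(1-F)/F,
  (1-p)(1-F)/F)$, parameterized by a single $F_{ST}$; genotypes are
  Hardy-Weinberg within subpopulation. An optional Gaussian-copula
  correlation between the pair's subpopulation frequencies plants
  population-level LD for violation experiments.
* **Disease.** Affection is drawn from the logistic model above, so cases
  arise by rejection from the population — exact, with no retrospective
  inversion. The baseline $\beta_0$ is free (the generating model of any
  real cohort is unknowable); defaults put prevalence near 2% so that
  desk-scale populations yield enough cases.
* **Artifacts.** Per-center symmetric genotype miscalls (uniform choice
  among the other two genotypes), truncated-Gaussian fractional dosages,
  and Uniform(`call_prob_floor`, 1) call probabilities emulating
  imputation output; `hard_call()` downstream applies the 0.8
  imputation-probability threshold.
* **Placement.** Synthetic SNPs receive GRCh37-style coordinates; the ME
  SNP and its planted partner sit on 12q and 12p respectively, so the
  cross-arm rule passes by default.

What the generator does **not** emulate: recombination and coalescent LD
structure along the genome, the X chromosome, relatedness/pedigrees, and
imputation-quality variation by allele frequency. Tests passing on these
cohorts validate the statistical machinery, not robustness to those
phenomena.

All randomness flows from a single seed, with fixed offsets per stage
(population, case sampling, age-at-onset), so identical configurations are
byte-identical. The demonstration configuration (`demo_sim_config()`) uses
8 centers x 700 cases, 60 SNPs, two evenly mixed subpopulations at
$F_{ST} = 0.01$ and a planted dominant-by-dominant interaction OR of 1.8 at
MAF 0.3 — sized so a full screen runs in seconds and the planted signal
clears $5.6\times10^{-10}$ when the centers are pooled. Calibration tests
use 2-SNP configurations (500 null replicates; 100 coverage replicates at
2,000 cases), and PCA validation uses up to 2,000 SNPs; these problem
sizes are the package's choices for a desk-scale test bench.

## Power: case-only versus case-control

`co_power()` computes the exact 3x3 genotype-pair distribution among cases
by Bayes' rule from HWE, locus independence and the logistic disease model
(with $\beta_0$ solved to the target prevalence), collapses it under the
interaction coding, and evaluates the Wald noncentrality of the CO log-OR
at the case sample size; power is
$P\{\chi^2_1(\lambda) > \chi^2_{1,1-\alpha}\}$. `cc_power()` does the
analogous computation for the product-term in a prospective logistic model
fitted to the expected case and control tables. `simulate_power()`
verifies both by Monte-Carlo, and the suite requires analytic and
simulated power to agree within binomial error — the analytic values are
not approximations of a different test than the one actually run.

Default settings, each exposed as a parameter:

* **Prevalence 0.005.** The CO estimator is exactly consistent only for a
  rare disease; at this baseline the residual attenuation is negligible
  relative to the effects screened for. Power falls visibly as prevalence
  grows (a sensitivity test in the suite tracks this), so the default is
  deliberately in the rare band.
* **Per-allele main effects.** The main-effect ORs enter log-additively
  for both SNPs, matching how GWAS risk SNP effects are reported.
* **Dominant interaction coding.** Carrier-versus-non-carrier is the
  binary-factor model that interaction power calculators conventionally
  assume for a gene, and it reproduces the minimum-detectable-OR
  bounds that Quanto-style calculators report for moderate-MAF scenarios
  on the same grid; the additive
  (linear-by-linear, fitted as a log-linear association model on the 3x3
  table) and recessive codings are available via `coding =`.

`min_detectable_or()` walks the interaction OR up a 0.05 grid until 80%
power is reached. One honest discrepancy deserves note: for low-MAF
scenarios (MAF 0.05, strong main effects, $\alpha = 5.6\times10^{-10}$)
the grid value found here is noticeably **smaller** than what
Quanto-style sample-size calculators report (about 2.55 rather than 2.95
at 2,000 cases). The Monte-Carlo cross-check sides with the analytic value: the
simulated power of the actual CO Wald test at the 2.55 grid point already
reaches 0.8. Classical sample-size formulas that evaluate the variance
under the null (or mix null and alternative variances) are conservative in
exactly this skewed-cell regime, and prevalence assumptions above the rare
band push in the same direction. We report what the implemented test
actually achieves rather than tuning the calculation to reproduce a
conservative approximation.

## LD audit

`em_haplotypes()` estimates two-locus haplotype frequencies from unphased
genotypes by EM over the double-heterozygote phase ambiguity, initialized
at linkage equilibrium (the biallelic two-locus likelihood is unimodal in
practice; iteration cap 1,000, log-likelihood tolerance $10^{-10}$), and
derives $D$, $D' = |D|/D_{\max}$ and $r^2 = D^2/(p_A p_a p_B p_b)$.
`weighted_ld()` forms sample-size-weighted averages across reference
populations, and `ld_window()` scans a ±1 Mb window around a focal SNP —
the audit used to argue that a pair associated among cases is *not*
associated in a reference population. Haplotype-based EM estimates are the
implemented route; block detection (Gabriel-style) is out of scope, as
pairwise LD suffices for an independence audit. One subtlety found while
testing: the often-quoted identity between the haplotype $r^2$ and the
squared Pearson correlation of dosages holds exactly only when gamete
pairing within individuals is symmetric (e.g. fully homozygous samples);
in finite random-mating samples it holds only in expectation, and the test
suite asserts the exact version on the appropriate fixture.

## Supportive statistics

`aao_interaction()` fits, per center, the linear model
$y = G_1 + G_2 + G_1{\times}G_2 + \text{sex} + PC_1 + \dots + PC_k$ for
age at onset among cases and pools the interaction coefficient with the
same DL machinery as the main screen. A frailty-type survival model with a
kinship matrix (appropriate for family cohorts with censored unaffected
carriers) is an explicit non-goal: cases all have observed onsets, so OLS
is the in-scope analysis. `direction_fisher()` averages replicates per
individual, dichotomizes the day-70-minus-day-90 expression change by
sign, and applies a two-sided Fisher exact test with probability-mass
ordering (the convention under which a 4-down-versus-3-up split yields
$p = 1/35 \approx 0.03$); a zero change is refused rather than silently
assigned a direction. `group_compare()` is a two-sided rank-sum test
(exact for 25 or fewer values without ties) — the rank-sum rather than
signed-rank variant, since the compared groups are different individuals —
and `expr_correlation()` a Pearson correlation with a t-based p-value.
None of these apply multiple-testing corrections: they are exploratory or
targeted analyses read at a nominal 0.05.

## Degenerate inputs and numerical choices

* `fit_co()`: single-class response and constant predictors are errors
  ("degenerate response"/"degenerate predictor"); separation yields a
  non-converged flag with the estimate withheld, never an exception.
  Convergence: relative deviance change $<10^{-8}$, 100 iterations.
* `pool_estimates()` requires at least one converged center;
  `stability_filter()` errors when nothing stable remains.
* Minor-allele orientation is fixed once per dataset (combined case
  sample; lexicographic tie-break), and missingness is handled
  pairwise-complete per SNP pair, not listwise.
* Margins of observed contingency tables are always recomputed from
  cells — printed totals in secondary sources can be internally
  inconsistent and are never trusted.
* The early-onset subgroup analysis re-computes PCs within the subgroup
  (the conservative reading of "center-level" PCA under subsetting).
* The imputation filter is per-genotype (dosage rounded only where the
  call probability reaches the threshold); a per-SNP INFO-score variant
  would filter whole columns and is intentionally not the default.

## Known limitations

* DL pooling with very few centers (k <= 4) estimates $\tau^2$ noisily;
  the demonstration uses 8 centers for that reason.
* The CO estimator attenuates with prevalence; all power defaults and the
  demo keep the disease in the rare band, and nothing here corrects for
  attenuation at high prevalence.
* The two-stage protocol's stage 1 is biased by construction; stage-1
  p-values must never be reported as evidence.
* Synthetic cohorts lack chromosomal LD, so the cross-arm rule is never
  stress-tested against real long-range LD here.
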