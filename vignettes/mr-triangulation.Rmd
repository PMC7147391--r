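---
title: "Triangulating arsenic-metabolism effects on DNA methylation with Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating arsenic-metabolism effects on DNA methylation with Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmamr)
```

## The scientific question

Chronic exposure to inorganic arsenic in drinking water is associated with
altered DNA methylation at hundreds of CpG sites in blood, but epigenome-wide
association studies (EWAS) of an environmental exposure cannot by themselves
establish causality: confounding by lifestyle, diet or batch structure can
produce the same associations. Arsenic metabolism efficiency offers a genetic
lever on this question. The fraction of dimethylarsinic acid among urinary
arsenic species (DMA%) measures how efficiently an individual methylates and
excretes arsenic; higher DMA% means a lower internal dose of arsenic at the
same external exposure. DMA% has well-established common genetic determinants
— two variants in the 10q24.32/*AS3MT* region (rs9527, rs11191527) and one in
*FTCD* (rs61735836) — which can serve as instrumental variables. If arsenic
truly drives the methylation changes seen in EWAS, then *genetically
predicted* metabolism efficiency should associate with those same CpGs in the
**opposite** direction to arsenic exposure, because efficient metabolizers
carry a lower internal dose.

`dmamr` implements this triangulation as a reusable, fully testable pipeline:

1. **Genetic scores** — a weighted genetically-predicted DMA% score
   (GP-DMA%) and a weight-free binary high-efficiency-carrier score;
2. **Per-CpG association models** — linear regressions of methylation
   beta-values on each metabolism-efficiency predictor under fixed covariate
   sets;
3. **Two-sample Mendelian randomization** — inverse-variance-weighted (IVW)
   and maximum-likelihood (ML) estimates combining SNP-to-DMA% weights with
   SNP-to-CpG summary statistics;
4. **Directional consistency** — each CpG coded consistent/inconsistent
   against the prior EWAS sign and tested with a one-sided exact binomial
   test;
5. **A synthetic cohort generator** with the full causal structure, so every
   downstream stage can be validated against known truth without access to
   any cohort data.

## The estimators

**GP-DMA% score.** With $X_j$ the high-efficiency allele count at SNP $j$
and $\beta_{Xj}$ its per-allele effect on DMA%, the score is the plain
weighted sum $\sum_j \beta_{Xj} X_j$ — no intercept, no standardization — so
it reads as the predicted increase in DMA% over a carrier of zero
high-efficiency alleles. The binary score is 1 only for individuals
homozygous for the high-efficiency allele at both rs9527 and rs61735836, the
two large-effect, low-minor-allele-frequency instruments; it avoids choosing
weights at all.

**Association models.** Methylation is regressed on each predictor by
homoskedastic OLS with covariate sets fixed declaratively
(`model_covariates()`): every model adjusts for age, sex, methylation batch
and smoking status (never/former/current, never as reference); combined
two-cohort analyses add a cohort indicator; measured-phenotype models (DMA%,
log-DMA; restricted to the cohort with arsenic speciation data) add BMI,
years of education and log water arsenic, and the log-DMA model additionally
adjusts for log urinary arsenic and log urinary creatinine to control
exposure level. Because minor-allele homozygotes are rare at these SNPs,
single-SNP analyses collapse them with heterozygotes (binary coding for
higher effect-allele count), and the two correlated 10q24.32 SNPs always
enter single-SNP models together.

**Two-sample MR.** For CpG $c$, instrument $j$ contributes the exposure
effect $\beta_{Xj}$ (from the weights table, playing the role of published
estimates) and the outcome effect $\beta_{Yj}$ (from this pipeline's additive
per-SNP regressions). The fixed-effect IVW estimate is

$$\hat\theta = \frac{\sum_j \beta_{Xj}\beta_{Yj}/se^2_{Yj}}
                    {\sum_j \beta^2_{Xj}/se^2_{Yj}},
  \qquad se(\hat\theta) = \Big(\sum_j \beta^2_{Xj}/se^2_{Yj}\Big)^{-1/2},$$

the precision-weighted no-intercept regression of $\beta_Y$ on $\beta_X$; it
reduces exactly to the Wald ratio $\beta_Y/\beta_X$ with one instrument. The
ML estimator maximizes the bivariate-normal likelihood
$\beta_{Xj} \sim N(\xi_j, se^2_{Xj})$,
$\beta_{Yj} \sim N(\theta \xi_j, se^2_{Yj})$ with free per-SNP exposure
effects $\xi_j$; the $\xi_j$ profile out in closed form, leaving a
one-dimensional problem solved by damped Newton iteration from the IVW start
(gradient tolerance $10^{-8}$, iteration cap 100), with the standard error
taken from the profile curvature. As $se_{Xj} \to 0$ the ML estimate
converges to IVW. With only three instruments, Egger regression is not
identified and is deliberately out of scope.

**Directional consistency.** A CpG's estimate is *consistent* with the prior
EWAS when its sign is opposite to the reported arsenic-exposure sign.
Under the chance null each CpG is consistent with probability $1/2$, so with
$k$ consistent CpGs out of $n$ the evidence for systematic consistency is
the exact upper tail $P(X \ge k)$, $X \sim \mathrm{Bin}(n, 1/2)$, computed
in survival-function form (no normal approximation — at the reported scale,
e.g. 29/41, the normal approximation visibly disagrees with the exact tail).
An estimate of exactly zero is coded inconsistent; this is conservative
under the alternative and has probability zero for continuous estimates.
The one-sided direction is fixed a priori (more consistent than chance);
the composite "equal or less" null is evaluated at its boundary $p = 1/2$,
which is standard and matches exact-test convention.

## The synthetic cohort generator

`simulate_cohort()` encodes the hypothesized causal diagram explicitly:

$$\mathrm{DMA\%} = b_0 + \textstyle\sum_j \beta_j X_j + \delta \ln U +
  \epsilon, \qquad I = \ln U - \lambda\,\mathrm{DMA\%},$$
$$\mathrm{logit}(m_c) = a_c + b_c I + \gamma_c' Z + e_c,$$

with $U$ creatinine-adjusted urinary arsenic (log-normal), $I$ the latent
internal dose, and $b_c \ne 0$ only for the causal fraction of CpGs. The
published facts the generator is calibrated to are cohort-scale anchors,
not estimates: DMA% centred near 72 with SD ≈ 8; urinary arsenic median
near 200 µg/g creatinine with log-SD 0.85; and the weak negative coupling
$\delta = -1.5$ chosen so that $\mathrm{corr}(\mathrm{DMA\%}, \ln U) \approx
\delta\,sd(\ln U)/sd(\mathrm{DMA\%}) \approx -0.16$. Smoking and cohort
membership shift both exposure and methylation, injecting the classical
confounding that genetic instruments are immune to.

Design choices worth knowing:

* **Internal dose is linear on the log scale**, $I = \ln U - \lambda
  \mathrm{DMA\%}$. The true dose-metabolism functional form is unknown; this
  form is analytically tractable (every induced covariance is closed-form)
  and monotone in both arguments. $\lambda = 0.05$ makes a 20-point DMA%
  difference equivalent to an $e^1$-fold change in exposure — large enough
  that a per-allele effect of ~4 DMA% points is detectable through the
  instruments at a few thousand samples (per-SNP z on the outcome scales as
  $b\,\lambda\,\beta_{Xj}\,sd(X_j)\sqrt{n}/\sigma$).
* **Methylation is generated on the logit scale** and inverse-logit
  transformed, guaranteeing beta-values strictly inside (0,1); noise is
  Gaussian on the logit scale ($\sigma = 0.5$), intercepts $N(0, 1.5)$ give
  a realistic spread of baseline methylation levels.
* **Causal effects on the beta-value scale are nonlinear**, so the truth
  table records both the logit-scale effect $b_c$ and the implied average
  marginal effect `true_theta` $= -\lambda b_c \overline{m(1-m)}$ of one
  DMA% point on the beta-value — the quantity the MR estimators target.
* **LD between the first two SNPs** is generated at the haplotype level
  ($D = r\sqrt{p_1q_1p_2q_2}$, with infeasible $r$ rejected along with the
  feasible bound). The real rs9527-rs11191527 LD is described only as
  "moderate"; the default `ld_r = 0.4` is this package's documented guess,
  not a published value.
* **DMA% is truncated** into (0.1, 99.9) rather than resampled; truncation
  events are counted and reported. Resampling would subtly distort the
  genotype-DMA% relationship that the MR stage relies on.
* **Reproducibility**: one master seed; each stage (genotypes, covariates,
  exposure, DMA%, methylation, EWAS table) draws from a deterministic
  substream, so identical config + seed gives bit-identical cohorts.

What the generator does **not** emulate: Illumina probe-type chemistry and
BMIQ normalization, batch distortions of the beta distribution, cell-type
composition, or the surrogate-variable structure of the discovery EWAS. A
passing test suite therefore demonstrates the statistical machinery is
correct under the stated causal model — not that real-array artefacts are
handled.

## The shipped weights file

Two-sample MR needs published SNP-to-exposure weights. The installed file
`snp_weights_synthetic.tsv` is **synthetic**: the numeric per-allele
estimates from the source genome-wide studies were not available when it was
assembled, so it contains plausible stand-ins calibrated to the same
cohort-scale anchors (maximum score $2\sum_j\beta_j = 17.4$, equal to the
reported median GP-DMA%, implying most individuals are high-efficiency
homozygotes at all three SNPs; rs11191527 the weakest instrument). Its
header flags this provenance. For simulation work, `weights_from_config()`
derives the weights actually used by the generator, mirroring the two-sample
design in which exposure-side weights come from a prior study of the same
population. Replace the file with published estimates before any real-data
use.

## Open modelling choices, resolved

* **Beta-values, not M-values**, are the regression outcome by default: the
  analysis being emulated reports slopes on the beta-value scale. The
  machinery is agnostic — any matrix can be supplied — and M-value users can
  transform upstream.
* **Natural logarithms** for water/urinary arsenic and creatinine: the
  covariate transforms are described only as "log-transformed"; the base
  affects slopes by a constant factor and p-values not at all.
* **"Log-DMA"** is interpreted as the log of the creatinine-adjusted urinary
  DMA concentration, `log(dma_pct/100 * urinary_as)`, which is why its model
  additionally adjusts for total urinary arsenic and creatinine.
* **Fixed-effect IVW** is the default; with three instruments a
  random-effects variance is barely estimable. A multiplicative
  random-effects option (`random_effects = TRUE`) inflates the standard
  error by $\max(1, \sqrt{Q/(J-1)})$ for sensitivity analyses.
* **First-order Wald-ratio standard error** ($se_Y/|\beta_X|$): exposure-side
  uncertainty is ignored in the ratio, as usual; the ML estimator is the
  principled alternative when $se_X$ matters.
* **Instruments are treated as independent in IVW/ML**, matching the
  standard summary-statistic implementation; the known 10q24.32 LD is a
  limitation of this analysis inherited by design, partially mitigated by
  the joint adjustment used in the individual-SNP regressions.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(seed = 1)          # 772 samples, 221 CpGs, 60% causal
run <- run_all(cfg, out_dir = "run1")
run$summary
```

The summary table has one row per analysis label (DMA%, log-DMA, GP-DMA%,
binary score, the three carrier-coded SNPs, IVW and ML MR, plus
stricter-tier restrictions), each with `k_consistent`, `n_total` and its
one-sided exact binomial p — the same layout as a published
metabolism-phenotype consistency table.

## Validation strategy and problem sizes

The test suite checks every estimator against an independent oracle: OLS
against an explicit normal-equations solve ($10^{-10}$), IVW against a
precision-weighted no-intercept `lm()` fit ($10^{-10}$), ML against a dense
grid search over the *joint* likelihood with closed-form profiling
($10^{-4}$) and against its IVW limit, and the binomial tail against
combinatorial enumeration for all $n \le 20$ ($10^{-12}$). Replicated
simulations then verify statistical calibration: with no causal CpGs and no
dose coupling (100 replicates of 1,000 samples × 200 CpGs) consistency
fractions sit at chance level and consistency tests are non-significant in
≥95% of replicates; with signal (200 replicates of 2,000 samples × 60 CpGs,
60% causal) the IVW 95% CI covers the generative `true_theta` at
near-nominal rates and the consistency analyses reject the null in ≥90% of
replicates. These sizes were chosen to keep Monte Carlo error comfortably
below the margins being tested.

## Limitations

Simulated covariate distributions are simple parametric stand-ins; the
generator's confounding structure is mild and known. The coverage check
relies on a local-linearization of the logistic link, accurate for the
modest per-allele effects simulated here but not for extreme effects. And
the whole package estimates *associations under an instrumental-variable
model*: the exclusion-restriction assumption (instruments affect methylation
only through metabolism efficiency) is untestable with three instruments,
here as in the analysis it implements.
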