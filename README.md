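# dmamr

Mendelian-randomization triangulation of arsenic metabolism efficiency
against DNA methylation.

## The problem

Epigenome-wide association studies (EWAS) have linked arsenic exposure to
DNA methylation at hundreds of CpG sites in blood, but an observational
association cannot distinguish a causal effect of arsenic from confounding.
Arsenic metabolism efficiency — measured as the percentage of dimethylarsinic
acid among urinary arsenic species (DMA%) — has well-established common
genetic determinants (two 10q24.32/*AS3MT* variants and one *FTCD* variant),
and higher DMA% lowers the internal arsenic dose at a given exposure. Those
variants can therefore serve as instrumental variables: if arsenic causally
drives the EWAS signals, genetically predicted DMA% should associate with
the same CpGs in the direction **opposite** to arsenic exposure.

`dmamr` is for epidemiologists and statistical geneticists who want to run
(or stress-test) this design end to end. It provides:

* **Genetic scores** — the weighted genetically predicted DMA% score
  `GP-DMA% = Σ_j β_Xj X_j` (per-allele DMA% weights × high-efficiency allele
  counts) and a weight-free binary score (homozygous high-efficiency at both
  rs9527 and rs61735836);
* **Per-CpG association models** — OLS of methylation beta-values on DMA%,
  log-DMA, the genetic scores, or carrier-coded single SNPs, under fixed
  covariate sets (age, sex, batch, smoking; plus cohort, BMI, education and
  exposure adjustments where appropriate);
* **Two-sample summary-statistic MR** — Wald ratio, fixed-effect
  inverse-variance-weighted (IVW)

  θ̂ = Σ_j(β_Xj β_Yj / se²_Yj) / Σ_j(β²_Xj / se²_Yj),

  and a profile-likelihood maximum-likelihood estimator
  (β_Xj ~ N(ξ_j, se²_Xj), β_Yj ~ N(θξ_j, se²_Yj));
* **Directional consistency** — each CpG coded consistent when its estimate
  opposes the prior EWAS sign, with the exact one-sided binomial tail
  P(X ≥ k), X ~ Bin(n, ½), as the headline statistic;
* **A synthetic cohort generator** encoding the full causal chain
  genotype → DMA% → internal dose → methylation with known per-CpG truth,
  so the whole pipeline is testable without any cohort data.

The shipped SNP weights file is **synthetic** (plausible values calibrated
to cohort-scale anchors; see its header and the vignette) — replace it with
published per-allele estimates before real-data use.

## Worked example

```r
library(dmamr)
cfg <- sim_config(seed = 1)          # 772 samples, 221 CpGs, 60% causal
run <- run_all(cfg, out_dir = "run1")
run
```

```
Arsenic-metabolism MR triangulation run (seed 1)

          analysis_label k_consistent n_total consistent_fraction binomial_p
                 dma_pct          172     221               0.778   1.60e-17
                 log_dma          171     221               0.774   5.57e-17
                  gp_dma          178     221               0.805   5.22e-21
            binary_score          173     221               0.783   4.50e-18
      snp_carrier:rs9527          164     221               0.742   1.71e-13
  snp_carrier:rs11191527          136     221               0.615   3.67e-04
  snp_carrier:rs61735836          170     221               0.769   1.89e-16
                     ivw          178     221               0.805   5.22e-21
                      ml          178     221               0.805   5.22e-21
       gp_dma_bonferroni           36      42               0.857   1.41e-06
 binary_score_bonferroni           35      42               0.833   7.55e-06
          ivw_bonferroni           36      42               0.857   1.41e-06
```

Each row is one analysis of the 221-CpG panel: `k_consistent` CpGs whose
estimate opposes the prior EWAS sign, out of `n_total`, with the exact
one-sided binomial p for enrichment beyond the chance level of ½. With 60%
of CpGs truly causal and ~2,000-strong genetic effects, every analysis —
measured phenotype, genetic scores, and MR — detects strong directional
consistency; the weakest single instrument (rs11191527) shows the weakest
skew, as expected. Per-CpG MR estimates live in `run$mr`:

```
      cpg_id   theta      se    ci_low ci_high      p
1 cg00000001 0.00183 0.00204 -0.002161 0.00583 0.3683
3 cg00000002 0.00237 0.00179 -0.001145 0.00588 0.1866
```

`theta` is the causal-effect estimate in methylation beta-value units per
percentage point of DMA% — individually noisy (this is why the headline
statistic aggregates signs), but with known truth in `run$cohort$truth` for
calibration studies.

A thin CLI over the same functions is installed at
`system.file("scripts", "dmamr", package = "dmamr")`, with subcommands
`simulate`, `score`, `associate`, `mr`, `consistency` and `run-all`.

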