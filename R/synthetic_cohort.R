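#' Specify a simulated instrument SNP
#'
#' Describes one biallelic SNP used as an instrument for arsenic metabolism
#' efficiency: its effect-allele (high-efficiency allele) frequency and its
#' per-allele effect on DMA% (percentage points), with standard error.
#'
#' @param snp_id SNP identifier.
#' @param effect_allele_freq frequency of the high-efficiency allele, in (0,1).
#' @param beta_dma effect of one effect-allele copy on DMA% (percentage points).
#' @param se_beta_dma standard error of `beta_dma`; must be > 0.
#' @param effect_allele,other_allele allele labels (used in weights files/VCF).
#' @return an object of class `snp_spec`.
#' @export
snp_spec <- function(snp_id, effect_allele_freq, beta_dma, se_beta_dma,
                     effect_allele = "A", other_allele = "G") {
  assert_that(is.character(snp_id) && length(snp_id) == 1L, "snp_id must be a single string")
  assert_that(is.numeric(effect_allele_freq) && effect_allele_freq > 0 && effect_allele_freq < 1,
              "effect_allele_freq must lie strictly in (0, 1)")
  assert_that(is.numeric(se_beta_dma) && se_beta_dma > 0, "se_beta_dma must be > 0")
  structure(
    list(snp_id = snp_id, effect_allele_freq = effect_allele_freq,
         beta_dma = beta_dma, se_beta_dma = se_beta_dma,
         effect_allele = effect_allele, other_allele = other_allele),
    class = "snp_spec"
  )
}

#' Default instrument SNP specifications
#'
#' Three biallelic instruments mirroring the structure of the published
#' DMA%-associated variants: two variants in the 10q24.32/AS3MT region (the
#' first two, optionally in LD) and one FTCD exonic variant. Frequencies and
#' effects are synthetic plausible values consistent with the shipped
#' synthetic weights file (see [default_snp_weights()]): the low-efficiency
#' allele is rare at rs9527 and rs61735836, and rs11191527 has the weakest
#' effect.
#'
#' @return a list of [snp_spec()] objects.
#' @export
default_snp_specs <- function() {
  list(
    snp_spec("rs9527",     0.90, 3.1, 0.55, effect_allele = "G", other_allele = "A"),
    snp_spec("rs11191527", 0.88, 1.2, 0.45, effect_allele = "C", other_allele = "T"),
    snp_spec("rs61735836", 0.95, 4.4, 0.80, effect_allele = "G", other_allele = "A")
  )
}

#' Simulation configuration for a synthetic arsenic cohort
#'
#' Parameterizes the generative causal chain: genotypes set DMA%
#' (arsenic-metabolism efficiency), arsenic exposure is log-normal and weakly
#' negatively coupled to DMA%, internal dose falls with DMA%, and a fraction
#' of CpGs respond to internal dose on the logit-methylation scale. Defaults
#' are calibrated to the cohort-scale facts reported for arsenic-exposed
#' Bangladeshi adults: DMA% centred near 72 with IQR width ~11, urinary
#' arsenic median ~200 ug/g creatinine, and corr(DMA%, ln urinary As) near
#' -0.16.
#'
#' @param n_samples number of individuals.
#' @param n_cpgs number of CpG sites.
#' @param frac_causal fraction of CpGs causally affected by internal dose.
#' @param snp_specs list of [snp_spec()] objects.
#' @param ld_r haplotype correlation between the first two SNPs, in [-1, 1].
#' @param dma_baseline DMA% intercept (percentage points).
#' @param dma_noise_sd residual SD of DMA% (percentage points).
#' @param exposure_log_mean,exposure_log_sd mean/SD of ln urinary arsenic
#'   (ug/g creatinine).
#' @param delta_dma_on_logAs coupling of ln urinary arsenic into DMA%
#'   (percentage points per log unit; negative gives the observed weak
#'   negative correlation).
#' @param lambda_dose per-percentage-point reduction of log internal dose by
#'   DMA%: internal dose I = ln(urinary As) - lambda_dose * DMA%.
#' @param effect_sd SD of causal CpG effects of internal dose on
#'   logit-methylation.
#' @param meth_intercept_sd SD of per-CpG logit-methylation intercepts.
#' @param meth_noise_sd residual SD on the logit-methylation scale.
#' @param covariate_effect_sd SD of per-CpG covariate effects (sex, smoking,
#'   batch, cohort) on logit methylation; age and BMI effects are scaled per
#'   unit and drawn with SD `covariate_effect_sd / 10`.
#' @param confound_smoking_logAs,confound_cohort_logAs additive shifts of ln
#'   urinary arsenic for current smokers and for cohort-2 members; these two
#'   variables also affect methylation, injecting classical confounding of
#'   the exposure-methylation path.
#' @param frac_cohort2 fraction of samples in the second cohort.
#' @param n_batches number of methylation batches.
#' @param seed master integer seed; all stages derive substreams from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 772L,
                       n_cpgs = 221L,
                       frac_causal = 0.6,
                       snp_specs = default_snp_specs(),
                       ld_r = 0.4,
                       dma_baseline = 64.3,
                       dma_noise_sd = 7.5,
                       exposure_log_mean = 5.2,
                       exposure_log_sd = 0.85,
                       delta_dma_on_logAs = -1.5,
                       lambda_dose = 0.05,
                       effect_sd = 0.5,
                       meth_intercept_sd = 1.5,
                       meth_noise_sd = 0.5,
                       covariate_effect_sd = 0.05,
                       confound_smoking_logAs = 0.15,
                       confound_cohort_logAs = -0.2,
                       frac_cohort2 = 0.5,
                       n_batches = 4L,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_cpgs = as.integer(n_cpgs),
    frac_causal = frac_causal, snp_specs = snp_specs, ld_r = ld_r,
    dma_baseline = dma_baseline, dma_noise_sd = dma_noise_sd,
    exposure_log_mean = exposure_log_mean, exposure_log_sd = exposure_log_sd,
    delta_dma_on_logAs = delta_dma_on_logAs, lambda_dose = lambda_dose,
    effect_sd = effect_sd, meth_intercept_sd = meth_intercept_sd,
    meth_noise_sd = meth_noise_sd, covariate_effect_sd = covariate_effect_sd,
    confound_smoking_logAs = confound_smoking_logAs,
    confound_cohort_logAs = confound_cohort_logAs,
    frac_cohort2 = frac_cohort2, n_batches = as.integer(n_batches),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$n_samples >= 1L, "n_samples must be >= 1")
  assert_that(cfg$n_cpgs >= 1L, "n_cpgs must be >= 1")
  assert_that(cfg$frac_causal >= 0 && cfg$frac_causal <= 1,
              "frac_causal must lie in [0, 1]")
  assert_that(abs(cfg$ld_r) <= 1, "ld_r must lie in [-1, 1]")
  assert_that(cfg$dma_noise_sd > 0, "dma_noise_sd must be > 0")
  assert_that(cfg$exposure_log_sd > 0, "exposure_log_sd must be > 0")
  assert_that(cfg$lambda_dose >= 0, "lambda_dose must be >= 0")
  assert_that(cfg$effect_sd > 0, "effect_sd must be > 0")
  assert_that(cfg$meth_noise_sd > 0, "meth_noise_sd must be > 0")
  assert_that(length(cfg$snp_specs) >= 1L, "at least one snp_spec is required")
  for (s in cfg$snp_specs) {
    assert_that(inherits(s, "snp_spec"), "snp_specs must be a list of snp_spec objects")
  }
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Keys are the [sim_config()] argument names; `snp_specs` is a list of
#' mappings with the [snp_spec()] field names. Absent keys take the defaults.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$snp_specs)) {
    raw$snp_specs <- lapply(raw$snp_specs, function(s) do.call(snp_spec, s))
  }
  do.call(sim_config, raw)
}

# Feasible interval for the haplotype covariance D given allele frequencies.
ld_feasible_r <- function(p1, p2) {
  q1 <- 1 - p1; q2 <- 1 - p2
  denom <- sqrt(p1 * q1 * p2 * q2)
  c(max(-p1 * p2, -q1 * q2) / denom, min(p1 * q2, q1 * p2) / denom)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium with optional LD
#'
#' Each SNP is marginally Binomial(2, f) under HWE. When `ld_r` is nonzero,
#' the first two SNPs' haplotypes are drawn jointly from the two-locus
#' haplotype distribution with covariance D = r * sqrt(p1 q1 p2 q2), so the
#' haplotype (and hence genotype) correlation is approximately `ld_r`;
#' remaining SNPs are independent.
#'
#' @param specs list of [snp_spec()] objects.
#' @param n number of individuals.
#' @param ld_r target haplotype correlation between the first two SNPs.
#' @param seed integer seed.
#' @return an `n` x `length(specs)` integer matrix of effect-allele counts in
#'   {0,1,2}, with SNP ids as column names. When `ld_r != 0` the drawn
#'   haplotypes of the first two SNPs are attached as attribute
#'   `"haplotypes"` (a 2n x 2 0/1 matrix) for diagnostics.
#' @export
simulate_genotypes <- function(specs, n, ld_r = 0, seed = 1L) {
  assert_that(n >= 1, "n must be >= 1")
  freqs <- vapply(specs, function(s) s$effect_allele_freq, numeric(1))
  ids <- vapply(specs, function(s) s$snp_id, character(1))
  set.seed(stage_seed(seed, "genotypes"))
  geno <- matrix(0L, nrow = n, ncol = length(specs), dimnames = list(NULL, ids))
  haps <- NULL
  if (ld_r != 0 && length(specs) >= 2L) {
    p1 <- freqs[1]; p2 <- freqs[2]
    bounds <- ld_feasible_r(p1, p2)
    if (ld_r < bounds[1] || ld_r > bounds[2]) {
      stop(sprintf(
        "ld_r = %.3f is infeasible for effect-allele frequencies (%.3f, %.3f); feasible range is [%.3f, %.3f]",
        ld_r, p1, p2, bounds[1], bounds[2]), call. = FALSE)
    }
    D <- ld_r * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
    # haplotype frequencies for allele pairs (1,1), (1,0), (0,1), (0,0)
    hf <- c(p1 * p2 + D, p1 * (1 - p2) - D, (1 - p1) * p2 - D, (1 - p1) * (1 - p2) + D)
    hap_idx <- sample.int(4L, size = 2L * n, replace = TRUE, prob = hf)
    a1 <- c(1L, 1L, 0L, 0L)[hap_idx]   # allele at SNP1
    a2 <- c(1L, 0L, 1L, 0L)[hap_idx]   # allele at SNP2
    haps <- cbind(a1, a2)
    odd <- seq(1L, 2L * n, by = 2L)
    geno[, 1L] <- a1[odd] + a1[odd + 1L]
    geno[, 2L] <- a2[odd] + a2[odd + 1L]
    rest <- seq_along(specs)[-(1:2)]
  } else {
    rest <- seq_along(specs)
  }
  for (j in rest) geno[, j] <- rbinom(n, 2L, freqs[j])
  if (!is.null(haps)) attr(geno, "haplotypes") <- haps
  geno
}

#' Simulate a full synthetic cohort with known causal structure
#'
#' Generates genotypes, covariates, arsenic exposure, DMA%, a latent internal
#' dose, and a CpG beta-value matrix in which a known subset of CpGs responds
#' to internal dose with known signs. The generative model is:
#' \deqn{DMA\% = b_0 + \sum_j \beta_j X_j + \delta \ln U + \epsilon}
#' \deqn{I = \ln U - \lambda \, DMA\%}
#' \deqn{logit(m_c) = a_c + b_c I + \gamma_c' Z + e_c}
#' where U is creatinine-adjusted urinary arsenic, I the internal dose, and
#' b_c is nonzero only for causal CpGs. Smoking status and cohort membership
#' shift both exposure and methylation, injecting confounding that genetic
#' instruments are immune to.
#'
#' @param config a [sim_config()].
#' @return a list of class `cohort_table` with elements
#'   \describe{
#'     \item{samples}{data.frame of per-sample covariates, exposure measures,
#'       `dma_pct`, and the latent `internal_dose` (retained for validation).}
#'     \item{genotype}{n_samples x n_snps effect-allele count matrix.}
#'     \item{methylation}{n_cpgs x n_samples beta-value matrix in (0,1).}
#'     \item{truth}{data.frame with `cpg_id`, `is_causal`, `true_sign`,
#'       `true_effect` (logit-scale effect of internal dose) and `true_theta`
#'       (implied average marginal effect of +1 percentage-point DMA% on the
#'       beta-value scale).}
#'   }
#'   The number of DMA% values truncated into (0.1, 99.9) is attached as
#'   attribute `"n_dma_truncated"`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_samples
  n_cpgs <- config$n_cpgs
  sample_id <- sprintf("S%04d", seq_len(n))
  cpg_id <- sprintf("cg%08d", seq_len(n_cpgs))

  geno <- simulate_genotypes(config$snp_specs, n, ld_r = config$ld_r,
                             seed = config$seed)
  attr(geno, "haplotypes") <- NULL

  set.seed(stage_seed(config$seed, "covariates"))
  age <- round(pmin(pmax(rnorm(n, 40, 8.5), 18), 75))
  sex <- rbinom(n, 1L, 0.52)                       # 1 = female
  cohort <- rbinom(n, 1L, config$frac_cohort2)     # 0 = cohort1, 1 = cohort2
  smoke_p1 <- c(0.607, 0.055, 0.338)               # never/former/current
  smoke_p2 <- c(0.626, 0.102, 0.272)
  smoking <- character(n)
  lv <- c("never", "former", "current")
  smoking[cohort == 0L] <- sample(lv, sum(cohort == 0L), TRUE, smoke_p1)
  smoking[cohort == 1L] <- sample(lv, sum(cohort == 1L), TRUE, smoke_p2)
  smoking <- factor(smoking, levels = lv)
  bmi <- rnorm(n, 20.5, 3)
  education <- round(rgamma(n, shape = 2, scale = 2.5))
  batch <- factor(sample(sprintf("B%d", seq_len(config$n_batches)), n, TRUE))

  set.seed(stage_seed(config$seed, "exposure"))
  log_uas <- config$exposure_log_mean +
    config$confound_smoking_logAs * (smoking == "current") +
    config$confound_cohort_logAs * cohort +
    rnorm(n, 0, config$exposure_log_sd)
  urinary_as <- exp(log_uas)
  water_as <- exp(log_uas - 1 + rnorm(n, 0, 0.5))
  urinary_creatinine <- exp(rnorm(n, -0.6, 0.35))

  set.seed(stage_seed(config$seed, "dma"))
  betas <- vapply(config$snp_specs, function(s) s$beta_dma, numeric(1))
  dma_raw <- config$dma_baseline + drop(geno %*% betas) +
    config$delta_dma_on_logAs * log_uas +
    rnorm(n, 0, config$dma_noise_sd)
  n_trunc <- sum(dma_raw <= 0.1 | dma_raw >= 99.9)
  dma_pct <- pmin(pmax(dma_raw, 0.1), 99.9)
  if (n_trunc > 0) {
    message(sprintf("simulate_cohort: %d DMA%% value(s) truncated into (0.1, 99.9)", n_trunc))
  }
  internal_dose <- log_uas - config$lambda_dose * dma_pct

  # per-CpG effects and covariate loadings
  set.seed(stage_seed(config$seed, "methylation"))
  n_causal <- round(config$frac_causal * n_cpgs)
  is_causal <- c(rep(TRUE, n_causal), rep(FALSE, n_cpgs - n_causal))
  true_sign <- ifelse(is_causal, sample(c(-1, 1), n_cpgs, TRUE), 0)
  true_effect <- ifelse(is_causal,
                        true_sign * abs(rnorm(n_cpgs, 0, config$effect_sd)), 0)
  # guard against near-zero causal effects: signs must be well defined
  tiny <- is_causal & abs(true_effect) < 0.05 * config$effect_sd
  true_effect[tiny] <- true_sign[tiny] * 0.05 * config$effect_sd

  a0 <- rnorm(n_cpgs, 0, config$meth_intercept_sd)
  cs <- config$covariate_effect_sd
  g_age <- rnorm(n_cpgs, 0, cs / 10)
  g_sex <- rnorm(n_cpgs, 0, cs)
  g_smk_f <- rnorm(n_cpgs, 0, cs)
  g_smk_c <- rnorm(n_cpgs, 0, cs)
  g_bmi <- rnorm(n_cpgs, 0, cs / 10)
  g_cohort <- rnorm(n_cpgs, 0, cs)
  g_batch <- matrix(rnorm(n_cpgs * config$n_batches, 0, cs),
                    nrow = n_cpgs)

  Z <- rbind(age - 40, sex, smoking == "former", smoking == "current",
             bmi - 20.5, cohort)                       # 6 x n
  G <- cbind(g_age, g_sex, g_smk_f, g_smk_c, g_bmi, g_cohort)  # n_cpgs x 6
  batch_idx <- as.integer(batch)
  eta <- matrix(a0, nrow = n_cpgs, ncol = n) +
    outer(true_effect, internal_dose) +
    G %*% Z +
    g_batch[, batch_idx] +
    matrix(rnorm(n_cpgs * n, 0, config$meth_noise_sd), nrow = n_cpgs)
  meth <- inv_logit(eta)
  meth <- pmin(pmax(meth, 1e-12), 1 - 1e-12)
  dimnames(meth) <- list(cpg_id, sample_id)

  # implied average marginal effect of +1 point DMA% on the beta-value scale:
  # dI/dDMA% = -lambda, d E[m]/dI = b_c * mean(logistic'(eta))
  kappa <- rowMeans(dinv_logit(eta))
  true_theta <- -config$lambda_dose * true_effect * kappa

  samples <- data.frame(
    sample_id = sample_id, age = age, sex = sex, smoking = smoking,
    bmi = bmi, education = education, batch = batch, cohort = cohort,
    water_as = water_as, urinary_as = urinary_as,
    urinary_creatinine = urinary_creatinine, dma_pct = dma_pct,
    internal_dose = internal_dose,
    stringsAsFactors = FALSE
  )
  rownames(geno) <- sample_id
  truth <- data.frame(cpg_id = cpg_id, is_causal = is_causal,
                      true_sign = true_sign, true_effect = true_effect,
                      true_theta = true_theta, stringsAsFactors = FALSE)
  structure(
    list(samples = samples, genotype = geno, methylation = meth, truth = truth),
    class = "cohort_table", n_dma_truncated = n_trunc
  )
}

#' Generate a synthetic prior-EWAS results table from simulation truth
#'
#' Emulates the input the directional-consistency stage expects: a table of
#' CpGs previously found associated with (log) arsenic exposure, with signed
#' effect estimates. Causal CpGs carry the generative sign of the
#' arsenic-to-methylation effect; non-causal CpGs represent prior false
#' positives and get a random sign. A `tier` column marks the
#' strongest-looking subset as `bonferroni_set` (the rest are `fdr_set`),
#' mirroring a two-tier discovery list.
#'
#' @param truth truth table from [simulate_cohort()].
#' @param seed integer seed.
#' @param frac_bonferroni fraction of CpGs assigned to the stricter tier.
#' @return data.frame with `cpg_id`, `ewas_beta`, `ewas_se`, `ewas_p`, `tier`.
#' @export
simulate_ewas_table <- function(truth, seed = 1L, frac_bonferroni = 0.19) {
  set.seed(stage_seed(seed, "ewas"))
  n <- nrow(truth)
  sign_vec <- ifelse(truth$is_causal, truth$true_sign,
                     sample(c(-1, 1), n, TRUE))
  mag <- abs(rnorm(n, 0.04, 0.015)) + 1e-4
  se <- mag / (2 + abs(rnorm(n, 2, 1)))
  beta <- sign_vec * mag
  p <- 2 * pnorm(-abs(beta) / se)
  n_bonf <- round(frac_bonferroni * n)
  tier <- rep("fdr_set", n)
  tier[order(p)[seq_len(n_bonf)]] <- "bonferroni_set"
  data.frame(cpg_id = truth$cpg_id, ewas_beta = beta, ewas_se = se,
             ewas_p = p, tier = tier, stringsAsFactors = FALSE)
}

#' Write a cohort to plain-text files
#'
#' Writes `genotypes.tsv` (rows = samples, columns = SNP ids, values 0/1/2),
#' `covariates.tsv`, `methylation.tsv` (rows = CpG ids, columns = sample
#' ids), and `truth.tsv` into `dir`. All tables are tab-separated with header
#' rows; missing values are written as empty fields.
#'
#' @param cohort a `cohort_table`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, "genotypes.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  gdf <- data.frame(sample_id = rownames(cohort$genotype),
                    cohort$genotype, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(gdf, paths[["genotypes"]])
  write_tsv(cohort$samples, paths[["covariates"]])
  mdf <- data.frame(cpg_id = rownames(cohort$methylation),
                    cohort$methylation, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(mdf, paths[["methylation"]])
  if (!is.null(cohort$truth)) write_tsv(cohort$truth, paths[["truth"]])
  invisible(paths)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "", ...)
}
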