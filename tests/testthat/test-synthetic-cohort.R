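test_that("genotypes recover their allele frequencies under HWE", {
  specs <- list(snp_spec("a", 0.5, 1, 0.1), snp_spec("b", 0.2, 1, 0.1),
                snp_spec("c", 0.9, 1, 0.1))
  n <- 20000
  g <- simulate_genotypes(specs, n, ld_r = 0, seed = 3)
  f_hat <- colMeans(g) / 2
  f <- c(0.5, 0.2, 0.9)
  expect_true(all(abs(f_hat - f) < 3 * sqrt(f * (1 - f) / (2 * n))))
  # independent SNPs are empirically uncorrelated
  expect_lt(abs(cor(g[, 1], g[, 2])), 3 / sqrt(n))
  expect_true(all(g %in% 0:2))
})

test_that("LD haplotype sampling achieves the requested correlation", {
  specs <- list(snp_spec("a", 0.2, 1, 0.1), snp_spec("b", 0.3, 1, 0.1))
  g <- simulate_genotypes(specs, 50000, ld_r = 0.5, seed = 5)
  haps <- attr(g, "haplotypes")
  # oracle: with D = r * sqrt(p1 q1 p2 q2), haplotype correlation is r;
  # check the empirical haplotype correlation directly
  r_hat <- cor(haps[, 1], haps[, 2])
  expect_lt(abs(r_hat - 0.5), 0.02)
  # genotype correlation under random mating equals the haplotype r
  expect_lt(abs(cor(g[, 1], g[, 2]) - 0.5), 0.03)
})

test_that("infeasible LD requests are rejected with the feasible bound", {
  specs <- list(snp_spec("a", 0.05, 1, 0.1), snp_spec("b", 0.95, 1, 0.1))
  # with p1 = 0.05, p2 = 0.95 the maximum achievable r is far below 0.9
  expect_error(simulate_genotypes(specs, 100, ld_r = 0.9, seed = 1),
               "feasible range")
})

test_that("cohorts are bit-identical under a fixed seed and config", {
  cfg <- sim_config(n_samples = 150, n_cpgs = 20, seed = 99)
  a <- suppressMessages(simulate_cohort(cfg))
  b <- suppressMessages(simulate_cohort(cfg))
  expect_identical(a$samples, b$samples)
  expect_identical(a$genotype, b$genotype)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$truth, b$truth)
})

test_that("cohort tables satisfy their range invariants", {
  tc <- tiny_cohort()
  sim <- tc$cohort
  expect_true(all(sim$genotype %in% 0:2))
  expect_true(all(sim$methylation > 0 & sim$methylation < 1))
  expect_true(all(sim$samples$dma_pct > 0 & sim$samples$dma_pct < 100))
  expect_equal(nrow(sim$methylation), tc$config$n_cpgs)
  expect_equal(ncol(sim$methylation), tc$config$n_samples)
  # truth table: non-causal rows have zero effect, causal signs match
  tr <- sim$truth
  expect_true(all(tr$true_effect[!tr$is_causal] == 0))
  expect_true(all(sign(tr$true_effect[tr$is_causal]) ==
                    tr$true_sign[tr$is_causal]))
})

test_that("DMA% and log urinary arsenic are weakly negatively correlated as calibrated", {
  cfg <- sim_config(n_samples = 10000, n_cpgs = 2, seed = 17)
  sim <- suppressMessages(simulate_cohort(cfg))
  r <- cor(sim$samples$dma_pct, log(sim$samples$urinary_as))
  expect_lt(abs(r - (-0.16)), 0.05)
})

test_that("a hypermethylation-causal CpG associates negatively with DMA%", {
  # oracle: cov(dma, internal dose) = delta var(lnU) - lambda var(dma) < 0
  # when delta < 0 and lambda >= 0, so a CpG hypermethylated by internal
  # dose (true_sign = +1) must show a negative DMA% slope in expectation
  cfg <- sim_config(n_samples = 4000, n_cpgs = 40, frac_causal = 1,
                    effect_sd = 1.2, seed = 23)
  sim <- suppressMessages(simulate_cohort(cfg))
  expect_lt(cov(sim$samples$dma_pct, sim$samples$internal_dose), 0)
  res <- run_analysis(sim, model_spec("dma_pct"))
  tr <- sim$truth
  strong <- abs(tr$true_effect) > 0.8
  expect_true(all(sign(res$beta[tr$true_sign == 1 & strong]) == -1))
  expect_true(all(sign(res$beta[tr$true_sign == -1 & strong]) == 1))
})

test_that("with no dose coupling, DMA% association p-values are uniform", {
  cfg <- sim_config(n_samples = 400, n_cpgs = 1000, frac_causal = 0.5,
                    lambda_dose = 0, delta_dma_on_logAs = 0, seed = 31)
  sim <- suppressMessages(simulate_cohort(cfg))
  res <- run_analysis(sim, model_spec("dma_pct"))
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("DMA% truncation into (0.1, 99.9) is counted", {
  cfg <- sim_config(n_samples = 500, n_cpgs = 2, dma_baseline = 97,
                    seed = 8)
  expect_message(sim <- simulate_cohort(cfg), "truncated")
  expect_gt(attr(sim, "n_dma_truncated"), 0)
  expect_true(all(sim$samples$dma_pct <= 99.9))
})

test_that("config validation rejects bad parameters and YAML round-trips", {
  expect_error(sim_config(frac_causal = 1.5), "frac_causal")
  expect_error(sim_config(dma_noise_sd = 0), "dma_noise_sd")
  expect_error(snp_spec("x", 1.2, 1, 0.1), "effect_allele_freq")
  expect_error(snp_spec("x", 0.5, 1, 0), "se_beta_dma")
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_samples = 50, n_cpgs = 5, seed = 2,
                        snp_specs = list(list(snp_id = "rs1",
                                              effect_allele_freq = 0.7,
                                              beta_dma = 2, se_beta_dma = 0.3))),
                   tf)
  cfg <- read_sim_config(tf)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_samples, 50L)
  expect_equal(cfg$snp_specs[[1]]$snp_id, "rs1")
})
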