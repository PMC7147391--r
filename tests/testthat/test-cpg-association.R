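test_that("a noiseless linear outcome is fit exactly", {
  x <- seq(0, 10, length.out = 25)
  y <- 0.3 + 0.01 * x
  res <- fit_cpg_model(y, x)
  expect_equal(res$beta, 0.01, tolerance = 1e-12)
  expect_equal(res$se, 0, tolerance = 1e-10)
  expect_equal(res$n_used, 25)
})

test_that("slope and se match a direct normal-equations solve", {
  set.seed(11)
  n <- 12
  pred <- rnorm(n)
  cov1 <- rnorm(n)
  cov2 <- rnorm(n)
  y <- 0.4 + 0.02 * pred - 0.05 * cov1 + 0.01 * cov2 + rnorm(n, 0, 0.03)
  res <- fit_cpg_model(y, pred, data.frame(cov1 = cov1, cov2 = cov2))
  X <- cbind(1, pred, cov1, cov2)
  o <- oracle_ols(X, y, j = 2)
  expect_equal(res$beta, o$beta, tolerance = 1e-10)
  expect_equal(res$se, o$se, tolerance = 1e-10)
  expect_equal(res$t, o$beta / o$se, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(o$beta / o$se), n - 4), tolerance = 1e-10)
})

test_that("p-values under a permuted predictor are uniform", {
  set.seed(13)
  n <- 120
  m <- 1000
  pred <- rnorm(n)
  Y <- matrix(rnorm(n * m, 0.5, 0.05), nrow = m)  # outcomes unrelated to pred
  pv <- vapply(seq_len(m), function(i)
    fit_cpg_model(Y[i, ], sample(pred))$p, numeric(1))
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("an orthogonal covariate leaves the slope unchanged", {
  set.seed(19)
  n <- 200
  pred <- rnorm(n)
  y <- 0.3 + 0.05 * pred + rnorm(n, 0, 0.1)
  # orthogonalize a random covariate against intercept, predictor, outcome
  z <- residuals(lm(rnorm(n) ~ pred + y))
  b0 <- fit_cpg_model(y, pred)$beta
  b1 <- fit_cpg_model(y, pred, data.frame(z = z))$beta
  expect_equal(b0, b1, tolerance = 1e-8)
})

test_that("slopes are equivariant under predictor rescaling", {
  set.seed(23)
  n <- 80
  pred <- rnorm(n, 70, 8)
  y <- plogis(0.2 - 0.01 * pred + rnorm(n, 0, 0.2))
  b <- fit_cpg_model(y, pred)$beta
  b_scaled <- fit_cpg_model(y, pred * 10)$beta
  expect_equal(b_scaled, b / 10, tolerance = 1e-12)
})

test_that("covariate sets follow the analysis plan per predictor", {
  expect_setequal(model_covariates("dma_pct"),
                  c("age", "sex", "batch", "smoking", "bmi", "education",
                    "log_water_as"))
  expect_setequal(model_covariates("log_dma"),
                  c(model_covariates("dma_pct"), "log_urinary_as",
                    "log_creatinine"))
  expect_setequal(model_covariates("gp_dma"),
                  c("age", "sex", "batch", "smoking", "cohort"))
  expect_equal(model_covariates("snp_carrier:rs9527"),
               model_covariates("binary_score"))
  expect_error(model_covariates("nonsense"), "unknown predictor")
  expect_error(model_spec("gp_dma", covariates = c("gp_dma", "age")),
               "predictor may not")
  # DMA%-based models restrict to the cohort with speciation data
  expect_equal(model_spec("dma_pct")$cohort_restriction, "cohort1_only")
  expect_equal(model_spec("gp_dma")$cohort_restriction, "combined")
})

test_that("rank-deficient designs and tiny samples are rejected informatively", {
  set.seed(3)
  n <- 30
  pred <- rnorm(n)
  dup <- data.frame(c1 = pred)  # perfectly collinear with the predictor
  expect_error(fit_cpg_model(rnorm(n), pred, dup), "collinear")
  expect_error(fit_cpg_model(rnorm(3), rnorm(3),
                             data.frame(a = rnorm(3), b = rnorm(3))),
               "complete cases")
})

test_that("run_analysis skips unknown CpGs with a warning and keeps known ones", {
  tc <- tiny_cohort()
  ids <- c(rownames(tc$cohort$methylation)[1:5], "cg_missing_1")
  expect_warning(
    res <- run_analysis(tc$cohort, model_spec("gp_dma"), cpg_ids = ids,
                        weights = tc$weights),
    "unknown CpG")
  expect_equal(nrow(res), 5)
})

test_that("the correlated 10q24.32 SNPs are modelled jointly in carrier analyses", {
  tc <- tiny_cohort()
  mf <- dmamr:::build_model_frame(tc$cohort, model_spec("snp_carrier:rs9527"),
                                  weights = tc$weights)
  expect_true("carrier_rs11191527" %in% names(mf$covars))
  mf2 <- dmamr:::build_model_frame(tc$cohort,
                                   model_spec("snp_carrier:rs61735836"),
                                   weights = tc$weights)
  expect_false(any(grepl("carrier_", names(mf2$covars))))
})

test_that("cohort restriction limits both design and methylation columns", {
  tc <- tiny_cohort()
  res <- run_analysis(tc$cohort, model_spec("dma_pct"),
                      weights = tc$weights)
  expect_equal(unique(res$n_used), sum(tc$cohort$samples$cohort == 0))
  res2 <- run_analysis(tc$cohort, model_spec("gp_dma"), weights = tc$weights)
  expect_equal(unique(res2$n_used), nrow(tc$cohort$samples))
})

test_that("causal CpG DMA% slopes oppose the generative arsenic sign at scale", {
  cfg <- sim_config(n_samples = 3000, n_cpgs = 120, frac_causal = 0.5,
                    effect_sd = 0.8, seed = 57)
  sim <- suppressMessages(simulate_cohort(cfg))
  res <- run_analysis(sim, model_spec("dma_pct"))
  tr <- sim$truth
  causal <- tr$is_causal
  agree <- sign(res$beta[causal]) == -tr$true_sign[causal]
  expect_gt(mean(agree), 0.9)
})
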