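test_that("the Wald ratio is definitional arithmetic with a first-order se", {
  inst <- data.frame(snp_id = "s", beta_x = 0.5, se_x = 0.1,
                     beta_y = 1.0, se_y = 0.2)
  res <- wald_ratio(inst)
  expect_equal(res$theta, 2.0)
  expect_equal(res$se, 0.4)
  expect_equal(res$ci_low, 2 - qnorm(0.975) * 0.4)
  inst0 <- transform(inst, beta_y = 0)
  expect_equal(wald_ratio(inst0)$theta, 0)
  flipped <- transform(inst, beta_x = -beta_x, beta_y = -beta_y)
  expect_equal(wald_ratio(flipped)$theta, res$theta)
  expect_equal(wald_ratio(flipped)$se, res$se)
  expect_error(wald_ratio(transform(inst, beta_x = 0)), "undefined")
})

test_that("IVW reduces to the Wald ratio with one instrument", {
  inst <- data.frame(snp_id = "s", beta_x = 0.7, se_x = 0.2,
                     beta_y = -0.03, se_y = 0.01)
  expect_equal(ivw_estimate(inst)$theta, wald_ratio(inst)$theta,
               tolerance = 1e-12)
  expect_equal(ivw_estimate(inst)$se, wald_ratio(inst)$se,
               tolerance = 1e-12)
})

test_that("IVW equals the weighted no-intercept regression oracle", {
  inst <- fixture_instruments()
  res <- ivw_estimate(inst)
  # oracle 1: weights = 1/se_y^2 no-intercept weighted least squares via lm
  fit <- lm(beta_y ~ 0 + beta_x, data = inst, weights = 1 / inst$se_y^2)
  expect_equal(res$theta, unname(coef(fit)), tolerance = 1e-10)
  # oracle 2: explicit normal-equations arithmetic for theta and the
  # fixed-effect standard error
  w <- 1 / inst$se_y^2
  expect_equal(res$theta,
               sum(inst$beta_x * inst$beta_y * w) / sum(inst$beta_x^2 * w),
               tolerance = 1e-12)
  expect_equal(res$se, sqrt(1 / sum(inst$beta_x^2 * w)), tolerance = 1e-12)
})

test_that("exactly proportional instruments give theta = c with zero heterogeneity", {
  inst <- fixture_instruments()
  inst$beta_y <- 0.004 * inst$beta_x
  res <- ivw_estimate(inst)
  expect_equal(res$theta, 0.004, tolerance = 1e-14)
  Q <- sum((inst$beta_y - res$theta * inst$beta_x)^2 / inst$se_y^2)
  expect_equal(Q, 0, tolerance = 1e-20)
  # with zero heterogeneity the random-effects se is not inflated
  expect_equal(ivw_estimate(inst, random_effects = TRUE)$se, res$se)
})

test_that("ML converges to IVW as exposure uncertainty vanishes", {
  inst <- fixture_instruments()
  inst$se_x <- 1e-8 * inst$se_y
  expect_equal(ml_estimate(inst)$theta, ivw_estimate(inst)$theta,
               tolerance = 1e-4)
})

test_that("a single symmetric instrument gives theta = 1 by symmetry", {
  inst <- data.frame(snp_id = "s", beta_x = 0.3, se_x = 0.05,
                     beta_y = 0.3, se_y = 0.05)
  expect_equal(ml_estimate(inst)$theta, 1, tolerance = 1e-8)
})

test_that("ML matches a dense grid-search oracle on the joint likelihood", {
  inst <- fixture_instruments()
  res <- ml_estimate(inst)
  t_grid <- oracle_ml_grid(inst, lo = -0.05, hi = 0.05)
  expect_equal(res$theta, t_grid, tolerance = 1e-4)
  expect_true(res$ci_low < res$theta && res$theta < res$ci_high)
  expect_gt(res$se, 0)
})

test_that("all estimators are invariant to allele flips of any subset", {
  inst <- fixture_instruments()
  for (flip in list(1L, 2L, c(1L, 3L), 1:3)) {
    f <- inst
    f$beta_x[flip] <- -f$beta_x[flip]
    f$beta_y[flip] <- -f$beta_y[flip]
    expect_equal(ivw_estimate(f)$theta, ivw_estimate(inst)$theta,
                 tolerance = 1e-12)
    expect_equal(ivw_estimate(f)$se, ivw_estimate(inst)$se,
                 tolerance = 1e-12)
    expect_equal(ml_estimate(f)$theta, ml_estimate(inst)$theta,
                 tolerance = 1e-6)
  }
})

test_that("estimates scale with the outcome units", {
  inst <- fixture_instruments()
  c_ <- 37.5
  sc <- transform(inst, beta_y = beta_y * c_, se_y = se_y * c_)
  expect_equal(ivw_estimate(sc)$theta, c_ * ivw_estimate(inst)$theta,
               tolerance = 1e-10)
  expect_equal(ivw_estimate(sc)$se, c_ * ivw_estimate(inst)$se,
               tolerance = 1e-10)
  expect_equal(ml_estimate(sc)$theta, c_ * ml_estimate(inst)$theta,
               tolerance = 1e-6)
})

test_that("the IVW se shrinks monotonically as instrument strength grows", {
  inst <- fixture_instruments()
  strengths <- c(1, 2, 4, 8)
  ses <- vapply(strengths, function(s) {
    ivw_estimate(transform(inst, beta_x = beta_x * s))$se
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("degenerate instrument sets are rejected", {
  expect_error(ivw_estimate(fixture_instruments()[0, ]), "empty")
  bad <- transform(fixture_instruments(), beta_x = 0)
  expect_error(ivw_estimate(bad), "not identified")
})

test_that("mr_analysis returns one estimate per CpG and method", {
  tc <- tiny_cohort()
  ids <- rownames(tc$cohort$methylation)[1:8]
  sa <- snp_outcome_associations(tc$cohort, cpg_ids = ids)
  mr <- mr_analysis(sa, tc$weights, methods = c("ivw", "ml"))
  expect_equal(nrow(mr), 16)
  expect_setequal(unique(mr$method), c("ivw", "ml"))
  expect_true(all(mr$ci_low < mr$theta & mr$theta < mr$ci_high))
  expect_true(all(mr$se > 0))
  expect_equal(unique(mr$n_instruments), 3L)
  # ivw and ml agree closely when instruments are strong relative to se_x
  bym <- split(mr, mr$method)
  expect_equal(bym$ivw$theta, bym$ml$theta, tolerance = 0.15)
})
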