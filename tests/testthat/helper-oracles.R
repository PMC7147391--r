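# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: plain normal-equations linear algebra, explicit
# likelihood evaluation, and combinatorial enumeration.

# OLS slope/se for column j of design X by direct normal equations
oracle_ols <- function(X, y, j) {
  XtX_inv <- solve(t(X) %*% X)
  b <- XtX_inv %*% t(X) %*% y
  res <- y - X %*% b
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(beta = b[j], se = sqrt(s2 * XtX_inv[j, j]))
}

# Maximum-likelihood MR oracle: dense two-stage grid search over theta,
# evaluating the FULL joint likelihood with the per-SNP exposure effects
# xi_j maximized in closed form for each candidate theta.
oracle_ml_grid <- function(inst, lo, hi, n_grid = 4001) {
  joint_ll <- function(theta) {
    xi <- (inst$beta_x / inst$se_x^2 + theta * inst$beta_y / inst$se_y^2) /
      (1 / inst$se_x^2 + theta^2 / inst$se_y^2)
    sum(-(inst$beta_x - xi)^2 / (2 * inst$se_x^2) -
          (inst$beta_y - theta * xi)^2 / (2 * inst$se_y^2))
  }
  grid <- seq(lo, hi, length.out = n_grid)
  ll <- vapply(grid, joint_ll, numeric(1))
  t0 <- grid[which.max(ll)]
  step <- grid[2] - grid[1]
  fine <- seq(t0 - step, t0 + step, length.out = n_grid)
  ll2 <- vapply(fine, joint_ll, numeric(1))
  fine[which.max(ll2)]
}

# Exact binomial upper tail by combinatorial enumeration (n small)
oracle_binom_tail <- function(k, n) {
  if (k == 0) return(1)
  sum(choose(n, k:n)) / 2^n
}

# Small deterministic instrument fixture
fixture_instruments <- function() {
  data.frame(
    snp_id = c("s1", "s2", "s3"),
    beta_x = c(3.1, 1.2, 4.4), se_x = c(0.55, 0.45, 0.80),
    beta_y = c(0.012, 0.003, 0.021), se_y = c(0.004, 0.005, 0.006),
    stringsAsFactors = FALSE
  )
}

# Small cohort shared by several files (built once per test run)
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_samples = 400, n_cpgs = 40, seed = 42)
      cache <<- list(config = cfg,
                     cohort = suppressMessages(simulate_cohort(cfg)),
                     weights = weights_from_config(cfg))
    }
    cache
  }
})
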