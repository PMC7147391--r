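#' Assemble an instrument summary table
#'
#' Joins SNP-to-exposure weights (beta_x, se_x) with SNP-to-outcome
#' association results (beta_y, se_y) by snp_id, preserving effect-allele
#' orientation: both betas must be coded on the same (high-efficiency)
#' allele.
#'
#' @param weights `snp_weights` table.
#' @param snp_assoc data.frame with `snp_id`, `beta`, `se` for one CpG.
#' @return data.frame with `snp_id`, `beta_x`, `se_x`, `beta_y`, `se_y`.
#' @export
instrument_summary <- function(weights, snp_assoc) {
  m <- match(snp_assoc$snp_id, weights$snp_id)
  assert_that(!anyNA(m), paste("snp_id(s) absent from weights:",
              paste(snp_assoc$snp_id[is.na(m)], collapse = ", ")))
  out <- data.frame(
    snp_id = snp_assoc$snp_id,
    beta_x = weights$beta_dma[m], se_x = weights$se[m],
    beta_y = snp_assoc$beta, se_y = snp_assoc$se,
    stringsAsFactors = FALSE
  )
  assert_that(all(out$se_x > 0) && all(out$se_y > 0),
              "all instrument standard errors must be > 0")
  out
}

mr_result <- function(method, theta, se, n_instruments, cpg_id = NA_character_) {
  z <- stats::qnorm(0.975)
  data.frame(
    cpg_id = cpg_id, method = method, theta = theta, se = se,
    ci_low = theta - z * se, ci_high = theta + z * se,
    p = 2 * stats::pnorm(-abs(theta / se)), n_instruments = n_instruments,
    stringsAsFactors = FALSE
  )
}

#' Single-instrument Wald ratio estimate
#'
#' theta = beta_y / beta_x with first-order standard error
#' se = se_y / |beta_x| (uncertainty in the instrument-exposure effect is
#' ignored, as usual for the first-order ratio); normal 95% CI.
#'
#' @param inst one-row instrument table ([instrument_summary()]) or a list
#'   with `beta_x`, `beta_y`, `se_y`.
#' @return one-row MR-estimate data.frame.
#' @export
wald_ratio <- function(inst) {
  assert_that(length(inst$beta_x) == 1L, "wald_ratio takes a single instrument")
  assert_that(inst$beta_x != 0, "beta_x = 0: Wald ratio undefined")
  mr_result("wald", inst$beta_y / inst$beta_x, inst$se_y / abs(inst$beta_x), 1L)
}

#' Inverse-variance-weighted two-sample MR estimate
#'
#' Fixed-effect IVW combination of per-SNP Wald ratios:
#' \deqn{\hat\theta = \frac{\sum_j \beta_{Xj}\beta_{Yj}/se_{Yj}^2}
#'                         {\sum_j \beta_{Xj}^2/se_{Yj}^2},\qquad
#'       se(\hat\theta) = \sqrt{1/\textstyle\sum_j \beta_{Xj}^2/se_{Yj}^2}}
#' equivalent to a no-intercept regression of beta_y on beta_x weighted by
#' 1/se_y^2. With one instrument this reduces exactly to the Wald ratio.
#' With `random_effects = TRUE` the standard error is inflated
#' multiplicatively by max(1, sqrt(Q/(J-1))) where Q is Cochran's
#' heterogeneity statistic.
#'
#' @param instruments instrument table with >= 1 row.
#' @param random_effects inflate the se under multiplicative random effects?
#' @return one-row MR-estimate data.frame.
#' @export
ivw_estimate <- function(instruments, random_effects = FALSE) {
  J <- nrow(instruments)
  assert_that(!is.null(J) && J >= 1L, "empty instrument list")
  assert_that(any(instruments$beta_x != 0),
              "all beta_x are zero: causal effect not identified")
  w <- 1 / instruments$se_y^2
  denom <- sum(instruments$beta_x^2 * w)
  theta <- sum(instruments$beta_x * instruments$beta_y * w) / denom
  se <- sqrt(1 / denom)
  if (random_effects && J > 1L) {
    Q <- sum(w * (instruments$beta_y - theta * instruments$beta_x)^2)
    se <- se * max(1, sqrt(Q / (J - 1)))
  }
  mr_result(if (random_effects) "ivw_re" else "ivw", theta, se, J)
}

# Profile log-likelihood of theta: per-SNP true exposure effects are
# profiled out in closed form, leaving
#   l_p(theta) = -1/2 sum_j (beta_y - theta beta_x)^2 / (se_y^2 + theta^2 se_x^2)
profile_loglik <- function(theta, inst) {
  -0.5 * sum((inst$beta_y - theta * inst$beta_x)^2 /
               (inst$se_y^2 + theta^2 * inst$se_x^2))
}

profile_gradient <- function(theta, inst) {
  r <- inst$beta_y - theta * inst$beta_x
  v <- inst$se_y^2 + theta^2 * inst$se_x^2
  sum(r * inst$beta_x / v + r^2 * theta * inst$se_x^2 / v^2)
}

#' Maximum-likelihood two-sample MR estimate
#'
#' Maximizes the bivariate-normal likelihood in which each instrument's true
#' exposure effect xi_j is a free parameter: beta_Xj ~ N(xi_j, se_Xj^2),
#' beta_Yj ~ N(theta xi_j, se_Yj^2), instruments independent. The xi_j are
#' profiled out in closed form and theta is found by Newton iteration from
#' the IVW start point (gradient tolerance 1e-8, damped steps, iteration cap
#' 100). The standard error comes from the curvature of the profile
#' log-likelihood at the optimum. As all se_x tend to 0 the estimate tends
#' to the fixed-effect IVW estimate.
#'
#' @param instruments instrument table with >= 1 row.
#' @param tol convergence tolerance on the gradient norm.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   iteration trace.
#' @return one-row MR-estimate data.frame.
#' @export
ml_estimate <- function(instruments, tol = 1e-8, max_iter = 100L) {
  J <- nrow(instruments)
  assert_that(!is.null(J) && J >= 1L, "empty instrument list")
  theta <- ivw_estimate(instruments)$theta
  trace <- numeric(0)
  h_step <- function(t) max(1e-6, 1e-6 * abs(t))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- profile_gradient(theta, instruments)
    trace <- c(trace, theta)
    if (abs(g) < tol) { converged <- TRUE; break }
    h <- h_step(theta)
    hess <- (profile_gradient(theta + h, instruments) -
             profile_gradient(theta - h, instruments)) / (2 * h)
    step <- if (is.finite(hess) && hess < 0) -g / hess else sign(g) * h_step(theta) * 100
    # damped Newton: halve until the profile likelihood does not decrease
    ll0 <- profile_loglik(theta, instruments)
    lambda <- 1
    repeat {
      cand <- theta + lambda * step
      if (profile_loglik(cand, instruments) >= ll0 - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    theta <- theta + lambda * step
  }
  if (!converged) {
    stop("ml_estimate did not converge after ", max_iter,
         " iterations; trace: ",
         paste(sprintf("%.6g", utils::tail(trace, 8)), collapse = ", "),
         call. = FALSE)
  }
  h <- h_step(theta)
  hess <- (profile_gradient(theta + h, instruments) -
           profile_gradient(theta - h, instruments)) / (2 * h)
  assert_that(is.finite(hess) && hess < 0,
              "profile likelihood is not locally concave at the optimum")
  mr_result("ml", theta, sqrt(-1 / hess), J)
}

#' Per-CpG two-sample MR across a panel of CpGs
#'
#' Combines the SNP-to-DMA% weights (exposure side) with this pipeline's
#' SNP-to-methylation regressions (outcome side) into one causal-effect
#' estimate per CpG and method. theta is expressed as methylation
#' beta-value change per percentage-point DMA%.
#'
#' @param snp_assoc long table from [snp_outcome_associations()].
#' @param weights `snp_weights` table.
#' @param methods subset of `c("ivw", "ml", "wald")` (wald requires exactly
#'   one instrument per CpG).
#' @param random_effects passed to [ivw_estimate()].
#' @return data.frame, one row per CpG x method.
#' @export
mr_analysis <- function(snp_assoc, weights = default_snp_weights(),
                        methods = c("ivw", "ml"), random_effects = FALSE) {
  methods <- match.arg(methods, c("ivw", "ml", "wald"), several.ok = TRUE)
  out <- lapply(split(snp_assoc, snp_assoc$cpg_id), function(d) {
    inst <- instrument_summary(weights, d)
    res <- lapply(methods, function(m) {
      est <- switch(m,
        ivw = ivw_estimate(inst, random_effects = random_effects),
        ml = ml_estimate(inst),
        wald = wald_ratio(inst))
      est$cpg_id <- d$cpg_id[1]
      est
    })
    do.call(rbind, res)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$cpg_id, unique(snp_assoc$cpg_id))), , drop = FALSE]
}
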