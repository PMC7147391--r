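#' Code a CpG estimate's direction against the prior EWAS sign
#'
#' An estimate is "consistent" with the prior arsenic-exposure EWAS when its
#' sign is *opposite* to the EWAS sign: efficient arsenic metabolism lowers
#' the internal dose, so a CpG hypermethylated by arsenic should be
#' negatively associated with metabolism efficiency, and vice versa. An
#' estimate of exactly 0 is coded inconsistent (conservative tie rule; a
#' probability-zero event for continuous estimates).
#'
#' @param estimate_beta numeric vector of estimates (slopes or MR thetas).
#' @param ewas_beta numeric vector of prior EWAS effects; must be nonzero.
#' @return character vector of `"consistent"` / `"inconsistent"`.
#' @export
code_direction <- function(estimate_beta, ewas_beta) {
  assert_that(all(ewas_beta != 0),
              "ewas_beta must be nonzero: direction undefined at 0")
  ifelse(sign(estimate_beta) == -sign(ewas_beta) & estimate_beta != 0,
         "consistent", "inconsistent")
}

#' One-sided exact binomial tail probability
#'
#' Exact upper-tail probability P(X >= k) for X ~ Binomial(n, 1/2): the
#' probability, under the chance null, of observing at least k
#' directionally consistent CpGs out of n. Computed with the survival-form
#' binomial distribution function (numerically stable summation); no normal
#' approximation.
#'
#' @param k number of consistent CpGs (0 <= k <= n); vectorized.
#' @param n total CpGs tested (>= 1).
#' @return upper-tail probability in (0, 1].
#' @export
binomial_one_sided <- function(k, n) {
  assert_that(all(n >= 1), "n must be >= 1")
  assert_that(all(k >= 0 & k <= n), "k must satisfy 0 <= k <= n")
  stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
}

#' Summarize directional consistency of a set of estimates
#'
#' Flags each CpG as consistent/inconsistent against the prior EWAS signs
#' via [code_direction()], counts k consistent out of n, and attaches the
#' one-sided exact binomial p-value for enrichment of consistency beyond
#' chance.
#'
#' @param estimates data.frame with `cpg_id` and an effect column (`beta`
#'   for regression results, `theta` for MR results; auto-detected, or name
#'   it via `effect_col`). Duplicate CpG ids are rejected.
#' @param ewas data.frame with `cpg_id`, `ewas_beta`, and optionally `tier`.
#' @param label analysis label carried into the summary.
#' @param tier optional: restrict to CpGs with this `tier` value in `ewas`
#'   (e.g. `"bonferroni_set"`).
#' @param effect_col name of the effect column in `estimates`.
#' @return an object of class `consistency_summary`: a list with
#'   `analysis_label`, `k_consistent`, `n_total`, `binomial_p_one_sided`,
#'   and `per_cpg_flags` (data.frame `cpg_id`, `flag`).
#' @export
summarize_consistency <- function(estimates, ewas, label = "analysis",
                                  tier = NULL, effect_col = NULL) {
  if (is.null(effect_col)) {
    effect_col <- intersect(c("beta", "theta"), names(estimates))[1]
  }
  assert_that(!is.na(effect_col) && effect_col %in% names(estimates),
              "estimates must have a 'beta' or 'theta' column")
  assert_that(!anyDuplicated(estimates$cpg_id),
              "duplicate cpg_id in estimates")
  if (!is.null(tier)) {
    assert_that("tier" %in% names(ewas), "ewas has no 'tier' column")
    ewas <- ewas[ewas$tier == tier, , drop = FALSE]
    estimates <- estimates[estimates$cpg_id %in% ewas$cpg_id, , drop = FALSE]
    assert_that(nrow(estimates) > 0, paste("no estimates in tier", tier))
  }
  m <- match(estimates$cpg_id, ewas$cpg_id)
  if (anyNA(m)) {
    stop("CpG id(s) missing from the EWAS table: ",
         paste(utils::head(estimates$cpg_id[is.na(m)], 10), collapse = ", "),
         call. = FALSE)
  }
  flag <- code_direction(estimates[[effect_col]], ewas$ewas_beta[m])
  k <- sum(flag == "consistent")
  n <- length(flag)
  structure(
    list(analysis_label = label, k_consistent = k, n_total = n,
         binomial_p_one_sided = binomial_one_sided(k, n),
         per_cpg_flags = data.frame(cpg_id = estimates$cpg_id, flag = flag,
                                    stringsAsFactors = FALSE)),
    class = "consistency_summary"
  )
}

#' @export
print.consistency_summary <- function(x, ...) {
  cat(sprintf("%s: %d / %d CpGs directionally consistent (one-sided binomial p = %.3g)\n",
              x$analysis_label, x$k_consistent, x$n_total,
              x$binomial_p_one_sided))
  invisible(x)
}

#' Bind consistency summaries into one table
#'
#' @param ... `consistency_summary` objects (or a single list of them).
#' @return data.frame with `analysis_label`, `k_consistent`, `n_total`,
#'   `consistent_fraction`, `binomial_p`.
#' @export
consistency_table <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "consistency_summary")) xs <- xs[[1]]
  do.call(rbind, lapply(xs, function(x) data.frame(
    analysis_label = x$analysis_label, k_consistent = x$k_consistent,
    n_total = x$n_total,
    consistent_fraction = x$k_consistent / x$n_total,
    binomial_p = x$binomial_p_one_sided, stringsAsFactors = FALSE)))
}
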