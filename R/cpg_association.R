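#' Covariate sets for each predictor model
#'
#' The covariate sets are fixed declaratively, mirroring the analysis plan:
#' every regression adjusts for age, sex, methylation batch, and smoking
#' status; combined two-cohort analyses (genetic predictors) additionally
#' adjust for cohort; DMA%-based predictors (cohort-1 only, where arsenic
#' speciation is measured) additionally adjust for BMI, years of education
#' and log water arsenic; the log-DMA model further adjusts for log urinary
#' arsenic and log urinary creatinine.
#'
#' @param predictor one of `dma_pct`, `log_dma`, `gp_dma`, `binary_score`,
#'   `snp_carrier:<id>`, `snp_additive:<id>`.
#' @return character vector of covariate names.
#' @export
model_covariates <- function(predictor) {
  base <- c("age", "sex", "batch", "smoking")
  kind <- sub(":.*$", "", predictor)
  switch(kind,
    dma_pct = c(base, "bmi", "education", "log_water_as"),
    log_dma = c(base, "bmi", "education", "log_water_as",
                "log_urinary_as", "log_creatinine"),
    gp_dma = ,
    binary_score = ,
    snp_carrier = ,
    snp_additive = c(base, "cohort"),
    stop("unknown predictor: ", predictor, call. = FALSE)
  )
}

#' Declare a per-CpG association model
#'
#' @param predictor predictor name (see [model_covariates()]).
#' @param covariates covariate names; defaults to the declarative set for
#'   the predictor. The predictor may not appear among the covariates.
#' @param cohort_restriction `"combined"` or `"cohort1_only"`; defaults to
#'   cohort-1-only for the measured-phenotype predictors (DMA% models) and
#'   combined for genetic predictors.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(predictor,
                       covariates = model_covariates(predictor),
                       cohort_restriction = NULL) {
  kind <- sub(":.*$", "", predictor)
  if (is.null(cohort_restriction)) {
    cohort_restriction <- if (kind %in% c("dma_pct", "log_dma"))
      "cohort1_only" else "combined"
  }
  assert_that(cohort_restriction %in% c("combined", "cohort1_only"),
              "cohort_restriction must be 'combined' or 'cohort1_only'")
  assert_that(!(predictor %in% covariates),
              "predictor may not also appear among the covariates")
  structure(list(predictor = predictor, covariates = covariates,
                 cohort_restriction = cohort_restriction),
            class = "model_spec")
}

#' Ordinary-least-squares fit of one CpG on a predictor with covariates
#'
#' Homoskedastic OLS of a methylation outcome (beta-values) on a predictor
#' plus covariates. The standard error, t statistic and two-sided p-value
#' for the predictor slope use the t distribution with `n - p` degrees of
#' freedom. Complete cases only; the design must be full rank.
#'
#' @param y numeric outcome vector (beta-values for one CpG).
#' @param predictor numeric predictor vector.
#' @param covariates optional data.frame of covariates (factors encoded via
#'   treatment contrasts).
#' @param cpg_id label carried into the result.
#' @return one-row data.frame: `cpg_id`, `predictor`, `beta`, `se`, `t`,
#'   `p`, `n_used`.
#' @export
fit_cpg_model <- function(y, predictor, covariates = NULL, cpg_id = "cpg") {
  df <- data.frame(.pred = predictor)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  keep <- stats::complete.cases(df) & !is.na(y)
  X <- stats::model.matrix(~ ., data = df[keep, , drop = FALSE])
  fit <- ols_multi(X, matrix(y[keep], ncol = 1), target = ".pred")
  data.frame(cpg_id = cpg_id, predictor = ".pred", beta = fit$beta,
             se = fit$se, t = fit$t, p = fit$p, n_used = fit$n_used,
             stringsAsFactors = FALSE)
}

# Multi-outcome OLS sharing one design matrix. Y is n x m (one column per
# CpG); returns slope/se/t/p for the design column whose name starts with
# `target`.
ols_multi <- function(X, Y, target) {
  n <- nrow(X); p <- ncol(X)
  assert_that(n > p, sprintf(
    "too few complete cases (n = %d) for %d model parameters", n, p))
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  j <- grep(paste0("^", target), colnames(X))
  assert_that(length(j) == 1L, paste("target column not found uniquely:", target))
  coefs <- qr.coef(qx, Y)                        # p x m
  resid <- Y - X %*% coefs
  df_resid <- n - p
  s2 <- colSums(resid^2) / df_resid
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  jj <- numeric(p); jj[qx$pivot] <- diag(xtx_inv)
  se <- sqrt(s2 * jj[j])
  beta <- coefs[j, ]
  tstat <- beta / se
  list(beta = unname(beta), se = unname(se), t = unname(tstat),
       p = unname(2 * stats::pt(-abs(tstat), df_resid)),
       n_used = n, df_resid = df_resid)
}

# Build the predictor column(s) and covariate frame for a model_spec.
# Returns list(pred, covars, label); `extra` are additional adjustment
# columns (the jointly modelled LD partner for 10q24.32 carrier analyses).
build_model_frame <- function(cohort, spec, scores = NULL,
                              weights = default_snp_weights(),
                              ld_pair = c("rs9527", "rs11191527")) {
  s <- cohort$samples
  if (is.null(scores)) scores <- compute_scores(cohort$genotype, weights)
  stopifnot(identical(scores$sample_id, s$sample_id))
  kind <- sub(":.*$", "", spec$predictor)
  snp <- if (grepl(":", spec$predictor)) sub("^[^:]*:", "", spec$predictor) else NULL

  covar_pool <- data.frame(
    age = s$age, sex = s$sex, batch = factor(s$batch),
    smoking = factor(s$smoking, levels = c("never", "former", "current")),
    cohort = factor(s$cohort), bmi = s$bmi, education = s$education,
    log_water_as = log(s$water_as), log_urinary_as = log(s$urinary_as),
    log_creatinine = log(s$urinary_creatinine)
  )
  unknown <- setdiff(spec$covariates, names(covar_pool))
  assert_that(length(unknown) == 0L,
              paste("unknown covariate(s):", paste(unknown, collapse = ", ")))
  covars <- covar_pool[spec$covariates]

  pred <- switch(kind,
    dma_pct = s$dma_pct,
    log_dma = log(s$dma_pct / 100 * s$urinary_as),
    gp_dma = scores$gp_dma,
    binary_score = scores$binary_score,
    snp_carrier = carrier_predictor(cohort$genotype, snp),
    snp_additive = genotype_column(cohort$genotype, snp),
    stop("unknown predictor kind: ", kind, call. = FALSE)
  )

  # the two correlated 10q24.32 SNPs are modelled jointly in single-SNP
  # carrier analyses; the reported slope is for the named SNP
  if (kind == "snp_carrier" && snp %in% ld_pair) {
    partner <- setdiff(ld_pair, snp)
    if (partner %in% colnames(cohort$genotype)) {
      covars[[paste0("carrier_", partner)]] <-
        carrier_predictor(cohort$genotype, partner)
    }
  }
  if (spec$cohort_restriction == "cohort1_only") {
    keep <- s$cohort == 0
    pred <- pred[keep]
    covars <- covars[keep, , drop = FALSE]
    covars$cohort <- NULL
    meth_cols <- keep
  } else {
    meth_cols <- rep(TRUE, nrow(s))
  }
  list(pred = pred, covars = droplevels(covars), meth_cols = meth_cols)
}

genotype_column <- function(genotype, snp) {
  assert_that(snp %in% colnames(genotype), paste("SNP not in genotypes:", snp))
  genotype[, snp]
}

# Binary coding "for higher effect allele count": rare-homozygote class is
# collapsed into the heterozygotes. When the effect allele is the major
# allele the indicator is homozygous-effect (count == 2); when it is the
# minor allele the indicator is carrier (count >= 1).
carrier_predictor <- function(genotype, snp) {
  x <- genotype_column(genotype, snp)
  eaf <- mean(x, na.rm = TRUE) / 2
  if (eaf > 0.5) as.integer(x == 2) else as.integer(x >= 1)
}

#' Run a per-CpG association analysis across a CpG panel
#'
#' Fits [fit_cpg_model()] for every CpG in `cpg_ids` under one model
#' specification, sharing a single design factorization across CpGs.
#' Complete cases are determined once from the predictor and covariates
#' (the methylation matrix is assumed complete per sample). Unknown CpG ids
#' are skipped with a warning.
#'
#' @param cohort a `cohort_table` ([simulate_cohort()] / [load_cohort()]).
#' @param spec a [model_spec()] (or predictor name, converted with defaults).
#' @param cpg_ids CpGs to analyse; default all rows of the methylation
#'   matrix.
#' @param scores optional precomputed [compute_scores()] table.
#' @param weights SNP weights used if scores must be computed.
#' @return data.frame with one row per CpG: `cpg_id`, `predictor`, `beta`,
#'   `se`, `t`, `p`, `n_used`.
#' @export
run_analysis <- function(cohort, spec, cpg_ids = NULL, scores = NULL,
                         weights = default_snp_weights()) {
  if (is.character(spec)) spec <- model_spec(spec)
  meth <- cohort$methylation
  if (is.null(cpg_ids)) cpg_ids <- rownames(meth)
  unknown <- setdiff(cpg_ids, rownames(meth))
  if (length(unknown) > 0) {
    warning(length(unknown), " unknown CpG id(s) skipped: ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ..." else "")
    cpg_ids <- setdiff(cpg_ids, unknown)
  }
  assert_that(length(cpg_ids) > 0, "no known CpG ids to analyse")

  mf <- build_model_frame(cohort, spec, scores = scores, weights = weights)
  Y_all <- t(meth[cpg_ids, mf$meth_cols, drop = FALSE])   # n x m
  df <- cbind(data.frame(.pred = mf$pred), mf$covars)
  keep <- stats::complete.cases(df)
  X <- stats::model.matrix(~ ., data = df[keep, , drop = FALSE])
  fit <- ols_multi(X, Y_all[keep, , drop = FALSE], target = ".pred")
  data.frame(cpg_id = cpg_ids, predictor = spec$predictor, beta = fit$beta,
             se = fit$se, t = fit$t, p = fit$p, n_used = fit$n_used,
             stringsAsFactors = FALSE)
}

#' Per-SNP additive association summaries for use as MR instrument outcomes
#'
#' For each instrument SNP, regresses every CpG on the effect-allele count
#' (additive coding) with the base + cohort covariate set, yielding the
#' SNP-to-methylation effects and standard errors that the two-sample MR
#' stage combines with the SNP-to-DMA% weights.
#'
#' @param cohort a `cohort_table`.
#' @param snp_ids SNPs to fit; default all genotype columns.
#' @param cpg_ids CpGs; default all.
#' @return data.frame with `cpg_id`, `snp_id`, `beta`, `se`, `n_used`.
#' @export
snp_outcome_associations <- function(cohort, snp_ids = colnames(cohort$genotype),
                                     cpg_ids = NULL) {
  res <- lapply(snp_ids, function(snp) {
    a <- run_analysis(cohort, model_spec(paste0("snp_additive:", snp)),
                      cpg_ids = cpg_ids)
    data.frame(cpg_id = a$cpg_id, snp_id = snp, beta = a$beta, se = a$se,
               n_used = a$n_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
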