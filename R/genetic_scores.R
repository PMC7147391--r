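#' Weighted genetically predicted DMA% score
#'
#' For each sample, the score is the exact dot product of the per-allele
#' DMA% weights with the effect-allele counts:
#' \deqn{GP\text{-}DMA\% = \sum_j \beta_{Xj} X_j}
#' with no intercept and no normalization, so the score measures the
#' predicted increase in DMA% relative to a baseline individual carrying
#' zero high-efficiency alleles (whose score is 0).
#'
#' Counts must be coded on the same effect allele as the weights. Samples
#' with any missing genotype get `NA` (complete-case handling is left to the
#' analysis stage; genotypes are never imputed).
#'
#' @param genotypes matrix or data.frame of effect-allele counts in {0,1,2},
#'   columns named by snp_id (a single row may be given as a named vector).
#' @param weights a `snp_weights` table ([read_snp_weights()]).
#' @return numeric vector of scores, one per sample.
#' @export
weighted_score <- function(genotypes, weights) {
  g <- as_genotype_matrix(genotypes, weights$snp_id)
  drop(g %*% weights$beta_dma)
}

as_genotype_matrix <- function(genotypes, snp_ids) {
  if (is.null(dim(genotypes))) {
    genotypes <- matrix(genotypes, nrow = 1,
                        dimnames = list(NULL, names(genotypes)))
  }
  g <- as.matrix(genotypes)
  missing_snps <- setdiff(snp_ids, colnames(g))
  assert_that(length(missing_snps) == 0L,
              paste("genotype table lacks SNP(s):",
                    paste(missing_snps, collapse = ", ")))
  g <- g[, snp_ids, drop = FALSE]
  ok <- is.na(g) | (g %in% c(0, 1, 2))
  assert_that(all(ok), "genotype entries must be effect-allele counts in {0,1,2} or NA")
  storage.mode(g) <- "double"
  g
}

#' Binary high-efficiency-carrier score
#'
#' A weight-free sensitivity score: 1 if and only if the sample is
#' homozygous for the high-efficiency allele at BOTH rs9527 and rs61735836
#' (i.e., carries only high-efficiency alleles at the two large-effect,
#' low-minor-allele-frequency instruments), else 0. rs11191527 is ignored.
#' Missing genotypes at either SNP yield `NA`.
#'
#' @param genotypes as in [weighted_score()]; must contain columns for the
#'   two SNPs.
#' @param snps the two SNP ids forming the score.
#' @return integer vector of 0/1 (or NA) per sample.
#' @export
binary_score <- function(genotypes, snps = c("rs9527", "rs61735836")) {
  assert_that(length(snps) == 2L, "binary_score uses exactly two SNPs")
  g <- as_genotype_matrix(genotypes, snps)
  as.integer(g[, 1L] == 2 & g[, 2L] == 2)
}

#' Collapse an allele count to minor-allele-carrier coding
#'
#' Minor-allele homozygotes are merged with heterozygotes into a single
#' "minor allele carrier" class, as is standard when homozygotes are rare.
#' The orientation must be resolved by the caller (e.g., from the sample
#' allele frequency): when the count is coded on the minor allele
#' (`minor_is_effect = TRUE`) a carrier is anyone with count >= 1; when the
#' count is coded on the major allele, a carrier of the minor allele is
#' anyone with count <= 1.
#'
#' @param count vector of allele counts in {0,1,2} (NA allowed).
#' @param minor_is_effect is the counted allele the minor allele?
#' @return integer 0/1 vector: 1 = carries at least one minor allele.
#' @export
carrier_collapse <- function(count, minor_is_effect) {
  ok <- is.na(count) | count %in% c(0, 1, 2)
  assert_that(all(ok), "counts must be in {0,1,2} or NA")
  if (minor_is_effect) as.integer(count >= 1) else as.integer(count <= 1)
}

#' Compute both genetic scores for a cohort
#'
#' @param genotypes sample x SNP effect-allele count matrix (rownames =
#'   sample ids) or data.frame with a `sample_id` column.
#' @param weights a `snp_weights` table; defaults to the shipped synthetic
#'   weights.
#' @return data.frame with `sample_id`, `gp_dma`, `binary_score`. Samples
#'   with missing genotypes have `NA` in the affected score.
#' @export
compute_scores <- function(genotypes, weights = default_snp_weights()) {
  if (is.data.frame(genotypes) && "sample_id" %in% names(genotypes)) {
    ids <- genotypes$sample_id
    genotypes <- as.matrix(genotypes[setdiff(names(genotypes), "sample_id")])
    rownames(genotypes) <- ids
  }
  ids <- rownames(genotypes) %||% sprintf("S%04d", seq_len(nrow(genotypes)))
  data.frame(
    sample_id = ids,
    gp_dma = weighted_score(genotypes, weights),
    binary_score = binary_score(genotypes),
    stringsAsFactors = FALSE
  )
}
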