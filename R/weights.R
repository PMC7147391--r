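#' Read a SNP weights file
#'
#' A weights file is a tab-separated table with columns `snp_id`,
#' `effect_allele`, `beta_dma` (percentage points DMA% per effect-allele
#' copy) and `se` (> 0); lines starting with `#` are header commentary and
#' are skipped. Counts in genotype tables fed to the scoring functions must
#' be coded on the same effect (high-efficiency) allele.
#'
#' @param path path to a weights TSV.
#' @return data.frame of class `snp_weights`.
#' @export
read_snp_weights <- function(path) {
  w <- utils::read.delim(path, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  needed <- c("snp_id", "effect_allele", "beta_dma", "se")
  missing_cols <- setdiff(needed, names(w))
  assert_that(length(missing_cols) == 0L,
              paste("weights file lacks column(s):",
                    paste(missing_cols, collapse = ", ")))
  assert_that(!anyDuplicated(w$snp_id), "duplicate snp_id in weights file")
  assert_that(all(w$se > 0), "all weight standard errors must be > 0")
  class(w) <- c("snp_weights", "data.frame")
  w
}

#' The package's shipped synthetic default weights
#'
#' Loads the weights file installed with the package. These values are
#' synthetic plausible stand-ins (see the file header and the methods
#' vignette), calibrated so the maximum weighted score is 17.4 percentage
#' points; they are suitable for simulation studies, not for real-data
#' inference.
#'
#' @return data.frame of class `snp_weights`.
#' @export
default_snp_weights <- function() {
  read_snp_weights(system.file("extdata", "snp_weights_synthetic.tsv",
                               package = "dmamr", mustWork = TRUE))
}
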