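#' Load a cohort from a directory of plain-text tables
#'
#' Reads `genotypes.tsv`, `covariates.tsv`, `methylation.tsv` (and
#' `truth.tsv` if present) as written by [write_cohort()], inner-joining on
#' sample id. Per-file sample counts and the overlap are reported; analyses
#' downstream apply complete-case filtering per predictor, so samples
#' missing one SNP are excluded only from analyses needing that SNP.
#'
#' @param dir directory containing the tables.
#' @return a `cohort_table`.
#' @export
load_cohort <- function(dir) {
  g <- read_tsv(file.path(dir, "genotypes.tsv"))
  s <- read_tsv(file.path(dir, "covariates.tsv"))
  m <- read_tsv(file.path(dir, "methylation.tsv"))
  for (d in list(g = g, s = s)) {
    assert_that(!anyDuplicated(d$sample_id), "duplicated sample ids")
  }
  meth_ids <- setdiff(colnames(m), "cpg_id")
  common <- Reduce(intersect, list(g$sample_id, s$sample_id, meth_ids))
  message(sprintf(
    "load_cohort: %d genotype, %d covariate, %d methylation samples; %d overlap",
    nrow(g), nrow(s), length(meth_ids), length(common)))
  assert_that(length(common) >= 2, "fewer than 2 overlapping samples across files")

  s <- s[match(common, s$sample_id), , drop = FALSE]
  s$smoking <- factor(s$smoking, levels = c("never", "former", "current"))
  s$batch <- factor(s$batch)
  geno <- as.matrix(g[match(common, g$sample_id),
                      setdiff(colnames(g), "sample_id"), drop = FALSE])
  rownames(geno) <- common
  meth <- as.matrix(m[, common, drop = FALSE])
  rownames(meth) <- m$cpg_id
  truth <- NULL
  tp <- file.path(dir, "truth.tsv")
  if (file.exists(tp)) truth <- read_tsv(tp)
  structure(list(samples = s, genotype = geno, methylation = meth,
                 truth = truth), class = "cohort_table")
}

#' Read effect-allele genotype counts from a VCF file
#'
#' Convenience ingestion of a VCF 4.2 file with GT fields: counts the
#' effect allele per sample for each SNP in the weights table, matching
#' records by ID and orienting counts on the weights' effect allele (REF or
#' ALT). Requires the `vcfR` package.
#'
#' @param path VCF path (plain or bgzipped).
#' @param weights `snp_weights` table giving snp ids and effect alleles.
#' @return sample x SNP matrix of effect-allele counts (NA for missing GT).
#' @export
genotypes_from_vcf <- function(path, weights = default_snp_weights()) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("genotypes_from_vcf requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  idx <- match(weights$snp_id, fix[, "ID"])
  assert_that(!anyNA(idx), paste("VCF lacks SNP(s):",
              paste(weights$snp_id[is.na(idx)], collapse = ", ")))
  out <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(weights),
                dimnames = list(colnames(gt), weights$snp_id))
  for (j in seq_len(nrow(weights))) {
    row <- idx[j]
    alt_count <- vapply(strsplit(gt[row, ], "[/|]"), function(a) {
      if (anyNA(a) || any(a == ".")) return(NA_integer_)
      sum(a != "0")
    }, integer(1))
    effect_is_alt <- isTRUE(weights$effect_allele[j] == fix[row, "ALT"])
    effect_is_ref <- isTRUE(weights$effect_allele[j] == fix[row, "REF"])
    assert_that(effect_is_alt || effect_is_ref, paste(
      "effect allele of", weights$snp_id[j], "matches neither REF nor ALT"))
    out[, j] <- if (effect_is_alt) alt_count else 2L - alt_count
  }
  out
}

#' Write genotypes as a minimal VCF 4.2 file
#'
#' One record per SNP with GT-only FORMAT; counts are interpreted as ALT
#' (= effect allele) dosages. Placeholder CHROM/POS are used since the
#' simulator carries no genomic coordinates.
#'
#' @param genotype sample x SNP effect-allele count matrix.
#' @param weights `snp_weights` table supplying allele labels.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_genotypes_vcf <- function(genotype, weights, path) {
  ids <- rownames(genotype)
  gt_string <- function(x) c("0/0", "0/1", "1/1")[x + 1L]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  for (j in seq_len(nrow(weights))) {
    snp <- weights$snp_id[j]
    assert_that(snp %in% colnames(genotype),
                paste("genotype matrix lacks", snp))
    counts <- genotype[, snp]
    gt <- ifelse(is.na(counts), "./.", gt_string(replace(counts, is.na(counts), 0L)))
    lines <- c(lines, paste(c("1", as.character(1000L + j), snp,
                              weights$other_allele[j] %||% "A",
                              weights$effect_allele[j], ".", "PASS", ".",
                              "GT", gt), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Run the full triangulation pipeline on one synthetic cohort
#'
#' Executes simulate -> score -> associate -> MR -> directional consistency
#' as a single reproducible run: simulates a cohort and a prior-EWAS table,
#' computes both genetic scores, fits the five predictor models (DMA%,
#' log-DMA, weighted score, binary score, and carrier-coded single SNPs),
#' computes IVW and maximum-likelihood MR estimates from the per-SNP
#' summary statistics, and summarizes directional consistency of every
#' analysis against the EWAS signs. Stage outputs are written as TSVs with
#' a JSON manifest recording the config hash, seed and file digests.
#'
#' @param config a [sim_config()] or the path to a YAML config file.
#' @param out_dir output directory; created if needed. `NULL` skips all
#'   file output.
#' @param seed optional integer overriding the config's seed.
#' @param weights `snp_weights` used for scoring and MR. The default is the
#'   matching generative weights derived from the config's snp_specs, so
#'   that the two-sample structure uses the same instrument effects that
#'   generated the data.
#' @param tier optional EWAS tier restriction applied in a second pass
#'   (e.g. `"bonferroni_set"`); adds `*_bonferroni` analysis labels.
#' @return a list of class `pipeline_run` with `summary` (the per-analysis
#'   consistency table), `consistency` (the summary objects), `mr`
#'   (per-CpG MR estimates), `associations`, `cohort`, `ewas`, and
#'   `manifest`.
#' @export
run_all <- function(config = sim_config(), out_dir = NULL, seed = NULL,
                    weights = NULL, tier = "bonferroni_set") {
  if (is.character(config)) config <- read_sim_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(weights)) weights <- weights_from_config(config)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cohort <- run_stage("simulate", simulate_cohort(config))
  ewas <- run_stage("simulate", simulate_ewas_table(cohort$truth,
                                                    seed = config$seed))
  scores <- run_stage("score", compute_scores(cohort$genotype, weights))

  predictors <- c("dma_pct", "log_dma", "gp_dma", "binary_score",
                  paste0("snp_carrier:", colnames(cohort$genotype)))
  assoc <- run_stage("associate", {
    res <- lapply(predictors, function(p)
      run_analysis(cohort, model_spec(p), scores = scores, weights = weights))
    names(res) <- predictors
    res
  })
  snp_assoc <- run_stage("associate", snp_outcome_associations(cohort))
  mr <- run_stage("mr", mr_analysis(snp_assoc, weights,
                                    methods = c("ivw", "ml")))

  cons <- run_stage("consistency", {
    out <- lapply(predictors, function(p)
      summarize_consistency(assoc[[p]], ewas, label = p))
    names(out) <- predictors
    for (m in c("ivw", "ml")) {
      est <- mr[mr$method == m, , drop = FALSE]
      out[[m]] <- summarize_consistency(est, ewas, label = m)
    }
    if (!is.null(tier) && any(ewas$tier == tier)) {
      for (p in c("gp_dma", "binary_score", "ivw")) {
        est <- if (p == "ivw") mr[mr$method == "ivw", , drop = FALSE] else assoc[[p]]
        lbl <- paste0(p, "_bonferroni")
        out[[lbl]] <- summarize_consistency(est, ewas, label = lbl, tier = tier)
      }
    }
    out
  })
  summary_tab <- consistency_table(cons)

  manifest <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- write_cohort(cohort, out_dir)
    write_tsv(ewas, file.path(out_dir, "ewas.tsv"))
    write_tsv(scores, file.path(out_dir, "scores.tsv"))
    write_tsv(do.call(rbind, assoc), file.path(out_dir, "associations.tsv"))
    write_tsv(snp_assoc, file.path(out_dir, "snp_associations.tsv"))
    write_tsv(mr, file.path(out_dir, "mr_estimates.tsv"))
    write_tsv(summary_tab, file.path(out_dir, "consistency_summary.tsv"))
    flags <- do.call(rbind, lapply(cons, function(x)
      cbind(analysis_label = x$analysis_label, x$per_cpg_flags)))
    write_tsv(flags, file.path(out_dir, "consistency_flags.tsv"))
    stage_outputs <- c(paths, ewas = file.path(out_dir, "ewas.tsv"),
                       scores = file.path(out_dir, "scores.tsv"),
                       associations = file.path(out_dir, "associations.tsv"),
                       snp_associations = file.path(out_dir, "snp_associations.tsv"),
                       mr = file.path(out_dir, "mr_estimates.tsv"),
                       consistency = file.path(out_dir, "consistency_summary.tsv"))
    manifest <- list(
      config_hash = config_hash(config),
      seed = config$seed,
      stage_outputs = as.list(stage_outputs),
      output_md5 = as.list(tools::md5sum(unname(stage_outputs))),
      versions = list(
        dmamr = as.character(utils::packageVersion("dmamr")),
        weights = attr(weights, "version") %||% "config-derived"),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    manifest <- list(config_hash = config_hash(config), seed = config$seed)
  }

  structure(list(summary = summary_tab, consistency = cons, mr = mr,
                 associations = assoc, snp_associations = snp_assoc,
                 scores = scores, cohort = cohort, ewas = ewas,
                 manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Arsenic-metabolism MR triangulation run (seed ",
      x$manifest$seed, ")\n\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Derive the generative SNP weights table from a simulation config
#'
#' Two-sample MR on a simulated cohort uses the exposure-side effects that
#' actually generated DMA%; this mirrors taking published weights from a
#' prior genome-wide study of the exposure.
#'
#' @param config a [sim_config()].
#' @return a `snp_weights` data.frame.
#' @export
weights_from_config <- function(config) {
  w <- do.call(rbind, lapply(config$snp_specs, function(s) data.frame(
    snp_id = s$snp_id, effect_allele = s$effect_allele,
    other_allele = s$other_allele, beta_dma = s$beta_dma,
    se = s$se_beta_dma, effect_allele_freq = s$effect_allele_freq,
    stringsAsFactors = FALSE)))
  class(w) <- c("snp_weights", "data.frame")
  attr(w, "version") <- "config-derived"
  w
}

# Content hash of a config: stable digest of the deparsed, class-stripped
# object via tools::md5sum on a temporary dump.
config_hash <- function(config) {
  x <- unclass(config)
  x$snp_specs <- lapply(x$snp_specs, unclass)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(x[order(names(x))]), tf)
  unname(tools::md5sum(tf))
}
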