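#' Run the full eQTL analysis pipeline
#'
#' Orchestrates, in order: sample depth filter, variant QC, exon filter and
#' normalization, latent-covariate inference, cis scan, adaptive
#' permutation with Storey q-values, effector-transcript nomination at GWAS
#' loci, chromatin enrichment of significant index variants, and (when ASE
#' counts are supplied) the allelic-imbalance report.  All module tables
#' are written as TSV under \code{config$out_dir} together with a run log
#' recording the package version, seeds and per-filter attrition; reruns
#' with the same config and seed are byte-identical.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return invisible list with every intermediate and final table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("isleteqtl run, package version %s",
                         as.character(utils::packageVersion("isleteqtl"))),
                 sprintf("master seed: %d", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  gm <- stage("read_genotypes", read_vcf_dosages(config$vcf))
  ec <- stage("read_counts", read_exon_table(config$counts))

  keep <- stage("filter_samples",
                filter_samples(ec, config$min_mapped_reads))
  assert_that(length(keep) >= 2, "pipeline: fewer than 2 samples pass the depth filter")
  common <- intersect(keep, rownames(gm$dosages))
  log_lines <- c(log_lines,
                 sprintf("samples: %d in counts, %d pass depth filter, %d with genotypes",
                         ncol(ec$counts), length(keep), length(common)))
  ec <- exon_counts(ec$counts[, common, drop = FALSE], ec$exons)
  gm$dosages <- gm$dosages[common, , drop = FALSE]
  sex <- config$sex
  if (!is.null(sex)) {
    assert_that(!is.null(names(sex)) || length(sex) == length(common),
                "pipeline: sex indicator must be named or aligned with retained samples")
    if (!is.null(names(sex))) sex <- sex[common]
  }

  n_var0 <- ncol(gm$dosages)
  gm <- stage("variant_qc", filter_variants(
    gm, config$min_call_rate, config$pre_imputation_maf, config$hwe_alpha,
    config$min_info, config$analysis_maf))
  qc_report <- attr(gm, "qc_report")
  log_lines <- c(log_lines,
                 sprintf("variants: %d read, %d pass QC", n_var0, ncol(gm$dosages)))

  n_ex0 <- nrow(ec$counts)
  ec <- stage("filter_exons", filter_exons(
    ec, config$max_zero_samples, mode = config$exon_filter_mode,
    min_nonzero_fraction = config$min_nonzero_fraction))
  log_lines <- c(log_lines,
                 sprintf("exons: %d read, %d pass expression filter",
                         n_ex0, nrow(ec$counts)))
  norm <- stage("normalize", normalize_expression(ec))
  covs <- stage("covariates",
                infer_hidden_factors(norm, k = min(config$k_factors,
                                                   length(common) - 1L),
                                     sex = sex))

  scan <- stage("cis_scan", map_cis_eqtl(norm, gm, covs, config$flank))
  perm <- stage("permutation", permute_study(
    norm, gm, scan, covs, config$flank, config$min_perm, config$max_perm,
    config$stop_exceedances, config$perm_batch,
    seed = child_seed(config$seed, 10)))
  fdr <- stage("fdr", fdr_table(perm, config$q_threshold,
                                config$nominal_threshold))
  log_lines <- c(log_lines,
                 sprintf("pi0 estimate: %.4f; study-wide significant exons: %d",
                         attr(fdr, "pi0"), sum(fdr$significant)))

  chromatin <- if (!is.null(config$bed))
    stage("read_chromatin", read_bed_states(config$bed)) else NULL
  effectors <- NULL
  if (!is.null(config$gwas)) {
    gwas <- stage("read_gwas", read_gwas_leads(config$gwas))
    effectors <- stage("nominate", nominate_effectors(
      fdr, gwas, norm, gm, covs, chromatin, config$r2_min,
      config$coloc_alpha, config$q_threshold, config$nominal_threshold,
      config$flank))
    log_lines <- c(log_lines,
                   sprintf("GWAS loci: %d; effector calls: %d",
                           nrow(gwas), nrow(effectors)))
  }

  enrichment <- NULL
  if (!is.null(chromatin)) {
    sig <- fdr[fdr$significant, , drop = FALSE]
    nonsig <- fdr[!fdr$significant, , drop = FALSE]
    if (nrow(sig) >= 1 && nrow(nonsig) >= nrow(sig)) {
      v <- gm$variants
      fg <- v[match(unique(sig$index_variant), v$id), , drop = FALSE]
      bg <- v[match(unique(setdiff(nonsig$index_variant, sig$index_variant)),
                    v$id), , drop = FALSE]
      if (nrow(bg) >= nrow(fg))
        enrichment <- stage("enrichment", enrichment_test(
          fg, bg, chromatin, n_samplings = config$n_samplings,
          seed = child_seed(config$seed, 20)))
    }
  }

  ase_tab <- NULL
  if (!is.null(config$ase)) {
    ase_counts <- stage("read_ase", read_ase_counts(config$ase))
    ase_tab <- stage("ase", ase_report(ase_counts, config$min_ase_depth))
  }

  out <- function(x, name) {
    if (!is.null(x))
      data.table::fwrite(x, file.path(config$out_dir, name), sep = "\t")
  }
  out(qc_report, "variant_qc.tsv")
  out(data.frame(sample = common), "samples_retained.tsv")
  out(fdr, "fdr_table.tsv")
  out(effectors, "effector_report.tsv")
  if (!is.null(enrichment))
    out(data.frame(n_fg = enrichment$n_fg,
                   n_fg_overlap = enrichment$n_fg_overlap,
                   n_bg = enrichment$n_bg,
                   n_bg_overlap = enrichment$n_bg_overlap,
                   fold = enrichment$fold, fisher_p = enrichment$fisher_p,
                   resampling_p = enrichment$resampling_p,
                   n_samplings = enrichment$n_samplings),
        "enrichment.tsv")
  out(ase_tab, "ase_report.tsv")
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(genotypes = gm, counts = ec, normalized = norm,
                 covariates = covs, qc_report = qc_report, scan = scan,
                 fdr = fdr, effectors = effectors, enrichment = enrichment,
                 ase = ase_tab, log = log_lines))
}
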