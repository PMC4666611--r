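# Builders for small synthetic studies shared across test files.

# One gene per LD block, blocks laid out so each 1 Mb cis window holds
# exactly its own block of variants.
study_config <- function(n_samples = 200, n_genes = 10, n_exons = 1,
                         n_variants = 50, target_r2 = 0.95, maf = 0.3,
                         planted_genes = integer(), beta = 1,
                         n_hidden_factors = 0, factor_sd = 0.5,
                         seed = 1L, ...) {
  blocks <- replicate(n_genes,
                      list(n_variants = n_variants, target_r2 = target_r2,
                           maf = maf), simplify = FALSE)
  genes <- lapply(seq_len(n_genes), function(i)
    list(gene_id = sprintf("G%03d", i), n_exons = n_exons,
         tss = (i - 1) * 2.5e6 + 1.2e6, strand = "+"))
  planted <- if (length(planted_genes))
    data.frame(gene = sprintf("G%03d", planted_genes),
               variant = sprintf("G%03d_v%02d", planted_genes,
                                 ceiling(n_variants / 2)),
               beta = beta)
  else data.frame(gene = character(), variant = character(),
                  beta = numeric())
  sim_config(n_samples = n_samples, ld_blocks = blocks, genes = genes,
             planted_eqtls = planted, n_hidden_factors = n_hidden_factors,
             factor_sd = factor_sd, seed = seed, ...)
}

# Simulate, normalize and scan a study; returns every intermediate.
run_study <- function(cfg, k = cfg$n_hidden_factors) {
  gm <- simulate_genotypes(cfg)
  se <- simulate_expression(gm, cfg)
  ec <- filter_exons(se$counts)
  norm <- normalize_expression(ec)
  covs <- infer_hidden_factors(norm, k = k)
  scan <- map_cis_eqtl(norm, gm, covs)
  list(cfg = cfg, gm = gm, truth = se$truth, counts = ec, norm = norm,
       covs = covs, scan = scan)
}
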