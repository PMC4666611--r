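test_that("genotype simulation is deterministic and honors block structure", {
  cfg <- study_config(n_samples = 50, n_genes = 3, n_variants = 8, seed = 9)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$variants, g2$variants)
  expect_true(all(g1$dosages %in% 0:2))
  # target_r2 = 1: every block variant is a copy of the founder
  cfg1 <- study_config(n_samples = 60, n_genes = 1, n_variants = 6,
                       target_r2 = 1.0, seed = 10)
  gm1 <- simulate_genotypes(cfg1)
  r2 <- cor(gm1$dosages)^2
  expect_true(all(abs(r2[upper.tri(r2)] - 1) < 1e-12))
  expect_error(study_config(maf = 0.7), "maf")
})

test_that("realized MAF and within-block r2 converge to their targets at n = 10000", {
  cfg <- study_config(n_samples = 10000, n_genes = 2, n_variants = 10,
                      target_r2 = 0.9, maf = 0.3, seed = 12)
  gm <- simulate_genotypes(cfg)
  mafs <- apply(gm$dosages, 2, compute_maf)
  expect_true(all(abs(mafs - 0.3) < 0.02))
  G <- gm$dosages[, 1:10]
  r2 <- cor(G)^2
  expect_lt(abs(mean(r2[upper.tri(r2)]) - 0.9), 0.05)
})

test_that("null expression shows no genotype correlation; planted effects are recovered", {
  cfg0 <- study_config(n_samples = 150, n_genes = 10, n_exons = 2, seed = 13)
  st0 <- run_study(cfg0)
  exons <- st0$norm$exons
  rs <- vapply(seq_len(nrow(exons)), function(i) {
    blk <- match(exons$gene_id[i], sprintf("G%03d", 1:10))
    v <- st0$gm$variants$id[st0$gm$variants$block == blk][1]
    cor(st0$norm$mat[i, ], st0$gm$dosages[, v])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
  cfg_bad <- cfg0
  cfg_bad$planted_eqtls <- data.frame(gene = "G001", variant = "rs_missing",
                                      beta = 1)
  expect_error(simulate_expression(st0$gm, cfg_bad), "not in genotypes")
})

test_that("a large single hidden factor is recovered by the factor inference", {
  cfg <- study_config(n_samples = 150, n_genes = 40, n_exons = 1,
                      n_variants = 5, n_hidden_factors = 1, factor_sd = 3,
                      seed = 14)
  gm <- simulate_genotypes(cfg)
  se <- simulate_expression(gm, cfg)
  norm <- normalize_expression(filter_exons(se$counts))
  # depth renormalization of a strong multiplicative confounder leaves a
  # linear and a curvature component; the true factor must appear among
  # the top two inferred factors
  covs <- infer_hidden_factors(norm, k = 2)
  cors <- abs(cor(covs[, 1:2], se$truth$factors[1, ]))
  expect_gt(max(cors), 0.9)
})

test_that("GWAS locus simulation fulfills its LD contracts", {
  cfg <- study_config(n_samples = 300, n_genes = 4, planted_genes = 1,
                      beta = 1, seed = 15)
  st <- run_study(cfg)
  gl <- simulate_gwas_loci(st$gm, st$truth, shared = c(TRUE, FALSE))
  shared <- gl$loci[1, ]
  causal <- st$truth$planted$variant[1]
  expect_gt(compute_ld_r2(st$gm$dosages[, shared$variant],
                          st$gm$dosages[, causal]), 0.8)
  indep <- gl$loci[2, ]
  expect_lt(max(compute_ld_r2(st$gm$dosages[, indep$variant],
                              st$gm$dosages[, causal])), 0.05)
  expect_identical(gl$truth$gwas_map$locus01$type, "shared")
  expect_identical(gl$truth$gwas_map$locus02$type, "independent")
  # a perfect-LD block: the lead proxy has r2 = 1
  cfg1 <- study_config(n_samples = 100, n_genes = 2, target_r2 = 1,
                       planted_genes = 1, seed = 16)
  st1 <- run_study(cfg1)
  gl1 <- simulate_gwas_loci(st1$gm, st1$truth, shared = TRUE)
  expect_equal(compute_ld_r2(st1$gm$dosages[, gl1$loci$variant[1]],
                             st1$gm$dosages[, st1$truth$planted$variant[1]]),
               1.0)
  # single-variant block: the lead must be the planted variant, flagged
  cfg2 <- study_config(n_samples = 100, n_genes = 2, n_variants = 1,
                       planted_genes = 1, seed = 17)
  st2 <- run_study(cfg2)
  gl2 <- simulate_gwas_loci(st2$gm, st2$truth, shared = TRUE)
  expect_true(gl2$loci$identical_to_eqtl[1])
})

test_that("chromatin simulation plants the requested enrichment", {
  cfg <- study_config(n_samples = 20, n_genes = 40, n_variants = 50,
                      seed = 18)
  gm <- simulate_genotypes(cfg)
  ids <- gm$variants$id
  fg_ids <- ids[seq(1, 2000, by = 4)][1:400]
  ann <- simulate_chromatin(gm, enrichment_fold = 2, background_rate = 0.15,
                            seed = 19, eqtl_ids = fg_ids)
  fg <- gm$variants[match(fg_ids, ids), ]
  bg <- gm$variants[-match(fg_ids, ids), ]
  rate_fg <- mean(overlap_variants(fg, ann))
  rate_bg <- mean(overlap_variants(bg, ann))
  expect_lt(abs(rate_fg / rate_bg - 2), 0.6)
  # fold = 1 is a null; background = 0 gives no enhancer intervals at all
  ann_null <- simulate_chromatin(gm, enrichment_fold = 1,
                                 background_rate = 0.15, seed = 20,
                                 eqtl_ids = fg_ids)
  r1 <- mean(overlap_variants(fg, ann_null))
  r0 <- mean(overlap_variants(bg, ann_null))
  expect_lt(abs(r1 - r0), 0.08)
  ann_zero <- simulate_chromatin(gm, enrichment_fold = 2,
                                 background_rate = 0, seed = 21,
                                 eqtl_ids = fg_ids)
  expect_equal(sum(ann_zero$state == "enhancer"), 0)
  expect_error(simulate_chromatin(gm, enrichment_fold = 8,
                                  background_rate = 0.2, seed = 1),
               "exceeds 1")
})

test_that("ASE count simulation is binomial per site and valid at depth 1", {
  s <- simulate_ase_counts(5000, 0.7, 30, seed = 22)
  expect_true(all(s$ref_count + s$alt_count == 30))
  expect_lt(abs(mean(s$alt_count) / 30 - 0.7), 0.01)
  s1 <- simulate_ase_counts(10, 0.5, 1, seed = 23)
  expect_true(all(s1$alt_count %in% 0:1))
  expect_error(simulate_ase_counts(0, 0.5, 10), "n_het")
  expect_error(simulate_ase_counts(5, 1.2, 10), "allelic_fraction")
})
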