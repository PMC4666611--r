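test_that("compute_ld_r2 is symmetric in allele orientation", {
  g <- c(0, 1, 2, 0)
  expect_equal(compute_ld_r2(g, g), 1.0)
  expect_equal(compute_ld_r2(g, 2 - g), 1.0)
  expect_equal(compute_ld_r2(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0.0)
  expect_error(compute_ld_r2(g, rep(1, 4)), "constant")
})

test_that("conditional_test absorbs a shared signal and flags collinearity", {
  set.seed(51)
  n <- 100
  g <- rbinom(n, 2, 0.3)
  y <- g + rnorm(n)
  same <- conditional_test(y, g, g)
  expect_equal(same$conditional_p, 1)
  expect_true(same$collinear)
  # shared causal variant tagged by a strong proxy: signal absorbed
  flip <- rbinom(n, 1, 0.02)
  proxy <- ifelse(flip == 1, rbinom(n, 2, 0.3), g)
  ct <- conditional_test(y, proxy, g)
  expect_gt(ct$conditional_p, 0.05)
  # independent second signal is not absorbed
  g2 <- rbinom(n, 2, 0.3)
  y2 <- g + g2 + rnorm(n)
  ct2 <- conditional_test(y2, g2, g)
  expect_lt(ct2$conditional_p, 0.001)
})

test_that("conditional discrimination holds across replicates", {
  # shared arm: effector-scale effect (0.4) with the lead in near-complete LD
  # with the causal variant; independent arm: strong effect, unlinked lead
  shared_pass <- independent_reject <- logical(30)
  for (i in 1:30) {
    cfg <- study_config(n_samples = 200, n_genes = 3, n_exons = 1,
                        target_r2 = 0.98, planted_genes = 1, beta = 0.4,
                        seed = 5100 + i)
    st <- run_study(cfg)
    gl <- simulate_gwas_loci(st$gm, st$truth, shared = c(TRUE, FALSE))
    causal <- st$truth$planted$variant[1]
    y <- st$norm$mat[match("G001_e1", st$norm$exons$exon_id), ]
    g_c <- st$gm$dosages[, causal]
    shared_pass[i] <-
      conditional_test(y, g_c, st$gm$dosages[, gl$loci$variant[1]])$conditional_p > 0.05
    y_str <- y + st$gm$dosages[, causal] * 0.6   # total effect ~1 for power
    independent_reject[i] <-
      conditional_test(y_str, g_c, st$gm$dosages[, gl$loci$variant[2]])$conditional_p < 0.001
  }
  expect_gte(mean(shared_pass), 0.80)
  expect_gte(mean(independent_reject), 0.90)
})

test_that("directional_consistency counts sign agreement including the index exon", {
  b <- c(e1 = 0.2, e2 = 0.3, e3 = 0.1, e4 = -0.05)
  dc <- directional_consistency(b, "e2")
  expect_equal(dc$n_consistent, 3)
  expect_equal(dc$label, "3/4")
  allpos <- directional_consistency(c(a = 1, b = 2), "a")
  expect_equal(allpos$label, "2/2")
  expect_error(directional_consistency(b, "missing"), "index exon")
})

make_coloc_study <- function(seed = 61, shared = c(TRUE, FALSE)) {
  cfg <- study_config(n_samples = 200, n_genes = 6, n_exons = 3,
                      planted_genes = 1, beta = 1, seed = seed)
  st <- run_study(cfg)
  gl <- simulate_gwas_loci(st$gm, st$truth, shared = shared)
  perm <- permute_study(st$norm, st$gm, st$scan, st$covs,
                        min_perm = 500, max_perm = 2000, batch = 500,
                        seed = seed + 1)
  fdr <- fdr_table(perm)
  chrom <- simulate_chromatin(st$gm, st$truth, enrichment_fold = 6,
                              background_rate = 0.15, seed = seed + 2)
  list(st = st, loci = gl$loci, truth = gl$truth, fdr = fdr, chrom = chrom)
}

test_that("the nomination cascade emits the shared-causal gene and applies each gate", {
  cs <- make_coloc_study()
  calls <- nominate_effectors(cs$fdr, cs$loci, cs$st$norm, cs$st$gm,
                              cs$st$covs, cs$chrom)
  expect_true("G001" %in% calls$gene_id)
  g1 <- calls[calls$gene_id == "G001", ][1, ]
  expect_identical(g1$tier, "study_wide")
  expect_gt(g1$r2_with_lead, 0.8)
  expect_gt(g1$conditional_p, 0.05)
  expect_true(g1$chromatin_overlap_proxy)
  expect_identical(g1$risk_direction, "up")
  expect_match(g1$consistency, "^[0-9]+/3$")
  # LD gate: a lead in weak LD with the index variant yields no call even
  # though the gene is significant and nearby
  set.seed(99)
  gm_plus <- cs$st$gm
  rand_dos <- rbinom(nrow(gm_plus$dosages), 2, 0.3) + 0.0
  gm_plus$dosages <- cbind(gm_plus$dosages, rs_rand = rand_dos)
  gm_plus$variants <- rbind(gm_plus$variants,
                            data.frame(id = "rs_rand", chrom = "chr1",
                                       pos = 1.2e6 + 500, ref = "A",
                                       alt = "G", info = 1, typed = FALSE,
                                       block = 99))
  weak <- cs$loci[1, ]
  weak$variant <- "rs_rand"
  weak$pos <- 1.2e6 + 500
  calls_weak <- nominate_effectors(cs$fdr, weak, cs$st$norm, gm_plus,
                                   cs$st$covs, cs$chrom)
  expect_false("G001" %in% calls_weak$gene_id)
  # chromatin gate: an empty annotation removes every call
  empty <- chromatin_annotation(data.frame(chrom = "chr1", start = 0, end = 1,
                                           state = "repressed"))
  calls_nochrom <- nominate_effectors(cs$fdr, cs$loci, cs$st$norm, cs$st$gm,
                                      cs$st$covs, empty)
  expect_equal(nrow(calls_nochrom), 0)
  # tier gate: q threshold 0 with nominal 0 drops everything
  calls_none <- nominate_effectors(cs$fdr, cs$loci, cs$st$norm, cs$st$gm,
                                   cs$st$covs, cs$chrom, q_threshold = 0,
                                   nominal_threshold = 0)
  expect_equal(nrow(calls_none), 0)
})

test_that("a missing lead genotype skips the locus with a warning", {
  cs <- make_coloc_study(seed = 62, shared = TRUE)
  ghost <- cs$loci[1, ]
  ghost$variant <- "rs_absent"
  expect_warning(
    calls <- nominate_effectors(cs$fdr, ghost, cs$st$norm, cs$st$gm,
                                cs$st$covs, cs$chrom),
    "absent")
  expect_equal(nrow(calls), 0)
})

test_that("the effector report is invariant to ref/alt relabeling of the lead", {
  cs <- make_coloc_study(seed = 63, shared = TRUE)
  calls <- nominate_effectors(cs$fdr, cs$loci, cs$st$norm, cs$st$gm,
                              cs$st$covs, cs$chrom)
  # flip the lead variant's allele labels: dosage 2 - d, swap ref/alt
  gm2 <- cs$st$gm
  j <- match(cs$loci$variant[1], gm2$variants$id)
  gm2$dosages[, j] <- 2 - gm2$dosages[, j]
  r <- gm2$variants$ref[j]
  gm2$variants$ref[j] <- gm2$variants$alt[j]
  gm2$variants$alt[j] <- r
  calls2 <- nominate_effectors(cs$fdr, cs$loci, cs$st$norm, gm2,
                               cs$st$covs, cs$chrom)
  expect_equal(calls$risk_direction, calls2$risk_direction)
  expect_equal(calls$r2_with_lead, calls2$r2_with_lead, tolerance = 1e-12)
  expect_equal(calls$conditional_p, calls2$conditional_p, tolerance = 1e-10)
})
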