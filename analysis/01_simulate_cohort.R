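#!/usr/bin/env Rscript
# Build the synthetic islet-style cohort used by the downstream analysis
# scripts: 150 donors, 60 genes with 3 exons each, one 50-variant LD block
# per gene, four planted cis-eQTLs at effect sizes typical of GWAS effector
# transcripts, two hidden technical factors, four GWAS loci (two sharing
# their causal variant with a planted eQTL, two independent), a chromatin
# map 2-fold enriched at eQTL variants, and three ASE sites (one balanced,
# two imbalanced).  Everything is written in the pipeline's input formats
# under results/synthetic_study/.

suppressPackageStartupMessages(library(isleteqtl))

out <- "results/synthetic_study"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 42

blocks <- c(
  replicate(2, list(n_variants = 50, target_r2 = 0.98, maf = 0.3),
            simplify = FALSE),                  # shared-causal GWAS blocks
  replicate(58, list(n_variants = 50, target_r2 = 0.9, maf = 0.25),
            simplify = FALSE)
)
genes <- lapply(1:60, function(i)
  list(gene_id = sprintf("G%03d", i), n_exons = 3,
       tss = (i - 1) * 2.5e6 + 1.2e6, strand = "+"))
planted <- data.frame(
  gene = c("G001", "G002", "G010", "G011"),
  variant = c("G001_v25", "G002_v25", "G010_v25", "G011_v25"),
  beta = c(0.6, -0.8, 0.5, 1.0)
)
cfg <- sim_config(n_samples = 150, ld_blocks = blocks, genes = genes,
                  planted_eqtls = planted, n_hidden_factors = 2,
                  factor_sd = 0.6, seed = seed)

gm <- simulate_genotypes(cfg)
se <- simulate_expression(gm, cfg)
gl <- simulate_gwas_loci(gm, se$truth, shared = c(TRUE, TRUE, FALSE, FALSE),
                         trait = c("T2D", "fasting glucose", "T2D", "2h glucose"))
# enhancers tag the causal haplotype: enrich the planted variants together
# with their strong-LD proxies (r2 > 0.8), not just the causal site itself
proxies <- unlist(lapply(planted$variant, function(pv) {
  blk <- gm$variants$block[match(pv, gm$variants$id)]
  cand <- which(gm$variants$block == blk)
  r2 <- vapply(cand, function(j)
    suppressWarnings(stats::cor(gm$dosages[, j], gm$dosages[, pv])^2),
    numeric(1))
  gm$variants$id[cand[!is.na(r2) & r2 > 0.8]]
}))
ann <- simulate_chromatin(gm, gl$truth, enrichment_fold = 2,
                          background_rate = 0.15, seed = seed + 1,
                          eqtl_ids = unique(proxies))
ase <- rbind(
  simulate_ase_counts(24, 0.50, 60, seed = seed + 2, variant = "rs_balanced"),
  simulate_ase_counts(18, 0.65, 60, seed = seed + 3, variant = "rs_imbalanced_1"),
  simulate_ase_counts(15, 0.75, 40, seed = seed + 4, variant = "rs_imbalanced_2")
)

write_vcf(gm, file.path(out, "genotypes.vcf"))
write_exon_table(se$counts, file.path(out, "exon_counts.tsv"))
write_gwas_leads(gl$loci, file.path(out, "gwas_leads.tsv"))
write_bed_states(ann, file.path(out, "chromatin_states.bed"))
write_ase_counts(ase, file.path(out, "ase_counts.tsv"))
write_truth(gl$truth, file.path(out, "truth.json"))

cat(sprintf("cohort: %d samples, %d variants, %d exons\n",
            nrow(gm$dosages), ncol(gm$dosages), nrow(se$counts$counts)))
cat(sprintf("planted eQTLs: %s\n",
            paste(sprintf("%s (beta %+.1f)", planted$gene, planted$beta),
                  collapse = ", ")))
cat(sprintf("GWAS loci: %s\n",
            paste(sprintf("%s->%s", gl$loci$locus,
                          vapply(gl$truth$gwas_map, function(m)
                            if (m$type == "shared") m$gene else "independent",
                            character(1))), collapse = ", ")))
cat("inputs written under", out, "\n")
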