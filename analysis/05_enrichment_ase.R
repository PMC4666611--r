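#!/usr/bin/env Rscript
# Chromatin-state enrichment of significant eQTL index variants (Fisher
# exact + 10000 resamplings from the non-significant background) and the
# Wilcoxon signed-rank allele-specific-expression tests.

suppressPackageStartupMessages(library(isleteqtl))

state <- readRDS("scratch/normalized_state.rds")
gm <- state$gm
fdr <- as.data.frame(data.table::fread("results/fdr_table.tsv"))
chrom <- read_bed_states("results/synthetic_study/chromatin_states.bed")

v <- gm$variants
sig_ids <- unique(fdr$index_variant[fdr$significant])
bg_ids <- setdiff(unique(fdr$index_variant[!fdr$significant]), sig_ids)
fg <- v[match(sig_ids, v$id), , drop = FALSE]
bg <- v[match(bg_ids, v$id), , drop = FALSE]

flags <- overlap_variants(fg, chrom)
cat(sprintf("significant index variants overlapping enhancer/promoter: %d/%d (%.0f%%)\n",
            sum(flags), length(flags), 100 * mean(flags)))

if (nrow(bg) >= nrow(fg)) {
  er <- enrichment_test(fg, bg, chrom, n_samplings = 10000, seed = 4243)
  cat(sprintf("enrichment: fold %.2f, Fisher p %.2g, resampling p %.2g (%d samplings)\n",
              er$fold, er$fisher_p, er$resampling_p, er$n_samplings))
  cat("(a study this small has little power here; the package's calibration\n",
      "checks measure enrichment recovery at 2000 foreground variants)\n", sep = "")
  data.table::fwrite(
    data.frame(n_fg = er$n_fg, n_fg_overlap = er$n_fg_overlap,
               n_bg = er$n_bg, n_bg_overlap = er$n_bg_overlap,
               fold = er$fold, fisher_p = er$fisher_p,
               resampling_p = er$resampling_p),
    "results/enrichment.tsv", sep = "\t")
} else {
  cat("background smaller than foreground; enrichment skipped\n")
}

ase <- read_ase_counts("results/synthetic_study/ase_counts.tsv")
rep <- ase_report(ase, min_depth = 10)
data.table::fwrite(rep, "results/ase_report.tsv", sep = "\t")
for (i in seq_len(nrow(rep)))
  cat(sprintf("ASE %s: n_het %d, median alt fraction %.2f, Wilcoxon p %.3g%s\n",
              rep$variant[i], rep$n_het[i], rep$median_alt_fraction[i],
              rep$p[i], ifelse(rep$p[i] < 0.01, "  (allelic imbalance)",
                               ifelse(rep$p[i] > 0.1, "  (no imbalance)", ""))))
cat("reports written to results/enrichment.tsv and results/ase_report.tsv\n")
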