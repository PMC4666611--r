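#' Read allele dosages from a VCF
#'
#' The DS FORMAT field is preferred when present; otherwise the alt-allele
#' count is derived from GT.  Missing calls (\code{./.} or absent DS) become
#' \code{NA}.  Multiallelic records are skipped with a warning.  The
#' imputation quality is read from the INFO key given by \code{info_key}
#' (absent: treated as 1); a \code{TYPED} flag marks directly genotyped
#' variants.
#'
#' @param path VCF file (plain or gzipped).
#' @param info_key INFO key holding the imputation quality score.
#' @return a \code{\link{genotype_matrix}}.
#' @export
read_vcf_dosages <- function(path, info_key = "INFO") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning("read_vcf_dosages: skipping ", sum(multi), " multiallelic record(s)")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dos_gt <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos_gt[gt %in% c("0/0", "0|0")] <- 0
  dos_gt[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  dos_gt[gt %in% c("1/1", "1|1")] <- 2
  fmt <- vcf@gt[, 1]
  has_ds <- any(grepl("(^|:)DS(:|$)", fmt))
  dos <- dos_gt
  if (has_ds) {
    ds <- suppressWarnings(
      apply(vcfR::extract.gt(vcf, element = "DS"), 2, as.numeric))
    if (is.null(dim(ds))) ds <- matrix(ds, nrow(gt), ncol(gt))
    dos <- ifelse(is.na(ds), dos_gt, ds)
    dimnames(dos) <- dimnames(gt)
  }
  info_val <- function(key, info) {
    vapply(info, function(s) {
      m <- regmatches(s, regexpr(paste0("(^|;)", key, "=([^;]+)"), s))
      if (!length(m)) NA_character_ else sub(paste0("^.*", key, "="), "", m)
    }, character(1), USE.NAMES = FALSE)
  }
  info_str <- fix$INFO
  info_str[is.na(info_str)] <- ""
  score <- suppressWarnings(as.numeric(info_val(info_key, info_str)))
  score[is.na(score)] <- 1
  typed <- grepl("(^|;)TYPED(;|$)", info_str)
  variants <- data.frame(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT, info = score, typed = typed,
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(t(dos), variants)
  rownames(gm$dosages) <- colnames(gt)
  gm
}

#' Write a genotype matrix as VCF (GT + DS)
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param path output path.
#' @param info_key INFO key for the imputation quality score.
#' @export
write_vcf <- function(gm, path, info_key = "INFO") {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  samples <- rownames(gm$dosages)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Imputation quality\">", info_key),
    "##INFO=<ID=TYPED,Number=0,Type=Flag,Description=\"Directly genotyped\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  gt_of <- function(d) {
    out <- rep("./.", length(d))
    r <- round(d)
    out[!is.na(d) & r == 0] <- "0/0"
    out[!is.na(d) & r == 1] <- "0/1"
    out[!is.na(d) & r == 2] <- "1/1"
    out
  }
  for (j in seq_len(nrow(v))) {
    d <- gm$dosages[, j]
    cells <- ifelse(is.na(d), "./.",
                    paste0(gt_of(d), ":", formatC(d, format = "g", digits = 6)))
    info <- sprintf("%s=%s", info_key, formatC(v$info[j], format = "g", digits = 6))
    if (isTRUE(v$typed[j])) info <- paste0(info, ";TYPED")
    writeLines(paste(c(v$chrom[j], format(v$pos[j], scientific = FALSE),
                       v$id[j], v$ref[j], v$alt[j], ".", "PASS", info,
                       "GT:DS", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an exon count table
#'
#' Layout: columns \code{exon_id}, \code{gene_id}, \code{chrom},
#' \code{start}, \code{end}, \code{strand}, \code{tss}, then one column per
#' sample.
#'
#' @param path TSV path (plain or gzipped).
#' @return an \code{\link{exon_counts}}.
#' @export
read_exon_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  meta_cols <- c("exon_id", "gene_id", "chrom", "start", "end", "strand", "tss")
  assert_that(all(meta_cols %in% names(dt)),
              "read_exon_table: missing annotation columns")
  bad <- which(dt$start > dt$end)
  if (length(bad))
    stop("read_exon_table: start > end at line(s) ",
         paste(bad + 1, collapse = ", "), call. = FALSE)
  counts <- as.matrix(dt[, setdiff(names(dt), meta_cols), drop = FALSE])
  exon_counts(counts, dt[, meta_cols])
}

#' Write an exon count table
#' @param ec an \code{\link{exon_counts}}.
#' @param path output TSV path.
#' @export
write_exon_table <- function(ec, path) {
  stopifnot(inherits(ec, "exon_counts"))
  out <- cbind(ec$exons, as.data.frame(ec$counts))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read chromatin-state intervals from a BED-style file
#'
#' Columns: chrom, start (0-based), end (exclusive), state, and optionally
#' a 5th dataset-id column.  Intervals are kept 0-based half-open.
#'
#' @param path BED path.
#' @return a \code{\link{chromatin_annotation}}.
#' @export
read_bed_states <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  assert_that(ncol(dt) >= 4, "read_bed_states: need >= 4 columns (chrom start end state)")
  names(dt)[1:4] <- c("chrom", "start", "end", "state")
  if (ncol(dt) >= 5) names(dt)[5] <- "dataset"
  bad <- which(dt$start >= dt$end)
  if (length(bad))
    stop("read_bed_states: start >= end at line(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  chromatin_annotation(dt[, intersect(names(dt),
                                      c("chrom", "start", "end", "state", "dataset"))])
}

#' Write chromatin-state intervals as BED
#' @param annotation a \code{\link{chromatin_annotation}}.
#' @param path output path.
#' @export
write_bed_states <- function(annotation, path) {
  stopifnot(inherits(annotation, "chromatin_annotation"))
  data.table::fwrite(as.data.frame(annotation)[, c("chrom", "start", "end",
                                                   "state", "dataset")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a GWAS lead-variant table
#'
#' Columns: locus, trait, variant, chrom, pos, risk_allele, other_allele.
#'
#' @param path TSV path.
#' @return data.frame of GWAS loci.
#' @export
read_gwas_leads <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("locus", "trait", "variant", "chrom", "pos", "risk_allele",
            "other_allele")
  assert_that(all(need %in% names(dt)), "read_gwas_leads: missing columns")
  dt
}

#' Write a GWAS lead-variant table
#' @param loci GWAS loci data.frame.
#' @param path output path.
#' @export
write_gwas_leads <- function(loci, path) {
  data.table::fwrite(loci[, c("locus", "trait", "variant", "chrom", "pos",
                              "risk_allele", "other_allele")], path, sep = "\t")
  invisible(path)
}

#' Read per-sample ASE counts
#'
#' Columns: variant, sample, ref_count, alt_count.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_ase_counts <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("variant", "sample", "ref_count", "alt_count")
  assert_that(all(need %in% names(dt)), "read_ase_counts: missing columns")
  dt
}

#' Write per-sample ASE counts
#' @param ase data.frame with variant, sample, ref_count, alt_count.
#' @param path output path.
#' @export
write_ase_counts <- function(ase, path) {
  data.table::fwrite(ase[, c("variant", "sample", "ref_count", "alt_count")],
                     path, sep = "\t")
  invisible(path)
}

#' Write the simulation truth as JSON
#' @param truth a \code{sim_truth}.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(planted = truth$planted,
                            gwas_map = truth$gwas_map,
                            library_sizes = truth$library_sizes),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Pipeline configuration with study defaults
#'
#' Collects the file paths and every analysis threshold.  Defaults are the
#' standard settings of the pipeline: call rate 0.99, pre-imputation MAF
#' 0.01, Hardy-Weinberg alpha 1e-4, INFO 0.4, analysis MAF 0.05, 10 M
#' mapped reads per sample, exon filter at 10 zero-count samples, 1 Mb cis
#' flank, 15 latent factors, 1000-10000 adaptive permutations stopping at
#' 15 exceedances, q < 0.05 study-wide and empirical p < 0.05 nominal
#' tiers, LD r2 > 0.8, conditional absorption alpha 0.05, 10000 enrichment
#' samplings, RPKM 0.1 expressed threshold.
#'
#' @param vcf,counts,gwas,bed,ase input paths (\code{ase} optional).
#' @param out_dir output directory for the report bundle.
#' @param sex optional numeric vector of per-sample sex indicators, aligned
#'   with the VCF sample order.
#' @param seed master seed.
#' @param ... overrides for any threshold listed above.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(vcf, counts, gwas = NULL, bed = NULL, ase = NULL,
                            out_dir = "results", sex = NULL, seed = 1L, ...) {
  cfg <- list(
    vcf = vcf, counts = counts, gwas = gwas, bed = bed, ase = ase,
    out_dir = out_dir, sex = sex, seed = as.integer(seed),
    min_call_rate = 0.99, pre_imputation_maf = 0.01, hwe_alpha = 1e-4,
    min_info = 0.4, analysis_maf = 0.05, min_mapped_reads = 1e7,
    max_zero_samples = 10, exon_filter_mode = "zeros",
    min_nonzero_fraction = 0.10, flank = 1e6, k_factors = 15,
    min_perm = 1000, max_perm = 10000, stop_exceedances = 15,
    perm_batch = 1000, q_threshold = 0.05, nominal_threshold = 0.05,
    r2_min = 0.8, coloc_alpha = 0.05, n_samplings = 10000,
    rpkm_threshold = 0.1, min_ase_depth = 10
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  assert_that(length(unknown) == 0,
              paste("pipeline_config: unknown option(s):",
                    paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  assert_that(cfg$q_threshold >= 0 && cfg$q_threshold <= 1 &&
              cfg$r2_min >= 0 && cfg$r2_min <= 1 &&
              cfg$min_info >= 0 && cfg$min_info <= 1,
              "pipeline_config: thresholds out of range")
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a \code{\link{pipeline_config}}.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}
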