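#' Construct a genotype matrix object
#'
#' Container for sample-by-variant allele dosages plus per-variant metadata.
#' Dosages are real numbers in [0, 2] (expected alt-allele count under
#' imputation); \code{NA} marks missing calls, which survive only until
#' \code{\link{filter_variants}} mean-imputes them.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#' @param variants data.frame with columns \code{id}, \code{chrom},
#'   \code{pos} (1-based), \code{ref}, \code{alt}; optional \code{info}
#'   (imputation quality, absent treated as 1) and \code{typed} (logical,
#'   directly genotyped rather than imputed; default \code{FALSE}).
#' @return object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(dosages, variants) {
  stopifnot(is.matrix(dosages), is.data.frame(variants))
  assert_that(ncol(dosages) == nrow(variants),
              "dosage columns must match variant rows")
  need <- c("id", "chrom", "pos", "ref", "alt")
  assert_that(all(need %in% names(variants)),
              paste("variants must have columns:", paste(need, collapse = ", ")))
  if (is.null(variants$info)) variants$info <- 1
  if (is.null(variants$typed)) variants$typed <- FALSE
  variants$id <- as.character(variants$id)
  colnames(dosages) <- variants$id
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("S%03d", seq_len(nrow(dosages)))
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d typed, %d with missing calls)\n",
              nrow(x$dosages), ncol(x$dosages), sum(x$variants$typed),
              sum(colSums(is.na(x$dosages)) > 0)))
  invisible(x)
}

#' Minor allele frequency from allele dosages
#'
#' Alt-allele frequency is \code{sum(dosage) / (2 * n)} over non-missing
#' entries; the returned value is folded to the minor allele,
#' \code{min(f, 1 - f)}.
#'
#' @param dosages numeric vector of dosages in [0, 2]; \code{NA} allowed.
#' @return minor allele frequency in [0, 0.5].
#' @export
compute_maf <- function(dosages) {
  ok <- !is.na(dosages)
  assert_that(any(ok), "compute_maf: all dosages missing")
  f <- sum(dosages[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, the number of heterozygotes
#' follows a known distribution under random mating; the exact p-value is the
#' total probability of all heterozygote counts whose probability does not
#' exceed that of the observed count (the standard two-sided exact
#' convention, no mid-p correction).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (hard calls).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "hwe_exact_test: counts must be non-negative integers")
  n <- sum(counts)
  assert_that(n > 0, "hwe_exact_test: no genotypes")
  n_a <- n_Aa + 2 * n_aa                 # rarer-or-not allele count (either is fine)
  n_A <- n_Aa + 2 * n_AA
  if (n_a == 0 || n_A == 0) return(1.0)  # monomorphic
  # heterozygote count shares the parity of the minor allele count
  n_minor <- min(n_a, n_A)
  het <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(het | allele counts) up to a constant:
  #   n! / (n_AA! n_Aa! n_aa!) * 2^het  with n_AA, n_aa implied by het
  logp <- vapply(het, function(h) {
    aa <- (n_a - h) / 2
    AA <- (n_A - h) / 2
    h * log(2) - lfactorial(AA) - lfactorial(h) - lfactorial(aa)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, het)]
  # tolerance guards against ties broken by floating point
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Apply variant-level quality filters
#'
#' Two-stage semantics mirroring an array-then-imputation workflow: call
#' rate, pre-imputation MAF and the Hardy-Weinberg exact test apply only to
#' directly genotyped variants (\code{typed} flag); the imputation INFO score
#' and the analysis MAF apply to every variant entering analysis.  Surviving
#' variants have remaining missing dosages mean-imputed, which preserves the
#' allele frequency exactly.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param min_call_rate minimum call rate for typed variants.
#' @param pre_imputation_maf minimum MAF for typed variants.
#' @param hwe_alpha Hardy-Weinberg exact-test significance cutoff (typed
#'   variants; dosages are rounded to genotype classes for this test only).
#' @param min_info minimum imputation INFO score.
#' @param analysis_maf minimum MAF for any variant entering analysis.
#' @return filtered \code{genotype_matrix}; the QC report is attached as
#'   attribute \code{"qc_report"} (one row per input variant with per-filter
#'   pass flags and final status).
#' @export
filter_variants <- function(gm, min_call_rate = 0.99, pre_imputation_maf = 0.01,
                            hwe_alpha = 1e-4, min_info = 0.4,
                            analysis_maf = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosages
  v <- gm$variants
  n <- nrow(d)
  call_rate <- colMeans(!is.na(d))
  maf <- apply(d, 2, function(x) if (all(is.na(x))) NA_real_ else compute_maf(x))
  hwe_p <- rep(NA_real_, ncol(d))
  typed <- as.logical(v$typed)
  for (j in which(typed)) {
    g <- round(d[, j])
    g <- g[!is.na(g)]
    if (!length(g)) next
    hwe_p[j] <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }
  pass_call <- !typed | (call_rate >= min_call_rate)
  pass_premaf <- !typed | (!is.na(maf) & maf >= pre_imputation_maf)
  pass_hwe <- !typed | (is.na(hwe_p) | hwe_p >= hwe_alpha)
  pass_info <- v$info >= min_info
  pass_amaf <- !is.na(maf) & maf >= analysis_maf
  keep <- pass_call & pass_premaf & pass_hwe & pass_info & pass_amaf
  report <- data.frame(
    id = v$id, typed = typed, call_rate = call_rate, maf = maf,
    hwe_p = hwe_p, info = v$info,
    pass_call_rate = pass_call, pass_pre_imputation_maf = pass_premaf,
    pass_hwe = pass_hwe, pass_info = pass_info, pass_analysis_maf = pass_amaf,
    status = ifelse(keep, "pass", "fail"),
    stringsAsFactors = FALSE
  )
  if (!any(keep)) {
    attrition <- c(call_rate = sum(!pass_call), pre_imputation_maf = sum(!pass_premaf),
                   hwe = sum(!pass_hwe), info = sum(!pass_info),
                   analysis_maf = sum(!pass_amaf))
    stop("filter_variants: no variants survive QC; failures per filter: ",
         paste(names(attrition), attrition, sep = "=", collapse = ", "),
         call. = FALSE)
  }
  d <- d[, keep, drop = FALSE]
  # mean-impute residual missingness: design mean (hence allele frequency)
  # is unchanged
  nas <- which(colSums(is.na(d)) > 0)
  for (j in nas) {
    x <- d[, j]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    d[, j] <- x
  }
  out <- genotype_matrix(d, v[keep, , drop = FALSE])
  out$variants$maf <- maf[keep]
  attr(out, "qc_report") <- report
  out
}

#' Drop samples with insufficient sequencing depth
#'
#' Samples whose total exon-mapping read count falls below the threshold are
#' removed from the study (they must be dropped from both expression and
#' genotype data; the returned vector names the survivors).
#'
#' @param counts an \code{\link{exon_counts}} object or a counts matrix with
#'   samples in columns.
#' @param min_mapped_reads minimum total exon-mapping reads per sample.
#' @return character vector of retained sample ids (possibly empty).
#' @export
filter_samples <- function(counts, min_mapped_reads = 1e7) {
  m <- if (inherits(counts, "exon_counts")) counts$counts else counts
  totals <- colSums(m)
  colnames(m)[totals >= min_mapped_reads]
}
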