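#' Squared allelic correlation (LD r2) between two variants
#'
#' @param gA,gB dosage vectors over the same samples.
#' @return squared Pearson correlation in [0, 1].
#' @export
compute_ld_r2 <- function(gA, gB) {
  stopifnot(length(gA) == length(gB))
  if (stats::var(gA) == 0 || stats::var(gB) == 0)
    stop("compute_ld_r2: constant dosage vector", call. = FALSE)
  stats::cor(gA, gB)^2
}

#' Conditional association test against a GWAS lead variant
#'
#' Refits the additive model with the lead variant's dosage added as a
#' covariate.  A conditional p-value near 1 means the lead variant absorbs
#' the eQTL signal (colocalization); a persistently small conditional p
#' means the two signals are statistically independent.  When the two
#' dosages are collinear beyond tolerance (r2 > 0.999) the signal is fully
#' absorbed by construction and \code{conditional_p = 1} is returned with a
#' collinearity flag.
#'
#' @param y expression vector.
#' @param g_eqtl eQTL index variant dosages.
#' @param g_lead GWAS lead variant dosages.
#' @param C optional covariate matrix.
#' @return list: \code{conditional_p}, \code{conditional_beta},
#'   \code{collinear}.
#' @export
conditional_test <- function(y, g_eqtl, g_lead, C = NULL) {
  if (compute_ld_r2(g_eqtl, g_lead) > 0.999)
    return(list(conditional_p = 1, conditional_beta = NA_real_,
                collinear = TRUE))
  fit <- fit_additive_model(y, g_eqtl, cbind(C, g_lead = g_lead))
  list(conditional_p = fit$p, conditional_beta = fit$beta, collinear = FALSE)
}

#' Directional consistency of a variant's effect across a gene's exons
#'
#' Counts, over all tested exons of the gene, how many have a dosage effect
#' at the index variant with the same sign as the index exon's effect (the
#' index exon itself included).
#'
#' @param betas named numeric vector of per-exon effects at the index
#'   variant (names = exon ids).
#' @param index_exon id of the index exon.
#' @return list: \code{n_consistent}, \code{n_total}, \code{label}
#'   (e.g. "23/24").
#' @export
directional_consistency <- function(betas, index_exon) {
  assert_that(index_exon %in% names(betas),
              "directional_consistency: index exon not among betas")
  s <- sign(betas[[index_exon]])
  n_cons <- sum(sign(betas) == s)
  list(n_consistent = n_cons, n_total = length(betas),
       label = sprintf("%d/%d", n_cons, length(betas)))
}

#' Nominate candidate effector transcripts at GWAS loci
#'
#' Per locus x gene cascade: (1) the gene's TSS lies within \code{flank} of
#' the lead variant; (2) the gene's best exon (smallest empirical p, ties by
#' q then genomic order) is taken; (3) tier is "study_wide" when q <
#' \code{q_threshold}, else "nominal" when empirical p <
#' \code{nominal_threshold}, else the gene is dropped; (4) LD between the
#' exon's index variant and the lead must exceed \code{r2_min}; (5) the
#' conditional test must show absorption of the eQTL signal by the lead
#' (conditional p > \code{coloc_alpha}; a >= 90 percent drop in -log10 p is
#' reported alongside as an alternative absorption measure); (6) the index
#' variant or an LD proxy (r2 > \code{r2_min}) must overlap an active
#' chromatin state (enhancer/promoter) -- the index-only overlap flag is also
#' reported; (7) directional consistency across the gene's exons and the
#' risk-allele expression direction are attached.
#'
#' @param fdr fdr table from \code{\link{fdr_table}}.
#' @param gwas_loci data.frame of GWAS leads: \code{locus}, \code{trait},
#'   \code{variant}, \code{chrom}, \code{pos}, \code{risk_allele},
#'   \code{other_allele}.
#' @param norm_expr a \code{normalized_expression} object.
#' @param gm post-QC \code{\link{genotype_matrix}}.
#' @param C optional covariate matrix.
#' @param chromatin a \code{\link{chromatin_annotation}} (or NULL to skip
#'   the chromatin gate).
#' @param r2_min LD threshold (default 0.8).
#' @param coloc_alpha conditional-absorption threshold (default 0.05).
#' @param q_threshold,nominal_threshold significance tiers.
#' @param flank TSS window around the lead (default 1 Mb).
#' @param active_states chromatin states counted as active.
#' @return data.frame of effector calls (possibly zero rows), one per
#'   locus x gene passing the cascade.
#' @export
nominate_effectors <- function(fdr, gwas_loci, norm_expr, gm, C = NULL,
                               chromatin = NULL, r2_min = 0.8,
                               coloc_alpha = 0.05, q_threshold = 0.05,
                               nominal_threshold = 0.05, flank = 1e6,
                               active_states = c("enhancer", "promoter")) {
  stopifnot(inherits(norm_expr, "normalized_expression"))
  exons <- norm_expr$exons
  v <- gm$variants
  calls <- list()
  for (li in seq_len(nrow(gwas_loci))) {
    locus <- gwas_loci[li, ]
    jl <- match(locus$variant, v$id)
    if (is.na(jl)) {
      warning("nominate_effectors: lead variant ", locus$variant,
              " absent from genotypes; locus ", locus$locus, " skipped")
      next
    }
    g_lead <- gm$dosages[, jl]
    # (1) genes with TSS within flank of the lead
    gene_tss <- exons[!duplicated(exons$gene_id),
                      c("gene_id", "chrom", "tss")]
    near <- gene_tss$gene_id[gene_tss$chrom == locus$chrom &
                             abs(gene_tss$tss - locus$pos) <= flank]
    for (gene in near) {
      rows <- fdr[fdr$gene_id == gene, , drop = FALSE]
      if (!nrow(rows)) next
      # (2) best exon: smallest empirical p, ties by q then genomic order
      exon_order <- match(rows$exon_id, exons$exon_id)
      best <- rows[order(rows$empirical_p, rows$q, exon_order), ][1, ]
      # (3) significance tier
      tier <- if (best$q < q_threshold) "study_wide"
              else if (best$empirical_p < nominal_threshold) "nominal"
              else next
      # (4) LD filter
      jx <- match(best$index_variant, v$id)
      g_idx <- gm$dosages[, jx]
      r2 <- compute_ld_r2(g_idx, g_lead)
      if (r2 <= r2_min) next
      # (5) conditional absorption
      ei <- match(best$exon_id, exons$exon_id)
      y <- norm_expr$mat[ei, ]
      ct <- conditional_test(y, g_idx, g_lead, C)
      marg <- fit_additive_model(y, g_idx, C)
      logp_drop <- if (ct$collinear) 1 else
        1 - log10(ct$conditional_p) / log10(marg$p)
      if (ct$conditional_p <= coloc_alpha) next
      # (6) chromatin overlap of index variant or strong-LD proxy
      overlap_index <- overlap_proxy <- NA
      if (!is.null(chromatin)) {
        same_chr <- which(v$chrom == v$chrom[jx])
        prox_r2 <- vapply(same_chr, function(j) {
          if (stats::var(gm$dosages[, j]) == 0) return(0)
          stats::cor(gm$dosages[, j], g_idx)^2
        }, numeric(1))
        proxies <- v[same_chr[prox_r2 > r2_min], , drop = FALSE]
        flags <- overlap_variants(proxies, chromatin, states = active_states)
        overlap_proxy <- any(flags)
        overlap_index <- flags[match(best$index_variant, proxies$id)]
        if (!overlap_proxy) next
      }
      # (7) direction and consistency
      gene_exons <- exons$exon_id[exons$gene_id == gene]
      betas <- vapply(gene_exons, function(eid) {
        scan_window_stats(norm_expr$mat[match(eid, exons$exon_id), ],
                          gm$dosages[, jx, drop = FALSE],
                          covariate_basis(C, length(y)))$beta[1]
      }, numeric(1))
      betas <- betas[!is.na(betas)]
      dc <- directional_consistency(betas, best$exon_id)
      # beta is per alt allele; orient to the risk allele
      risk_is_alt <- locus$risk_allele == v$alt[jl]
      lead_eqtl_cor <- stats::cor(gm$dosages[, jl], g_idx)
      risk_beta <- best$beta * sign(lead_eqtl_cor) * if (risk_is_alt) 1 else -1
      calls[[length(calls) + 1L]] <- data.frame(
        locus = locus$locus, trait = locus$trait, gene_id = gene,
        exon_id = best$exon_id, index_variant = best$index_variant,
        lead_variant = locus$variant, r2_with_lead = r2,
        marginal_p = marg$p, empirical_p = best$empirical_p, q = best$q,
        tier = tier, conditional_p = ct$conditional_p,
        conditional_beta = ct$conditional_beta, collinear = ct$collinear,
        logp_drop = logp_drop,
        chromatin_overlap_index = overlap_index,
        chromatin_overlap_proxy = overlap_proxy,
        risk_direction = ifelse(risk_beta >= 0, "up", "down"),
        consistency = dc$label, n_consistent = dc$n_consistent,
        n_exons = dc$n_total,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(calls)) {
    return(data.frame(locus = character(), trait = character(),
                      gene_id = character(), exon_id = character(),
                      index_variant = character(), lead_variant = character(),
                      r2_with_lead = numeric(), marginal_p = numeric(),
                      empirical_p = numeric(), q = numeric(),
                      tier = character(), conditional_p = numeric(),
                      conditional_beta = numeric(), collinear = logical(),
                      logp_drop = numeric(),
                      chromatin_overlap_index = logical(),
                      chromatin_overlap_proxy = logical(),
                      risk_direction = character(), consistency = character(),
                      n_consistent = integer(), n_exons = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, calls)
}
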