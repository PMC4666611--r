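#' Define the cis window around a transcription start site
#'
#' Closed interval \code{[max(1, tss - flank), tss + flank]} in 1-based
#' coordinates.  The TSS is the annotated start for "+"-strand genes and the
#' annotated end for "-"-strand genes.
#'
#' @param tss transcription start site (1-based bp).
#' @param flank window half-width in bp (default 1 Mb).
#' @return numeric length-2 vector \code{c(start, end)}.
#' @export
define_cis_window <- function(tss, flank = 1e6) {
  assert_that(tss >= 1, "define_cis_window: tss must be >= 1")
  c(max(1, tss - flank), tss + flank)
}

#' Fit the additive linear eQTL model for one variant-exon pair
#'
#' Ordinary least squares of expression on \code{[1, g, C]} with a two-sided
#' t-test on the dosage coefficient (df = n - n_covariates - 2).  The dosage
#' effect is per alt-allele copy on the phenotype scale (normal scores in
#' the standard pipeline).
#'
#' @param y expression vector.
#' @param g allele dosage vector (non-constant).
#' @param C optional samples x covariates matrix (full column rank).
#' @return list of class \code{cis_association}: \code{beta}, \code{se},
#'   \code{t_stat}, \code{p}, \code{n}, \code{df}.
#' @export
fit_additive_model <- function(y, g, C = NULL) {
  n <- length(y)
  stopifnot(length(g) == n)
  if (stats::var(g) == 0)
    stop("fit_additive_model: constant dosage vector", call. = FALSE)
  X <- cbind(intercept = 1, g = g, C)
  p <- ncol(X)
  assert_that(n > p, "fit_additive_model: not enough samples for the design")
  qx <- qr(X)
  if (qx$rank < p) {
    # distinguish a rank-deficient covariate block from g-collinearity
    if (!is.null(C) && qr(cbind(1, C))$rank < ncol(C) + 1)
      stop("fit_additive_model: rank-deficient covariate matrix", call. = FALSE)
    stop("fit_additive_model: dosage collinear with covariates", call. = FALSE)
  }
  beta_all <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- n - p
  sigma2 <- sum(res^2) / df
  R <- qr.R(qx)[seq_len(p), seq_len(p), drop = FALSE]
  Rinv <- backsolve(R, diag(p))
  cov_unscaled <- Rinv %*% t(Rinv)
  # undo any column pivoting
  piv <- qx$pivot
  se_all <- sqrt(sigma2 * diag(cov_unscaled))[order(piv)]
  beta <- unname(beta_all["g"])
  se <- unname(se_all[2L])
  t_stat <- beta / se
  structure(list(beta = beta, se = se, t_stat = t_stat,
                 p = 2 * stats::pt(-abs(t_stat), df), n = n, df = df,
                 coefficients = beta_all),
            class = "cis_association")
}

# Orthonormal basis of [1, C] used to residualize the scan; shared by the
# observed scan and the permutation null.
covariate_basis <- function(C, n) {
  X <- cbind(rep(1, n), C)
  qx <- qr(X)
  assert_that(qx$rank == ncol(X),
              "covariate matrix is rank deficient after adding the intercept")
  qr.Q(qx)
}

# Vectorized per-window association statistics for one phenotype vector.
# Returns beta, se, t, p for every column of G; columns (near-)collinear
# with the covariate span are returned as NA and excluded from min-p.
scan_window_stats <- function(y, G, Q) {
  n <- length(y)
  y_r <- y - Q %*% crossprod(Q, y)
  yss <- sum(y_r^2)
  QtG <- crossprod(Q, G)
  gss <- colSums(G^2) - colSums(QtG^2)
  tol <- max(colSums(G^2), 1) * 1e-10
  ok <- gss > tol
  num <- drop(crossprod(y_r, G))
  df <- n - ncol(Q) - 1L
  beta <- se <- tval <- pval <- rep(NA_real_, ncol(G))
  beta[ok] <- num[ok] / gss[ok]
  rss <- yss - beta[ok] * num[ok]
  se[ok] <- sqrt(pmax(rss, 0) / df / gss[ok])
  tval[ok] <- beta[ok] / se[ok]
  pval[ok] <- 2 * stats::pt(-abs(tval[ok]), df)
  list(beta = beta, se = se, t = tval, p = pval, df = df, ok = ok)
}

#' Scan all variants in the cis window of one exon
#'
#' Fits the additive model for every testable window variant and reports the
#' index variant: smallest p, ties broken by larger |t|, then smaller
#' genomic position.
#'
#' @param y expression vector for the exon (normal scores).
#' @param exon one-row data.frame with \code{exon_id}, \code{gene_id},
#'   \code{chrom}, \code{tss}.
#' @param gm a \code{\link{genotype_matrix}} (post-QC).
#' @param C optional covariate matrix.
#' @param flank cis window half-width (default 1 Mb).
#' @param return_pairs also return the full per-variant table.
#' @return one-row data.frame (\code{exon_id}, \code{gene_id},
#'   \code{index_variant}, \code{min_p}, \code{beta}, \code{se},
#'   \code{tss_distance}, \code{n_variants_tested}), or \code{NULL} when no
#'   variant is testable (flagged by a warning).  With
#'   \code{return_pairs = TRUE}, a list with elements \code{index} and
#'   \code{pairs}.
#' @export
scan_cis <- function(y, exon, gm, C = NULL, flank = 1e6, return_pairs = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  win <- define_cis_window(exon$tss, flank)
  v <- gm$variants
  in_win <- v$chrom == exon$chrom & v$pos >= win[1] & v$pos <= win[2]
  if (!any(in_win)) {
    warning("scan_cis: no variants in cis window of exon ", exon$exon_id)
    return(NULL)
  }
  G <- gm$dosages[, in_win, drop = FALSE]
  Q <- covariate_basis(C, length(y))
  st <- scan_window_stats(y, G, Q)
  if (!any(st$ok)) {
    warning("scan_cis: no testable (non-constant) variants for exon ",
            exon$exon_id)
    return(NULL)
  }
  pos <- v$pos[in_win]
  idx <- order(st$p, -abs(st$t), pos)[1L]
  index <- data.frame(
    exon_id = exon$exon_id, gene_id = exon$gene_id,
    index_variant = v$id[in_win][idx], min_p = st$p[idx],
    beta = st$beta[idx], se = st$se[idx],
    tss_distance = pos[idx] - exon$tss,
    n_variants_tested = sum(st$ok),
    stringsAsFactors = FALSE
  )
  if (!return_pairs) return(index)
  pairs <- data.frame(
    exon_id = exon$exon_id, variant = v$id[in_win], pos = pos,
    beta = st$beta, se = st$se, t_stat = st$t, p = st$p,
    stringsAsFactors = FALSE
  )
  list(index = index, pairs = pairs[st$ok, , drop = FALSE])
}

#' Map cis-eQTLs for every exon in a study
#'
#' Runs \code{\link{scan_cis}} across all exons of a normalized expression
#' matrix.  Exons without a testable variant are dropped with a warning and
#' excluded from downstream FDR.
#'
#' @param norm_expr a \code{normalized_expression} object.
#' @param gm a \code{\link{genotype_matrix}} (post-QC; samples aligned with
#'   the expression columns).
#' @param C optional covariate matrix.
#' @param flank cis window half-width.
#' @param return_pairs also collect the full pair-level table.
#' @return data.frame of per-exon index rows; with
#'   \code{return_pairs = TRUE} a list \code{(index, pairs)}.
#' @export
map_cis_eqtl <- function(norm_expr, gm, C = NULL, flank = 1e6,
                         return_pairs = FALSE) {
  stopifnot(inherits(norm_expr, "normalized_expression"))
  assert_that(identical(colnames(norm_expr$mat), rownames(gm$dosages)),
              "expression samples and genotype samples must be aligned")
  exons <- norm_expr$exons
  res <- vector("list", nrow(exons))
  prs <- if (return_pairs) vector("list", nrow(exons)) else NULL
  for (i in seq_len(nrow(exons))) {
    out <- scan_cis(norm_expr$mat[i, ], exons[i, ], gm, C, flank,
                    return_pairs = return_pairs)
    if (is.null(out)) next
    if (return_pairs) {
      res[[i]] <- out$index
      prs[[i]] <- out$pairs
    } else res[[i]] <- out
  }
  index <- do.call(rbind, res)
  if (return_pairs)
    list(index = index, pairs = do.call(rbind, prs))
  else index
}
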