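#' Construct an exon count matrix object
#'
#' @param counts non-negative integer matrix, exons in rows, samples in
#'   columns.
#' @param exons data.frame with columns \code{exon_id}, \code{gene_id},
#'   \code{chrom}, \code{start}, \code{end} (1-based inclusive),
#'   \code{strand} ("+" or "-"), \code{tss} (gene transcription start site;
#'   the annotated start for "+" genes and the annotated end for "-" genes).
#' @return object of class \code{exon_counts}.
#' @export
exon_counts <- function(counts, exons) {
  stopifnot(is.matrix(counts), is.data.frame(exons))
  assert_that(nrow(counts) == nrow(exons),
              "count rows must match exon annotation rows")
  need <- c("exon_id", "gene_id", "chrom", "start", "end", "strand", "tss")
  assert_that(all(need %in% names(exons)),
              paste("exons must have columns:", paste(need, collapse = ", ")))
  assert_that(all(exons$start <= exons$end), "exon start must be <= end")
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "counts must be non-negative integers")
  rownames(counts) <- exons$exon_id <- as.character(exons$exon_id)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%03d", seq_len(ncol(counts)))
  structure(list(counts = counts, exons = exons), class = "exon_counts")
}

#' @export
print.exon_counts <- function(x, ...) {
  cat(sprintf("exon_counts: %d exons (%d genes) x %d samples\n",
              nrow(x$counts), length(unique(x$exons$gene_id)), ncol(x$counts)))
  invisible(x)
}

#' Remove weakly expressed exons
#'
#' Default rule: drop exons with zero counts in \code{max_zero_samples} or
#' more samples.  The alternative \code{mode = "fraction"} keeps exons with
#' non-zero counts in at least \code{min_nonzero_fraction} of samples; both
#' rules appear in practice and differ only at the margin.
#'
#' @param ec an \code{\link{exon_counts}} object.
#' @param max_zero_samples zero-count sample threshold ("zeros" mode).
#' @param mode "zeros" (default) or "fraction".
#' @param min_nonzero_fraction minimum fraction of samples with non-zero
#'   counts ("fraction" mode).
#' @return filtered \code{exon_counts}.
#' @export
filter_exons <- function(ec, max_zero_samples = 10, mode = c("zeros", "fraction"),
                         min_nonzero_fraction = 0.10) {
  stopifnot(inherits(ec, "exon_counts"))
  mode <- match.arg(mode)
  nzero <- rowSums(ec$counts == 0)
  n <- ncol(ec$counts)
  keep <- if (mode == "zeros") nzero < max_zero_samples
          else (n - nzero) >= min_nonzero_fraction * n
  if (!any(keep)) stop("filter_exons: all exons removed", call. = FALSE)
  exon_counts(ec$counts[keep, , drop = FALSE], ec$exons[keep, , drop = FALSE])
}

#' Scale counts to the median sequencing depth
#'
#' Each sample's column is multiplied by \code{median(totals) / total}, so
#' every scaled column sums to the cohort median depth.
#'
#' @param ec an \code{\link{exon_counts}} object or counts matrix.
#' @return real-valued matrix of depth-scaled counts.
#' @export
scale_to_median_depth <- function(ec) {
  m <- if (inherits(ec, "exon_counts")) ec$counts else ec
  totals <- colSums(m)
  assert_that(all(totals > 0), "scale_to_median_depth: zero-total sample present")
  sweep(m, 2, stats::median(totals) / totals, `*`)
}

#' Rank-based inverse normal transform
#'
#' Applies \code{log2(x + 1)} then maps average ranks r to normal scores
#' \code{qnorm((r - 0.5) / n)}.  Order-preserving and invariant to any
#' monotone transform of the input (so the log2 step matters only for how
#' ties arise, kept for fidelity to the count scale).
#'
#' @param values numeric vector with at least two distinct values.
#' @return numeric vector of normal scores.
#' @export
inverse_normal_transform <- function(values) {
  assert_that(length(unique(values)) >= 2,
              "inverse_normal_transform: constant vector (exon should have been filtered)")
  x <- log2(values + 1)
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 0.5) / length(x))
}

#' Normalize an exon count matrix to per-exon normal scores
#'
#' Fixed pipeline order: exon filter (done by the caller), depth scaling,
#' log2, per-exon inverse normal transform.
#'
#' @param ec an \code{\link{exon_counts}} object (already exon-filtered).
#' @return list of class \code{normalized_expression} with elements
#'   \code{mat} (exons x samples normal scores) and \code{exons} (annotation).
#' @export
normalize_expression <- function(ec) {
  stopifnot(inherits(ec, "exon_counts"))
  scaled <- scale_to_median_depth(ec)
  mat <- t(apply(scaled, 1, inverse_normal_transform))
  dimnames(mat) <- dimnames(ec$counts)
  structure(list(mat = mat, exons = ec$exons), class = "normalized_expression")
}

#' Infer hidden expression covariates
#'
#' Deterministic factor analysis of the normalized expression matrix: the
#' top-k left singular vectors of the sample-by-exon matrix after per-exon
#' centering.  These play the role Bayesian factor methods (PEER and
#' relatives) play in eQTL studies -- capturing batch, purity and other
#' unmodelled structure -- while being exactly reproducible.  A sex
#' indicator, when supplied, is always appended as an additional covariate.
#'
#' @param norm_expr a \code{normalized_expression} object or exons x samples
#'   matrix.
#' @param k number of latent factors (must be < number of samples).
#' @param sex optional numeric/integer indicator per sample (e.g. 0/1).
#' @return samples x covariates numeric matrix (factors orthonormal), with
#'   column names \code{factor1..k} and optionally \code{sex}.  A
#'   factor-vs-sex correlation screen is attached as attribute
#'   \code{"sex_screen"} when sex is given.
#' @export
infer_hidden_factors <- function(norm_expr, k = 15, sex = NULL) {
  mat <- if (inherits(norm_expr, "normalized_expression")) norm_expr$mat else norm_expr
  n <- ncol(mat)
  assert_that(k < n, "infer_hidden_factors: k must be smaller than the sample count")
  covs <- NULL
  if (k > 0) {
    x <- t(mat - rowMeans(mat))          # samples x exons, exon-centered
    sv <- svd(x, nu = k, nv = 0)
    covs <- sv$u[, seq_len(k), drop = FALSE]
    # fix signs for determinism: largest-magnitude loading positive
    for (j in seq_len(k)) {
      i <- which.max(abs(covs[, j]))
      if (covs[i, j] < 0) covs[, j] <- -covs[, j]
    }
    colnames(covs) <- paste0("factor", seq_len(k))
  }
  if (!is.null(sex)) {
    assert_that(length(sex) == n, "sex indicator length must match samples")
    screen <- NULL
    if (k > 0) {
      cors <- apply(covs, 2, function(f) stats::cor(f, sex))
      pvals <- vapply(seq_len(k), function(j)
        stats::cor.test(covs[, j], sex)$p.value, numeric(1))
      screen <- data.frame(factor = colnames(covs), cor_with_sex = cors,
                           p = pvals)
    }
    covs <- cbind(covs, sex = as.numeric(sex))
    attr(covs, "sex_screen") <- screen
  }
  if (is.null(covs)) covs <- matrix(numeric(0), nrow = n, ncol = 0)
  rownames(covs) <- colnames(mat)
  covs
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' @param counts exon x sample count matrix (or vector).
#' @param lengths exon lengths in bp (> 0).
#' @param totals per-sample total mapped reads (> 0).
#' @return RPKM matrix of the same shape.
#' @export
compute_rpkm <- function(counts, lengths, totals) {
  assert_that(all(lengths > 0), "compute_rpkm: zero exon length")
  assert_that(all(totals > 0), "compute_rpkm: zero sample total")
  m <- as.matrix(counts)
  m <- sweep(m, 1, lengths / 1000, `/`)
  sweep(m, 2, totals / 1e6, `/`)
}

#' Expressed / absent call from RPKM
#'
#' Values below 0.1 RPKM are treated as background; the boundary 0.1 itself
#' counts as expressed.
#'
#' @param rpkm numeric RPKM values.
#' @param threshold expression threshold (default 0.1).
#' @return logical of the same shape.
#' @export
is_expressed <- function(rpkm, threshold = 0.1) {
  rpkm >= threshold
}
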