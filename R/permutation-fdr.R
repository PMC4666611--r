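#' Adaptive permutation empirical p-value for one exon
#'
#' Each permutation shuffles the sample labels of the genotypes against the
#' fixed (expression, covariate) pairing -- equivalently, expression and
#' covariates are permuted jointly -- so the relation between expression and
#' its covariates is maintained while every genotype-expression pairing is
#' broken.  The full cis window is rescanned per permutation and the
#' permuted minimum p is compared with the observed minimum p.  Permutations
#' proceed in batches; after each batch the run stops once at least
#' \code{min_perm} permutations have been done and at least
#' \code{stop_exceedances} permuted minima were as small as the observed
#' one, with a hard stop at \code{max_perm}.  The empirical p-value uses the
#' pseudo-count convention \code{(r + 1) / (n + 1)}, so it is never 0 and
#' never exceeds 1.
#'
#' @param y expression vector for the exon.
#' @param G window dosage matrix (samples x variants).
#' @param C optional covariate matrix.
#' @param observed_min_p observed minimum p from \code{\link{scan_cis}}.
#' @param min_perm,max_perm minimum / maximum number of permutations.
#' @param stop_exceedances early-stop exceedance count.
#' @param batch batch size between stop-rule checks.
#' @param seed integer seed for this exon's permutation stream.
#' @return list of class \code{permutation_result}: \code{n_permutations},
#'   \code{n_exceedances}, \code{empirical_p}, \code{seed}.
#' @export
adaptive_permutation <- function(y, G, C = NULL, observed_min_p,
                                 min_perm = 1000, max_perm = 10000,
                                 stop_exceedances = 15, batch = 1000,
                                 seed = 1L) {
  n <- length(y)
  stopifnot(nrow(G) == n, is.finite(observed_min_p))
  Q <- covariate_basis(C, n)
  y_r <- y - Q %*% crossprod(Q, y)
  yss <- sum(y_r^2)
  G2 <- colSums(G^2)
  tol <- max(G2, 1) * 1e-10
  df <- n - ncol(Q) - 1L
  # permuting genotype rows by idx equals permuting (y, covariates) jointly
  # by the inverse permutation; the compiled batch does one small matrix
  # product per draw
  M <- cbind(as.numeric(y_r), Q)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  r <- 0L
  nperm <- 0L
  repeat {
    nb <- min(batch, max_perm - nperm)
    r <- r + perm_scan_batch(M, G, G2, yss, df, tol, observed_min_p, nb)
    nperm <- nperm + nb
    if ((nperm >= min_perm && r >= stop_exceedances) || nperm >= max_perm)
      break
  }
  structure(list(n_permutations = nperm, n_exceedances = r,
                 empirical_p = (r + 1) / (nperm + 1), seed = seed),
            class = "permutation_result")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Run adaptive permutations for every scanned exon
#'
#' Permutation streams are exon-indexed: exon i uses
#' \code{child_seed(seed, i)}, so the same master seed reproduces every
#' exon's empirical p exactly, in any order and for any subset.
#'
#' @param norm_expr a \code{normalized_expression} object.
#' @param gm post-QC \code{\link{genotype_matrix}}.
#' @param scan_index per-exon index table from \code{\link{map_cis_eqtl}}.
#' @param C optional covariate matrix.
#' @param flank cis window half-width (must match the scan).
#' @param min_perm,max_perm,stop_exceedances,batch see
#'   \code{\link{adaptive_permutation}}.
#' @param seed master seed.
#' @return \code{scan_index} with columns \code{n_permutations},
#'   \code{n_exceedances}, \code{empirical_p} appended.
#' @export
permute_study <- function(norm_expr, gm, scan_index, C = NULL, flank = 1e6,
                          min_perm = 1000, max_perm = 10000,
                          stop_exceedances = 15, batch = 1000, seed = 1L) {
  stopifnot(inherits(norm_expr, "normalized_expression"))
  exons <- norm_expr$exons
  rows <- match(scan_index$exon_id, exons$exon_id)
  assert_that(!anyNA(rows), "scan_index contains exons absent from norm_expr")
  v <- gm$variants
  out <- data.frame(n_permutations = integer(nrow(scan_index)),
                    n_exceedances = integer(nrow(scan_index)),
                    empirical_p = numeric(nrow(scan_index)))
  for (k in seq_len(nrow(scan_index))) {
    i <- rows[k]
    ex <- exons[i, ]
    win <- define_cis_window(ex$tss, flank)
    in_win <- v$chrom == ex$chrom & v$pos >= win[1] & v$pos <= win[2]
    pr <- adaptive_permutation(
      norm_expr$mat[i, ], gm$dosages[, in_win, drop = FALSE], C,
      observed_min_p = scan_index$min_p[k],
      min_perm = min_perm, max_perm = max_perm,
      stop_exceedances = stop_exceedances, batch = batch,
      seed = child_seed(seed, i)
    )
    out$n_permutations[k] <- pr$n_permutations
    out$n_exceedances[k] <- pr$n_exceedances
    out$empirical_p[k] <- pr$empirical_p
  }
  cbind(scan_index, out)
}

#' Storey q-values and null-proportion estimate
#'
#' The null proportion is estimated on the lambda grid 0.05, 0.10, ..., 0.95
#' as \code{mean(p > lambda) / (1 - lambda)}, smoothed with a cubic
#' smoothing spline and evaluated at lambda = 0.95, then clamped to (0, 1].
#' q-values follow the step-up rule
#' \code{q(p_(i)) = min_{j >= i} pi0 * m * p_(j) / j} and are monotone
#' non-decreasing in p.  For fewer than 100 p-values the grid estimate is
#' unstable and a fixed lambda = 0.5 is used, with a warning.
#'
#' @param pvals p-values in (0, 1].
#' @param pi0 optional fixed null proportion overriding the estimate.
#' @return list with \code{q} (same order as input) and \code{pi0}.
#' @export
storey_qvalues <- function(pvals, pi0 = NULL) {
  assert_that(length(pvals) > 0, "storey_qvalues: empty p-value vector")
  assert_that(all(pvals > 0 & pvals <= 1), "storey_qvalues: p-values must be in (0, 1]")
  m <- length(pvals)
  if (is.null(pi0)) {
    if (m < 100) {
      warning("storey_qvalues: fewer than 100 p-values; using fixed lambda = 0.5")
      pi0 <- mean(pvals > 0.5) / 0.5
    } else {
      lambda <- seq(0.05, 0.95, by = 0.05)
      pi0_l <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = 0.95)$y
    }
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  o <- order(pvals)
  q_sorted <- pi0 * m * pvals[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  list(q = q, pi0 = pi0)
}

#' Replication rate pi1 from a vector of replication p-values
#'
#' \code{pi1 = 1 - pi0} of the replication p-value vector for a
#' discovery-significant set: the estimated fraction of discoveries whose
#' association is also present in the replication data.
#'
#' @param replication_pvals p-values in (0, 1] for the discovery-significant
#'   associations, computed in the replication cohort.
#' @return pi1 estimate in [0, 1].
#' @export
estimate_pi1 <- function(replication_pvals) {
  assert_that(length(replication_pvals) > 0, "estimate_pi1: empty input")
  if (length(replication_pvals) < 100)
    warning("estimate_pi1: fewer than 100 p-values; estimate will be unstable")
  1 - storey_qvalues(replication_pvals)$pi0
}

#' Assemble the FDR table with significance tiers
#'
#' @param perm_table output of \code{\link{permute_study}}.
#' @param q_threshold study-wide q cutoff (default 0.05).
#' @param nominal_threshold nominal empirical-p cutoff (default 0.05).
#' @return \code{perm_table} with \code{q}, \code{significant},
#'   \code{nominal} and \code{tier} ("study_wide", "nominal", "ns")
#'   appended; the pi0 estimate is attached as attribute \code{"pi0"}.
#' @export
fdr_table <- function(perm_table, q_threshold = 0.05, nominal_threshold = 0.05) {
  st <- storey_qvalues(perm_table$empirical_p)
  perm_table$q <- st$q
  perm_table$significant <- perm_table$q < q_threshold
  perm_table$nominal <- perm_table$empirical_p < nominal_threshold
  perm_table$tier <- ifelse(perm_table$significant, "study_wide",
                            ifelse(perm_table$nominal, "nominal", "ns"))
  attr(perm_table, "pi0") <- st$pi0
  perm_table
}
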