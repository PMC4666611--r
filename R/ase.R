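#' Wilcoxon signed-rank test of allelic imbalance at one site
#'
#' For each heterozygous sample with total depth >= \code{min_depth}, the
#' deviation of the alt-allele fraction from 0.5 is computed; zero
#' deviations are dropped (classical Wilcoxon convention) and the signed
#' ranks of the remainder are tested against symmetry.  The null
#' distribution is exact for n <= 25 (all 2^n sign assignments, handled via
#' the generating-polynomial of the doubled average ranks so ties are
#' exact too); above that a normal approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param site data.frame with \code{ref_count} and \code{alt_count}
#'   columns, one row per heterozygous sample.
#' @param min_depth minimum total depth per sample (default 10).
#' @return two-sided p-value in (0, 1].
#' @export
wilcoxon_ase_test <- function(site, min_depth = 10) {
  stopifnot(is.data.frame(site),
            all(c("ref_count", "alt_count") %in% names(site)))
  depth <- site$ref_count + site$alt_count
  keep <- depth >= min_depth
  assert_that(any(keep), "wilcoxon_ase_test: no sample meets min_depth")
  # (alt - ref) / (2 depth) equals alt/(ref+alt) - 0.5 and is exactly
  # antisymmetric under ref/alt relabeling
  d <- (site$alt_count[keep] - site$ref_count[keep]) / (2 * depth[keep])
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1.0)   # every informative fraction exactly 0.5
  r <- rank(abs(d), ties.method = "average")
  if (n <= 25) {
    w <- as.integer(round(2 * r))         # doubled ranks are integers
    w_obs <- sum(w[d > 0])
    dist <- signed_rank_distribution(w)
    p_le <- sum(dist$prob[dist$w <= w_obs])
    p_ge <- sum(dist$prob[dist$w >= w_obs])
    return(min(1, 2 * min(p_le, p_ge)))
  }
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

# Exact distribution of the signed-rank sum over all equal-probability sign
# assignments, for integer rank weights w: generating polynomial
# prod_i (1 + x^{w_i}) / 2.
signed_rank_distribution <- function(w) {
  total <- sum(w)
  prob <- c(1, numeric(total))            # index i holds P(W = i - 1)
  for (wi in w) {
    shifted <- c(numeric(wi), prob[seq_len(total + 1 - wi)])
    prob <- (prob + shifted) / 2
  }
  list(w = 0:total, prob = prob)
}

#' Test allelic imbalance across many sites
#'
#' @param ase data.frame with columns \code{variant}, \code{sample},
#'   \code{ref_count}, \code{alt_count}.
#' @param min_depth minimum total depth per sample.
#' @return data.frame: one row per variant with \code{n_het} (samples
#'   meeting depth), \code{median_alt_fraction} and \code{p}.
#' @export
ase_report <- function(ase, min_depth = 10) {
  stopifnot(all(c("variant", "ref_count", "alt_count") %in% names(ase)))
  out <- lapply(split(ase, ase$variant), function(s) {
    depth <- s$ref_count + s$alt_count
    ok <- depth >= min_depth
    data.frame(
      variant = s$variant[1], n_het = sum(ok),
      median_alt_fraction = if (any(ok))
        stats::median(s$alt_count[ok] / depth[ok]) else NA_real_,
      p = if (any(ok)) wilcoxon_ase_test(s, min_depth) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$variant), , drop = FALSE]
}
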