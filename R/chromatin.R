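#' Construct a chromatin-state annotation
#'
#' Intervals are stored 0-based half-open (BED convention); variant
#' positions everywhere else in the package are 1-based.  Multiple source
#' datasets are allowed; overlap semantics downstream are "in at least one
#' dataset" by default.
#'
#' @param intervals data.frame with columns \code{chrom}, \code{start}
#'   (0-based), \code{end} (exclusive), \code{state}, and optionally
#'   \code{dataset} (default "dataset1").
#' @return object of class \code{chromatin_annotation}.
#' @export
chromatin_annotation <- function(intervals) {
  stopifnot(is.data.frame(intervals))
  need <- c("chrom", "start", "end", "state")
  assert_that(all(need %in% names(intervals)),
              paste("intervals must have columns:", paste(need, collapse = ", ")))
  assert_that(all(intervals$start < intervals$end),
              "chromatin intervals must satisfy start < end")
  if (is.null(intervals$dataset)) intervals$dataset <- "dataset1"
  structure(intervals, class = c("chromatin_annotation", "data.frame"))
}

#' Flag variants overlapping chromatin states
#'
#' A variant at 1-based position p overlaps a 0-based half-open interval
#' [s, e) iff s < p <= e.  A variant is flagged when any interval of any
#' requested state, in any dataset (or in the given subset of datasets),
#' covers it.  Variants on chromosomes absent from the annotation are
#' flagged \code{FALSE} with a warning.
#'
#' @param variants data.frame with \code{id}, \code{chrom}, \code{pos}.
#' @param annotation a \code{\link{chromatin_annotation}}.
#' @param states states to count (default enhancer/promoter).
#' @param datasets optional dataset subset (default: all).
#' @return logical vector, one flag per variant.
#' @export
overlap_variants <- function(variants, annotation,
                             states = c("enhancer", "promoter"),
                             datasets = NULL) {
  stopifnot(inherits(annotation, "chromatin_annotation"))
  ann <- annotation[annotation$state %in% states, , drop = FALSE]
  if (!is.null(datasets)) ann <- ann[ann$dataset %in% datasets, , drop = FALSE]
  if (nrow(variants) == 0) return(logical(0))
  unknown <- !(variants$chrom %in% unique(annotation$chrom))
  if (any(unknown))
    warning("overlap_variants: ", sum(unknown),
            " variant(s) on chromosomes absent from the annotation")
  if (nrow(ann) == 0) return(rep(FALSE, nrow(variants)))
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  # BED [s, e) covers 1-based positions s+1 .. e
  ar <- GenomicRanges::GRanges(ann$chrom,
                               IRanges::IRanges(ann$start + 1, ann$end))
  IRanges::overlapsAny(vr, ar)
}

#' Enrichment of foreground variants in chromatin states
#'
#' Two-sided Fisher's exact test on the 2x2 table {foreground, background}
#' x {overlap, no overlap}, plus a resampling p-value: each of
#' \code{n_samplings} draws takes |foreground| variants from the background
#' pool without replacement and records its overlap count;
#' \code{resampling_p = (#{draws >= observed} + 1) / (n_samplings + 1)}.
#' Fold is the ratio of overlap rates.
#'
#' @param fg_variants,bg_variants data.frames with \code{id}, \code{chrom},
#'   \code{pos}.
#' @param annotation a \code{\link{chromatin_annotation}}.
#' @param states active states to count.
#' @param n_samplings number of resampling draws (default 10000).
#' @param seed RNG seed for the resampling.
#' @return list of class \code{enrichment_result}: counts, \code{fold}
#'   (Inf with \code{fold_undefined = TRUE} when the background never
#'   overlaps), \code{fisher_p} (two-sided; one-sided values in
#'   \code{fisher_p_greater} / \code{fisher_p_less}), \code{resampling_p},
#'   \code{n_samplings}.
#' @export
enrichment_test <- function(fg_variants, bg_variants, annotation,
                            states = c("enhancer", "promoter"),
                            n_samplings = 10000, seed = 1L) {
  assert_that(nrow(bg_variants) >= nrow(fg_variants),
              "enrichment_test: background pool smaller than foreground")
  fg <- overlap_variants(fg_variants, annotation, states)
  bg <- overlap_variants(bg_variants, annotation, states)
  n_fg <- length(fg); n_fg_ov <- sum(fg)
  n_bg <- length(bg); n_bg_ov <- sum(bg)
  tab <- matrix(c(n_fg_ov, n_fg - n_fg_ov, n_bg_ov, n_bg - n_bg_ov), nrow = 2)
  fisher_two <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  fisher_gr <- stats::fisher.test(tab, alternative = "greater")$p.value
  fisher_le <- stats::fisher.test(tab, alternative = "less")$p.value
  fold_undefined <- n_bg_ov == 0
  fold <- if (fold_undefined) Inf else (n_fg_ov / n_fg) / (n_bg_ov / n_bg)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draws <- vapply(seq_len(n_samplings),
                  function(i) sum(sample(bg, n_fg)), numeric(1))
  resampling_p <- (sum(draws >= n_fg_ov) + 1) / (n_samplings + 1)
  structure(list(n_fg = n_fg, n_fg_overlap = n_fg_ov,
                 n_bg = n_bg, n_bg_overlap = n_bg_ov,
                 fold = fold, fold_undefined = fold_undefined,
                 fisher_p = fisher_two, fisher_p_greater = fisher_gr,
                 fisher_p_less = fisher_le,
                 resampling_p = resampling_p, n_samplings = n_samplings),
            class = "enrichment_result")
}

#' Overlap rate restricted to annotated variants
#'
#' Recomputes the overlap rate after discarding variants absent from every
#' annotation source (no chromatin call of any state in any dataset).
#'
#' @param overlap_flags logical: variant overlaps an active state.
#' @param annotated_flags logical: variant has any annotation at all.
#' @return fraction of annotated variants overlapping an active state.
#' @export
restricted_overlap_rate <- function(overlap_flags, annotated_flags) {
  stopifnot(length(overlap_flags) == length(annotated_flags))
  assert_that(any(annotated_flags),
              "restricted_overlap_rate: no variant has any annotation")
  sum(overlap_flags & annotated_flags) / sum(annotated_flags)
}
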