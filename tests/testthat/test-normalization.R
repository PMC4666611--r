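make_ec <- function(counts) {
  n_ex <- nrow(counts)
  exon_counts(counts, data.frame(
    exon_id = paste0("e", seq_len(n_ex)), gene_id = "G1", chrom = "chr1",
    start = seq_len(n_ex) * 1000, end = seq_len(n_ex) * 1000 + 200,
    strand = "+", tss = 500, stringsAsFactors = FALSE))
}

test_that("filter_exons supports the zero-count and non-zero-fraction rules", {
  set.seed(1)
  n <- 118
  base <- matrix(rpois(3 * n, 50), 3, n)
  m <- rbind(base, many0 = replace(rpois(n, 5), 1:12, 0),
             few0 = replace(rpois(n, 5) + 1, 1:9, 0))
  ec <- make_ec(m)
  kept <- filter_exons(ec, max_zero_samples = 10)
  expect_true("e5" %in% kept$exons$exon_id)    # 9 zeros: retained
  expect_false("e4" %in% kept$exons$exon_id)   # 12 zeros: removed
  # fraction mode recomputed by direct count
  kept_f <- filter_exons(ec, mode = "fraction", min_nonzero_fraction = 0.10)
  nz <- rowSums(ec$counts != 0)
  expect_identical(kept_f$exons$exon_id,
                   ec$exons$exon_id[nz >= ceiling(0.10 * n)])
  expect_error(filter_exons(make_ec(matrix(0L, 1, n))), "all exons removed")
})

test_that("scale_to_median_depth equalizes column totals at the median", {
  m <- matrix(c(1e6, 2e6, 4e6), 1, 3, dimnames = list("e1", c("a", "b", "c")))
  s <- scale_to_median_depth(m)
  expect_equal(unname(s[1, ] / m[1, ]), c(2, 1, 0.5))
  set.seed(2)
  m2 <- matrix(rpois(500, 40), 50, 10)
  s2 <- scale_to_median_depth(m2)
  expect_equal(unname(colSums(s2)), rep(median(colSums(m2)), 10))
  expect_equal(scale_to_median_depth(cbind(m2[, 1], m2[, 1])),
               cbind(m2[, 1], m2[, 1]))
})

test_that("inverse_normal_transform produces average-rank normal scores", {
  expect_equal(inverse_normal_transform(c(3, 1, 2)),
               qnorm(c(5 / 6, 1 / 6, 0.5)))
  expect_equal(inverse_normal_transform(c(1, 1, 2)),
               qnorm(c(1 / 3, 1 / 3, 5 / 6)))
  x <- rexp(50)
  expect_equal(inverse_normal_transform(x), inverse_normal_transform(x^3))
  expect_error(inverse_normal_transform(rep(2, 5)), "constant")
})

test_that("normalized rows are exact normal scores (KS distance at the tie-free bound)", {
  set.seed(3)
  n <- 80
  m <- matrix(rpois(20 * n, 200), 20, n)
  norm <- normalize_expression(make_ec(m))
  for (i in c(1, 7, 20)) {
    row <- norm$mat[i, ]
    if (anyDuplicated(round(row, 10))) next
    ks <- suppressWarnings(ks.test(row, pnorm)$statistic)
    expect_lte(unname(ks), 0.5 / n + 1e-9)
    expect_lt(abs(mean(row)), 0.05)
  }
})

test_that("infer_hidden_factors recovers planted structure and is orthonormal", {
  set.seed(6)
  n <- 100
  f_true <- rnorm(n)
  lam <- rnorm(200, 0, 2)
  mat <- outer(lam, f_true) + matrix(rnorm(200 * n, 0, 0.3), 200, n)
  covs <- infer_hidden_factors(mat, k = 3)
  expect_gt(abs(cor(covs[, 1], f_true)), 0.99)
  expect_equal(crossprod(covs[, 1:3]), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  sex <- rep(c(0, 1), length.out = n)
  only_sex <- infer_hidden_factors(mat, k = 0, sex = sex)
  expect_identical(colnames(only_sex), "sex")
  with_sex <- infer_hidden_factors(mat, k = 2, sex = sex)
  expect_identical(colnames(with_sex), c("factor1", "factor2", "sex"))
  expect_s3_class(attr(with_sex, "sex_screen"), "data.frame")
  expect_error(infer_hidden_factors(mat, k = n), "smaller than")
})

test_that("regressing out inferred factors restores detection power", {
  # the inverse-normal transform fixes each exon's marginal variance, so
  # confounder variance attenuates the planted signal; removing the
  # inferred factors must bring the association strength back to the
  # no-confounder baseline
  cfg_conf <- study_config(n_samples = 150, n_genes = 12, n_exons = 4,
                           planted_genes = 1, beta = 1,
                           n_hidden_factors = 2, factor_sd = 1, seed = 21)
  st_raw <- run_study(cfg_conf, k = 0)
  st_adj <- run_study(cfg_conf, k = 2)
  cfg_base <- study_config(n_samples = 150, n_genes = 12, n_exons = 4,
                           planted_genes = 1, beta = 1,
                           n_hidden_factors = 0, seed = 21)
  st_base <- run_study(cfg_base, k = 0)
  t_of <- function(st) {
    rows <- st$scan$gene_id == "G001"
    mean(abs(st$scan$beta[rows] / st$scan$se[rows]))
  }
  expect_gt(t_of(st_adj), t_of(st_raw))
  expect_gt(t_of(st_adj), 0.8 * t_of(st_base))
})

test_that("RPKM arithmetic and the expressed call behave at the boundary", {
  expect_equal(compute_rpkm(matrix(100), 500, 1e7)[1, 1], 20)
  expect_equal(compute_rpkm(matrix(0), 500, 1e7)[1, 1], 0)
  expect_false(is_expressed(0.09))
  expect_true(is_expressed(0.10))
  expect_false(is_expressed(0))
  expect_error(compute_rpkm(matrix(1), 0, 1e7), "length")
})
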