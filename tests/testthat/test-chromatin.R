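test_that("variant-interval overlap respects half-open BED coordinates", {
  ann <- chromatin_annotation(data.frame(chrom = "chr1", start = 999,
                                         end = 1005, state = "enhancer"))
  v <- data.frame(id = c("a", "b", "c"), chrom = "chr1",
                  pos = c(1000, 1005, 1006))
  flags <- overlap_variants(v, ann)
  expect_identical(flags, c(TRUE, TRUE, FALSE))
  # position exactly start is NOT covered (BED start is 0-based)
  v2 <- data.frame(id = "d", chrom = "chr1", pos = 999)
  expect_false(overlap_variants(v2, ann))
  # unknown chromosome: FALSE with a warning
  v3 <- data.frame(id = "e", chrom = "chrX", pos = 1000)
  expect_warning(f3 <- overlap_variants(v3, ann), "absent")
  expect_false(f3)
  # states filter and dataset union
  ann2 <- chromatin_annotation(data.frame(
    chrom = "chr1", start = c(999, 2000), end = c(1005, 2100),
    state = c("repressed", "promoter"), dataset = c("d1", "d2")))
  expect_false(overlap_variants(v[1, ], ann2))
  expect_true(overlap_variants(data.frame(id = "f", chrom = "chr1",
                                          pos = 2050), ann2))
})

test_that("overlap is invariant to interval fragmentation", {
  set.seed(71)
  pos <- sort(sample(1:10000, 200))
  v <- data.frame(id = paste0("v", 1:200), chrom = "chr1", pos = pos)
  whole <- chromatin_annotation(data.frame(chrom = "chr1", start = 3000,
                                           end = 7000, state = "enhancer"))
  cuts <- sort(c(3000, sample(3001:6999, 5), 7000))
  pieces <- chromatin_annotation(data.frame(
    chrom = "chr1", start = head(cuts, -1), end = cuts[-1],
    state = "enhancer"))
  expect_identical(overlap_variants(v, whole), overlap_variants(v, pieces))
})

test_that("enrichment fold and Fisher p match the hypergeometric oracle", {
  # fg 6/10 overlap, bg 30/100 overlap
  ann <- chromatin_annotation(data.frame(chrom = "chr1", start = 0,
                                         end = 1000, state = "enhancer"))
  fg <- data.frame(id = paste0("f", 1:10), chrom = "chr1",
                   pos = c(1:6 * 100, 2000 + 1:4))
  bg <- data.frame(id = paste0("b", 1:100), chrom = "chr1",
                   pos = c(1:30 * 10 + 3, 5000 + 1:70))
  er <- enrichment_test(fg, bg, ann, n_samplings = 500, seed = 2)
  expect_equal(er$fold, 2.0)
  expect_equal(er$fisher_p, fisher_oracle(6, 4, 30, 70), tolerance = 1e-10)
  expect_equal(er$n_fg_overlap, 6)
  expect_equal(er$n_bg_overlap, 30)
})

test_that("fisher.test agrees with the enumeration oracle over exhaustive and random tables", {
  for (n in c(2:12, 20, 25)) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      expect_equal(fisher.test(matrix(c(a, b, cc, d), 2))$p.value,
                   fisher_oracle(a, b, cc, d), tolerance = 1e-8)
    }
  }
  set.seed(72)
  for (i in 1:100) {
    x <- as.vector(rmultinom(1, sample(30:200, 1), runif(4, 0.05, 1)))
    expect_equal(fisher.test(matrix(x, 2))$p.value,
                 fisher_oracle(x[1], x[2], x[3], x[4]), tolerance = 1e-8)
  }
})

test_that("the resampling p-value follows its convention and tracks Fisher", {
  ann <- chromatin_annotation(data.frame(chrom = "chr1", start = 0,
                                         end = 10000, state = "enhancer"))
  # every fg variant overlaps, no bg variant does: maximal significance
  fg <- data.frame(id = paste0("f", 1:20), chrom = "chr1", pos = 1:20 * 100)
  bg <- data.frame(id = paste0("b", 1:200), chrom = "chr1",
                   pos = 20000 + 1:200)
  er <- enrichment_test(fg, bg, ann, n_samplings = 1000, seed = 3)
  expect_equal(er$resampling_p, 1 / 1001)
  expect_true(er$fold_undefined)
  expect_true(is.infinite(er$fold))
  # rank correlation between Fisher and resampling p across scenarios
  set.seed(73)
  fp <- rp <- numeric(40)
  for (i in 1:40) {
    rate_fg <- runif(1, 0.1, 0.6)
    pos_fg <- ifelse(runif(50) < rate_fg, 1, 30000) + sample(1:9000, 50, TRUE)
    pos_bg <- ifelse(runif(300) < 0.2, 1, 30000) + sample(1:9000, 300, TRUE)
    fgv <- data.frame(id = paste0("f", 1:50), chrom = "chr1", pos = pos_fg)
    bgv <- data.frame(id = paste0("b", 1:300), chrom = "chr1", pos = pos_bg)
    er_i <- enrichment_test(fgv, bgv, ann, n_samplings = 300, seed = i)
    fp[i] <- er_i$fisher_p_greater
    rp[i] <- er_i$resampling_p
  }
  expect_gt(cor(fp, rp, method = "spearman"), 0.8)
})

test_that("restricted_overlap_rate drops unannotated variants from the denominator", {
  ov <- c(rep(TRUE, 735), rep(FALSE, 2341 - 735))
  annotated <- c(rep(TRUE, 1252), rep(FALSE, 2341 - 1252))
  expect_equal(mean(ov), 735 / 2341)
  expect_equal(restricted_overlap_rate(ov, annotated), 735 / 1252)
  expect_equal(restricted_overlap_rate(ov, rep(TRUE, 2341)), 735 / 2341)
  expect_error(restricted_overlap_rate(ov, rep(FALSE, 2341)), "no variant")
})
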