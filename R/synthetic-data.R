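#' Configuration for a synthetic eQTL study
#'
#' Describes a cohort of unrelated samples, variants organized in LD blocks,
#' multi-exon genes, planted cis-eQTL effects on the inverse-normal
#' expression scale, hidden confounding factors and sequencing depths.  All
#' randomness downstream flows from \code{seed} through per-component child
#' seeds (see \code{\link{child_seed}}).
#'
#' @param n_samples number of samples (>= 2).
#' @param ld_blocks list; each element a list/vector with \code{n_variants},
#'   \code{target_r2} in [0, 1] and \code{maf} in (0, 0.5].
#' @param genes list; each element a list with \code{gene_id},
#'   \code{n_exons}, \code{tss} (bp) and \code{strand} ("+"/"-").  When
#'   omitted, gene i is laid out at \code{tss = (i - 1) * 2.5e6 + 1.2e6}
#'   on "chr1", "+" strand, paired with LD block i whose variants sit within
#'   25 kb of the TSS -- so each 1 Mb cis window contains exactly its own
#'   block.
#' @param planted_eqtls data.frame with columns \code{gene}, \code{variant},
#'   \code{beta} (effect per alt allele on the inverse-normal scale); zero
#'   rows for a null study.
#' @param n_hidden_factors,factor_sd hidden confounders: per-sample factor
#'   scores are standard normal, per-exon loadings are N(0, factor_sd^2).
#' @param noise_sd per-exon residual sd of the latent signal.
#' @param latent_gain slope from latent signal to log count mean.
#' @param library_size_range min/max total reads per sample.
#' @param flip_exons optional character vector of exon ids whose planted
#'   effect sign is flipped (to exercise directional-consistency checks).
#' @param seed master seed.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 118,
                       ld_blocks = replicate(10, list(n_variants = 50,
                                                      target_r2 = 0.95,
                                                      maf = 0.3),
                                             simplify = FALSE),
                       genes = NULL,
                       planted_eqtls = data.frame(gene = character(),
                                                  variant = character(),
                                                  beta = numeric()),
                       n_hidden_factors = 3, factor_sd = 0.7,
                       noise_sd = 0.8, latent_gain = 0.7,
                       library_size_range = c(3e7, 1e8),
                       flip_exons = character(), seed = 1L) {
  assert_that(n_samples >= 2, "sim_config: n_samples must be >= 2")
  for (b in ld_blocks) {
    assert_that(b$n_variants >= 1, "sim_config: each block needs >= 1 variant")
    assert_that(b$maf > 0 && b$maf <= 0.5,
                "sim_config: maf must be in (0, 0.5]")
    assert_that(b$target_r2 >= 0 && b$target_r2 <= 1,
                "sim_config: target_r2 must be in [0, 1]")
  }
  if (is.null(genes)) {
    genes <- lapply(seq_along(ld_blocks), function(i)
      list(gene_id = sprintf("G%03d", i), n_exons = 4,
           tss = (i - 1) * 2.5e6 + 1.2e6, strand = "+"))
  }
  assert_that(all(is.finite(planted_eqtls$beta)),
              "sim_config: planted betas must be finite")
  assert_that(all(library_size_range > 0) && diff(library_size_range) >= 0,
              "sim_config: library sizes must be positive, min <= max")
  structure(list(n_samples = n_samples, ld_blocks = ld_blocks, genes = genes,
                 planted_eqtls = planted_eqtls,
                 n_hidden_factors = n_hidden_factors, factor_sd = factor_sd,
                 noise_sd = noise_sd, latent_gain = latent_gain,
                 library_size_range = library_size_range,
                 flip_exons = flip_exons, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate genotype dosages with block LD structure
#'
#' Each block has a latent founder haplotype pair per sample; every emitted
#' variant copies the founder allele with probability 1 - s and redraws a
#' fresh Bernoulli(maf) allele otherwise, with
#' \code{s = 1 - target_r2^(1/4)}, which makes the expected pairwise r2
#' between any two block variants equal to \code{target_r2} (each variant
#' correlates with the founder at r = (1 - s)^2).  Dosages are the sum of
#' the two haplotypes: values in {0, 1, 2} under Hardy-Weinberg at the
#' block MAF.  Block i's variants are placed 1 kb apart starting 25 kb
#' upstream of gene i's TSS.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{\link{genotype_matrix}} with a \code{block} column in its
#'   variant table.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(config$seed, 1))
  n <- config$n_samples
  dos <- list(); meta <- list()
  for (i in seq_along(config$ld_blocks)) {
    b <- config$ld_blocks[[i]]
    gene <- config$genes[[min(i, length(config$genes))]]
    m <- b$n_variants
    s <- 1 - b$target_r2^(1 / 4)
    f1 <- matrix(stats::rbinom(n, 1, b$maf), n, 1)
    f2 <- matrix(stats::rbinom(n, 1, b$maf), n, 1)
    h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      keep1 <- stats::runif(n) < 1 - s
      keep2 <- stats::runif(n) < 1 - s
      h1[, j] <- ifelse(keep1, f1, stats::rbinom(n, 1, b$maf))
      h2[, j] <- ifelse(keep2, f2, stats::rbinom(n, 1, b$maf))
    }
    d <- h1 + h2
    pos <- gene$tss - 25000 + (seq_len(m) - 1) * 1000
    meta[[i]] <- data.frame(
      id = sprintf("%s_v%02d", gene$gene_id, seq_len(m)),
      chrom = "chr1", pos = pos, ref = "A", alt = "G",
      info = 1, typed = FALSE, block = i, stringsAsFactors = FALSE
    )
    dos[[i]] <- d
  }
  d <- do.call(cbind, dos)
  rownames(d) <- sprintf("S%03d", seq_len(n))
  genotype_matrix(d, do.call(rbind, meta))
}

#' Simulate exon counts with planted cis-eQTL effects
#'
#' The latent per-exon signal is \code{beta * dosage + loadings \%*\% factors
#' + noise}; counts are Poisson with log mean
#' \code{log(lib/1e6) + a_e + latent_gain * latent}, where \code{a_e} is a
#' per-exon baseline (log CPM drawn log-uniformly in [2, 50]) and lib the
#' sample's library size.  All exons of a gene share the gene's planted
#' beta, except exons listed in \code{config$flip_exons}, whose sign is
#' flipped.  Exon ids are \code{<gene>_e<j>}.
#'
#' @param gm genotypes from \code{\link{simulate_genotypes}}.
#' @param config the same \code{\link{sim_config}}.
#' @return list with \code{counts} (an \code{\link{exon_counts}}) and
#'   \code{truth} (class \code{sim_truth}: planted effects with per-exon
#'   signs, factor score matrix, loadings, library sizes).
#' @export
simulate_expression <- function(gm, config) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(config, "sim_config"))
  pe <- config$planted_eqtls
  missing_v <- setdiff(pe$variant, gm$variants$id)
  if (length(missing_v))
    stop("simulate_expression: planted variant(s) not in genotypes: ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(config$seed, 2))
  n <- config$n_samples
  lib <- round(stats::runif(n, config$library_size_range[1],
                            config$library_size_range[2]))
  K <- config$n_hidden_factors
  f <- if (K > 0) matrix(stats::rnorm(K * n), K, n) else
    matrix(0, 0, n)
  exon_rows <- list(); latent <- list(); load_rows <- list()
  planted_rows <- list()
  for (g in config$genes) {
    j <- match(g$gene_id, pe$gene)
    beta <- if (is.na(j)) 0 else pe$beta[j]
    gdos <- if (is.na(j)) numeric(n) else gm$dosages[, pe$variant[j]]
    for (e in seq_len(g$n_exons)) {
      start <- g$tss + 200 + (e - 1) * 1500
      end <- start + 300
      exon_id <- sprintf("%s_e%d", g$gene_id, e)
      if (identical(g$strand, "-")) {
        # mirror the exon upstream so the annotated end equals the TSS anchor
        end2 <- g$tss - 200 - (e - 1) * 1500
        start <- end2 - 300; end <- end2
      }
      b_e <- if (exon_id %in% config$flip_exons) -beta else beta
      lam <- if (K > 0) stats::rnorm(K, 0, config$factor_sd) else numeric(0)
      lat <- b_e * gdos +
        (if (K > 0) drop(lam %*% f) else 0) +
        stats::rnorm(n, 0, config$noise_sd)
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        exon_id = exon_id, gene_id = g$gene_id, chrom = "chr1",
        start = start, end = end, strand = g$strand, tss = g$tss,
        stringsAsFactors = FALSE
      )
      latent[[length(latent) + 1L]] <- lat
      load_rows[[length(load_rows) + 1L]] <- lam
      if (!is.na(j))
        planted_rows[[length(planted_rows) + 1L]] <- data.frame(
          gene = g$gene_id, exon = exon_id, variant = pe$variant[j],
          beta = b_e, stringsAsFactors = FALSE
        )
    }
  }
  exons <- do.call(rbind, exon_rows)
  lat <- do.call(rbind, latent)
  a_e <- stats::runif(nrow(exons), log(2), log(50))   # log baseline CPM
  mu <- exp(sweep(config$latent_gain * lat, 1, a_e, `+`))
  mu <- sweep(mu, 2, lib / 1e6, `*`)
  counts <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
  colnames(counts) <- rownames(gm$dosages)
  ec <- exon_counts(counts, exons)
  truth <- structure(list(
    planted = do.call(rbind, planted_rows) %||%
      data.frame(gene = character(), exon = character(),
                 variant = character(), beta = numeric()),
    factors = f, loadings = do.call(rbind, load_rows),
    library_sizes = lib, gwas_map = list()
  ), class = "sim_truth")
  list(counts = ec, truth = truth)
}

#' Simulate GWAS lead variants sharing or not sharing eQTL causal variants
#'
#' One locus per element of \code{shared}.  A shared locus takes the i-th
#' planted eQTL (in order) and picks as lead the block variant with the
#' highest realized r2 > 0.8 to the planted variant, preferring a proxy over
#' the planted variant itself (using the variant itself is allowed and
#' flagged \code{identical_to_eqtl}).  An independent locus picks, from a
#' block containing no planted variant, a variant whose realized r2 to every
#' planted variant is < 0.05.  The risk allele is the alt allele.
#'
#' @param gm genotypes from \code{\link{simulate_genotypes}}.
#' @param truth \code{sim_truth} from \code{\link{simulate_expression}}.
#' @param shared logical vector, one flag per locus.
#' @param trait trait label(s) recycled over loci.
#' @return list with \code{loci} (GWAS-lead data.frame: \code{locus},
#'   \code{trait}, \code{variant}, \code{chrom}, \code{pos},
#'   \code{risk_allele}, \code{other_allele}, \code{identical_to_eqtl}) and
#'   \code{truth} with its locus-to-causal-variant map filled in.
#' @export
simulate_gwas_loci <- function(gm, truth, shared, trait = "T2D") {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(truth, "sim_truth"))
  v <- gm$variants
  planted_variants <- unique(truth$planted$variant)
  planted_genes <- unique(truth$planted$gene)
  assert_that(sum(shared) <= length(planted_variants),
              "simulate_gwas_loci: more shared loci than planted eQTLs")
  planted_blocks <- v$block[match(planted_variants, v$id)]
  free_blocks <- setdiff(unique(v$block), planted_blocks)
  trait <- rep_len(trait, length(shared))
  loci <- list()
  i_shared <- 0L; i_free <- 0L
  for (li in seq_along(shared)) {
    if (shared[li]) {
      i_shared <- i_shared + 1L
      pv <- planted_variants[i_shared]
      blk <- planted_blocks[i_shared]
      cand <- which(v$block == blk)
      g0 <- gm$dosages[, pv]
      r2 <- vapply(cand, function(j) {
        gj <- gm$dosages[, j]
        if (stats::var(gj) == 0) return(NA_real_)
        stats::cor(gj, g0)^2
      }, numeric(1))
      ok <- !is.na(r2) & r2 > 0.8
      proxies <- cand[ok & v$id[cand] != pv]
      pick <- if (length(proxies))
        proxies[which.max(r2[match(proxies, cand)])]
      else if (any(ok & v$id[cand] == pv)) cand[v$id[cand] == pv]
      else stop("simulate_gwas_loci: no proxy with r2 > 0.8 for planted variant ",
                pv, call. = FALSE)
      ident <- v$id[pick] == pv
      truth$gwas_map[[sprintf("locus%02d", li)]] <-
        list(type = "shared", eqtl_variant = pv,
             gene = planted_genes[i_shared])
    } else {
      i_free <- i_free + 1L
      assert_that(i_free <= length(free_blocks),
                  "simulate_gwas_loci: not enough eQTL-free blocks for independent loci")
      blk <- free_blocks[i_free]
      cand <- which(v$block == blk)
      max_r2 <- vapply(cand, function(j) {
        gj <- gm$dosages[, j]
        if (stats::var(gj) == 0) return(Inf)
        if (!length(planted_variants)) return(0)
        max(vapply(planted_variants, function(pv)
          stats::cor(gj, gm$dosages[, pv])^2, numeric(1)))
      }, numeric(1))
      ok <- which(max_r2 < 0.05)
      if (!length(ok))
        stop("simulate_gwas_loci: no variant with r2 < 0.05 to all planted variants in block ",
             blk, call. = FALSE)
      pick <- cand[ok[1L]]
      ident <- FALSE
      truth$gwas_map[[sprintf("locus%02d", li)]] <- list(type = "independent")
    }
    loci[[li]] <- data.frame(
      locus = sprintf("locus%02d", li), trait = trait[li],
      variant = v$id[pick], chrom = v$chrom[pick], pos = v$pos[pick],
      risk_allele = v$alt[pick], other_allele = v$ref[pick],
      identical_to_eqtl = ident, stringsAsFactors = FALSE
    )
  }
  list(loci = do.call(rbind, loci), truth = truth)
}

#' Simulate chromatin-state intervals enriched around eQTL variants
#'
#' Every variant independently receives a 100 bp "enhancer" interval
#' centered on it with probability \code{background_rate}, raised to
#' \code{enrichment_fold * background_rate} for the planted eQTL variants
#' (or an explicit foreground set).  Variant spacing in the simulated
#' layout (1 kb) guarantees an interval covers only its own variant.
#' A coarse "repressed" interval per chromosome makes every variant
#' annotated in at least one state.
#'
#' @param gm a \code{\link{genotype_matrix}} or a variant data.frame with
#'   \code{id}, \code{chrom}, \code{pos}.
#' @param truth optional \code{sim_truth}; its planted variants form the
#'   enriched foreground unless \code{eqtl_ids} is given.
#' @param enrichment_fold fold enrichment >= 1 for foreground variants.
#' @param background_rate per-variant background coverage probability.
#' @param seed RNG seed.
#' @param eqtl_ids optional explicit foreground variant ids.
#' @return a \code{\link{chromatin_annotation}}.
#' @export
simulate_chromatin <- function(gm, truth = NULL, enrichment_fold = 2,
                               background_rate = 0.15, seed = 1L,
                               eqtl_ids = NULL) {
  v <- if (inherits(gm, "genotype_matrix")) gm$variants else gm
  assert_that(enrichment_fold >= 1, "simulate_chromatin: enrichment_fold must be >= 1")
  fg_rate <- enrichment_fold * background_rate
  assert_that(fg_rate <= 1,
              "simulate_chromatin: enrichment_fold * background_rate exceeds 1")
  if (is.null(eqtl_ids))
    eqtl_ids <- if (!is.null(truth)) unique(truth$planted$variant) else character()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rate <- ifelse(v$id %in% eqtl_ids, fg_rate, background_rate)
  covered <- stats::runif(nrow(v)) < rate
  iv <- if (any(covered)) data.frame(
    chrom = v$chrom[covered], start = v$pos[covered] - 50,
    end = v$pos[covered] + 50, state = "enhancer", dataset = "synthmap1",
    stringsAsFactors = FALSE
  ) else data.frame(chrom = character(), start = numeric(), end = numeric(),
                    state = character(), dataset = character(),
                    stringsAsFactors = FALSE)
  blanket <- do.call(rbind, lapply(split(v, v$chrom), function(vc)
    data.frame(chrom = vc$chrom[1], start = min(vc$pos) - 1e4,
               end = max(vc$pos) + 1e4, state = "repressed",
               dataset = "synthmap1", stringsAsFactors = FALSE)))
  rownames(blanket) <- NULL
  chromatin_annotation(rbind(iv, blanket))
}

#' Simulate allele-specific expression read counts
#'
#' Per heterozygous sample, the alt read count is
#' Binomial(\code{depth}, \code{allelic_fraction}).
#'
#' @param n_het number of heterozygous samples (> 0).
#' @param allelic_fraction expected alt fraction in (0, 1).
#' @param depth total reads per sample (>= 1).
#' @param seed RNG seed.
#' @param variant variant id label.
#' @return data.frame: \code{variant}, \code{sample}, \code{ref_count},
#'   \code{alt_count}.
#' @export
simulate_ase_counts <- function(n_het, allelic_fraction, depth, seed = 1L,
                                variant = "site1") {
  assert_that(n_het > 0, "simulate_ase_counts: n_het must be > 0")
  assert_that(allelic_fraction > 0 && allelic_fraction < 1,
              "simulate_ase_counts: allelic_fraction must be in (0, 1)")
  assert_that(depth >= 1, "simulate_ase_counts: depth must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  alt <- stats::rbinom(n_het, depth, allelic_fraction)
  data.frame(variant = variant, sample = sprintf("S%03d", seq_len(n_het)),
             ref_count = depth - alt, alt_count = alt,
             stringsAsFactors = FALSE)
}
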