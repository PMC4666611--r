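---
title: "Exon-level cis-eQTL mapping and effector-transcript nomination: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon-level cis-eQTL mapping and effector-transcript nomination: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`isleteqtl` implements an exon-level cis-eQTL mapping pipeline for modest
bulk RNA-seq cohorts (on the order of 100-200 donors) with dense imputed
genotypes, and the downstream integration steps that turn a cis-eQTL map
into candidate *effector transcripts* at GWAS loci: LD filtering,
conditional-analysis colocalization, chromatin-state overlap, and
directional bookkeeping.  Because real donor-level data of this kind is
access-controlled, the package ships a synthetic-data generator with
planted truth, and every statistical property of the pipeline is verified
against that truth.

This vignette is the package's account of the models it fits, the
conventions it fixes, the parameters that matter, and the places where a
design choice was genuinely open.

# The association model

Expression phenotypes are per-exon normal scores (see below).  For exon
$e$ and variant $v$ within the cis window, the package fits ordinary least
squares

$$y_e = \alpha + \beta\, g_v + C\gamma + \varepsilon,$$

where $g_v \in [0,2]$ is the expected alt-allele dosage and $C$ collects
the covariates (inferred expression factors plus an optional sex
indicator).  The test is the two-sided t-test on $\beta$ with
$n - n_{\text{cov}} - 2$ degrees of freedom.  The scan is implemented by
projecting $y$ and each dosage column off the covariate span once per
window (a QR basis of $[1, C]$), which is algebraically identical to the
full regression (Frisch-Waugh) and is cross-checked against a
normal-equations oracle in the tests to $10^{-8}$.

**Cis window.** Variants within 1 Mb of the gene's transcription start
site, both interval ends closed, 1-based coordinates; the TSS is the
annotated start for "+" genes and the annotated end for "-" genes.  The
window is anchored at the TSS rather than the transcript body; all exons
of a gene share the gene's window.

**Index variant.** Per exon, the variant with the smallest p-value; ties
are broken by larger $|t|$, then smaller genomic position, so reruns and
duplicate columns are deterministic.  Dosage columns that are constant or
collinear with the covariates are skipped and recorded.

# Normalization

The chain is fixed, in this order:

1. **Sample filter** - samples under 10M exon-mapping reads are dropped
   (column sums of the exon count matrix).
2. **Exon filter** - exons with zero counts in 10 or more samples are
   removed.  An alternative rule (non-zero counts in at least 10% of
   samples) is selectable; the two differ only at the margin and the
   zero-count form is the default.
3. **Depth scaling** - each sample's column is multiplied by
   median(total)/total, so scaled totals equal the cohort median.
4. **log2(x + 1)** - the pseudocount is 1 because zeros survive the exon
   filter.  Because the next step is rank-based, the log matters only for
   how ties arise.
5. **Inverse normal transform** - per exon, average ranks $r$ map to
   $\Phi^{-1}((r - 0.5)/n)$.  This makes every exon's marginal
   distribution standard normal, which caps the influence of outliers and
   puts effect sizes on a common per-exon scale.

A consequence worth stating: the INT fixes each exon's *total* variance at
1, so any variance contributed by confounders or by the genetic effect
itself is folded into the scale.  A planted per-allele effect of
$\beta = 1$ at MAF 0.3 with residual sd 0.8 has total latent variance
$\approx 1.06$ and is therefore re-estimated at $\approx 0.96$, not 1.0 -
the recovery tests budget for this (tolerance $\pm 0.25$ covers both the
scale fold-in and OLS sampling noise at $n = 200$).

**Hidden factors.** Technical and biological structure (batch, tissue
purity, storage) is captured by the top-$k$ left singular vectors of the
sample-by-exon matrix after per-exon centering - a deterministic factor
analysis playing the role Bayesian factor methods (PEER and relatives)
play in eQTL practice.  $k$ defaults to 15; the recovery tests use the
generator's true $k$.  Factors are orthonormal with a sign convention
(largest-magnitude loading positive) for bitwise reproducibility.  A sex
indicator, when available, is always appended; a factor-vs-sex correlation
screen is emitted as a diagnostic rather than used to gate the appending.

One interaction the tests document: when a single multiplicative
confounder is very strong, depth scaling (step 3) partially cancels it in
a count-dependent way and the normalized data carry a linear *and* a
curvature component of the factor - two comparable singular values.  The
true factor is then recovered at $|r| > 0.9$ among the top two inferred
factors rather than always as factor 1.  With $k$ at its default of 15
this distinction is immaterial downstream, since both components are
regressed out.

**RPKM.** For reporting, reads per kilobase per million mapped reads;
values at or above 0.1 are called expressed (the boundary itself counts as
expressed).

# Multiple testing

**Adaptive permutation.** The smallest p-value in a cis window is biased
by the number and correlation of variants tested, so per-exon significance
is empirical: the sample labels of the genotypes are permuted against the
fixed expression-covariate pairing (equivalently, expression and
covariates are permuted jointly), the whole window is rescanned, and the
permuted minimum p is compared with the observed one.  Permutations run in
batches of 1000; after each batch the run stops once at least 1000
permutations have been done *and* at least 15 permuted minima were as
extreme as the observed one, with a hard stop at 10000.  The empirical
p-value is $(r + 1)/(n + 1)$, which is never 0, never exceeds 1, and is
exactly uniform under the null (marginalizing a Binomial($n$, $u$) count
over $u \sim U(0,1)$ gives a uniform distribution on the lattice).
Whether the exceedance check is continuous or batched is not dictated by
anything statistical; the batched form is simple and deterministic.

Each exon owns an RNG stream seeded by `child_seed(master, exon_index)`,
so any subset of exons reproduces its empirical p-values exactly.  The
inner rescan is compiled (one small matrix product per permutation); the
permuted minimum p is recovered from the maximum of
$\mathrm{num}^2/\mathrm{gss}$ across variants, which is monotone in $t^2$
at fixed residual degrees of freedom.

**Storey q-values.** $\hat\pi_0$ comes from the
$\lambda$-grid $0.05, \dots, 0.95$ with a cubic smoothing spline evaluated
at $\lambda = 0.95$, clamped to $(0, 1]$; below 100 p-values the grid is
unstable and a fixed $\lambda = 0.5$ is used with a warning.  q-values
follow the step-up rule and are monotone in p.  Study-wide significance is
$q < 0.05$; a second, *nominal* tier (empirical $p < 0.05$) exists only
for the GWAS-locus cascade, where the prior expectation of a true signal
is higher.

**Replication $\pi_1$.** For a discovery-significant set tested in an
independent cohort, $\pi_1 = 1 - \hat\pi_0$ of the replication p-values.
A caveat the tests encode: the estimator evaluated at $\lambda = 0.95$
converges to $1 - \pi_0^{true}$ only when the alternative p-values are
concentrated well below 0.95.  For diffuse alternatives (e.g.
Beta(0.1, 1)) it under-reports $\pi_1$ by construction; the recovery test
therefore uses sharply significant alternatives and averages over nine
replication sets, the way a mean replication rate across tissues would be
formed.

# The effector-transcript cascade

Per GWAS locus and gene, in order:

1. gene TSS within 1 Mb of the lead variant;
2. the gene's best exon = smallest empirical p (ties by q, then genomic
   order);
3. tier: study-wide if $q < 0.05$, else nominal if empirical $p < 0.05$,
   else stop;
4. LD: $r^2$ between the exon's index variant and the lead must exceed
   0.8.  $r^2$ is the squared Pearson correlation of dosages *in the
   analysis cohort* - the same quantity the conditional model uses - not
   an external reference panel;
5. conditional analysis: refit with the lead's dosage as a covariate; the
   locus passes if the eQTL signal is absorbed (conditional $p > 0.05$).
   If index and lead dosages are collinear beyond $r^2 > 0.999$ the signal
   is absorbed by construction and the call is flagged.  The relative drop
   in $-\log_{10} p$ is reported alongside as an alternative absorption
   measure, since "eliminated or seriously depleted" has no unique
   quantification;
6. chromatin: the index variant or any $r^2 > 0.8$ proxy must overlap an
   active state (enhancer/promoter) in at least one annotation dataset.
   The index-only flag is also emitted; the proxy rule gates, because a
   regulatory element tags a haplotype, not a single site;
7. reporting: directional consistency across the gene's exons (count of
   exons whose effect at the index variant shares the index exon's sign,
   formatted "23/24"-style) and the expression direction of the risk
   allele (the sign of $\beta$ re-oriented through the lead-index dosage
   correlation and the risk/other allele labels - invariant to ref/alt
   relabeling in the input).

**Winner's curse and the conditional gate.** The scan picks the index
variant that maximizes the observed association, so conditioning that
*selected* variant on a merely-strong proxy retains a noise-aligned
residual signal; at $\beta = 1$, $n = 200$ and $r^2 = 0.9$ the conditional
noncentrality is $\beta\sqrt{2f(1-f)(1-r^2)n} \approx 2.9$ and the gate
would (correctly) reject most of the time.  Colocalization in the intended
sense - the same causal variant driving both signals - is only
recoverable when the lead tags the causal variant nearly perfectly, which
is exactly the situation in the motivating use case (GWAS leads from very
large meta-analyses; the flagship locus there has $r^2 = 0.98$).  The
discrimination tests therefore plant effector-scale effects
($\beta \approx 0.4$) with leads in near-complete LD, and the end-to-end
cascade check uses a perfect-LD shared block so its outcome is
deterministic; the statistical discrimination is measured separately.

# Chromatin overlap and enrichment

Intervals are 0-based half-open (BED); variants are 1-based.  A variant at
position $p$ overlaps $[s, e)$ iff $s < p \le e$ - fixed once and
exercised with boundary fixtures, and invariant to interval fragmentation.
Enrichment of foreground variants (significant eQTL index variants) over
background (index variants of non-significant exons, matching the
"tested but not significant" background concept) is measured two ways:
Fisher's exact test on the 2x2 overlap table (two-sided by default, both
one-sided values reported) and a resampling p-value from 10000 draws of
|foreground| variants from the background without replacement, with the
$(r+1)/(n+1)$ convention.  No MAF or TSS-distance matching is applied by
default; a matched sampler would be a straightforward extension but is
deliberately not the default because the reference procedure states plain
random sampling.

# Allele-specific expression

Per heterozygous sample with total depth $\ge 10$ (configurable), the
deviation of the alt fraction from one half is computed as
$(a - r)/(2(a + r))$ - algebraically the same but exactly antisymmetric
under ref/alt relabeling in floating point.  Zero deviations are dropped
(classical Wilcoxon convention).  For $n \le 25$ informative samples the
two-sided p-value is exact: the distribution of the signed-rank sum over
all $2^n$ sign assignments is built from the generating polynomial of the
doubled average ranks, so ties are handled exactly; above 25 a normal
approximation with tie-corrected variance and continuity correction takes
over.  The two-sided p is twice the smaller tail, capped at 1.

# The synthetic-data generator

The generator defines the study conditions; its defaults are fixed once.

**Genotypes.** Variants come in LD blocks.  Per block and sample, a
founder haplotype pair is drawn Bernoulli(MAF); each emitted variant
copies the founder allele with probability $1 - s$ and redraws otherwise,
with $s = 1 - \rho^{1/4}$ so that the expected pairwise $r^2$ between any
two block variants is the target $\rho$ (each variant correlates with the
founder at $r = (1-s)^2$).  Dosages are haplotype sums: values in
$\{0,1,2\}$, Hardy-Weinberg at the block MAF.  This star-shaped LD is all
the pipeline consumes (only pairwise $r^2$ matters to the LD filter and
the conditional model); realistic recombination maps, LD decay and
population structure are deliberately out of scope.  Realized MAF and
$r^2$ converge to their targets (tested at $n = 10000$ within $\pm 0.02$
and $\pm 0.05$).

**Expression.** Latent per-exon signal
$\beta g + \Lambda f + \mathcal{N}(0, \sigma^2)$ with $\sigma = 0.8$,
factor scores standard normal and loadings $\mathcal{N}(0,
\text{factor\_sd}^2)$ (default 0.7); all exons of a gene share the gene's
$\beta$, with per-exon sign flips available for directional-consistency
tests.  Counts are Poisson with log mean = log(lib/10^6) + $a_e$ +
0.7 x latent, where $a_e$ is a per-exon baseline log-CPM drawn uniformly
on [log 2, log 50] and library sizes are uniform on [30M, 100M] (the
scale of deep bulk RNA-seq).  Poisson rather than negative binomial is
the default because the pipeline immediately rank-normalizes per exon,
making the count law secondary; at these depths the Poisson jitter
attenuates rank information by under 2%.  What the generator does *not*
emulate: overdispersion beyond Poisson, splicing structure within genes
beyond shared-$\beta$ exons, GC/length biases, mapping artifacts, and
relatedness - so passing tests demonstrate the statistical machinery, not
robustness to those artifacts.

**GWAS loci.** A shared locus takes a planted eQTL and picks as lead the
block variant with the highest realized $r^2 > 0.8$ to the causal variant
(the causal variant itself is allowed and flagged); an independent locus
picks, from an eQTL-free block, a variant with realized $r^2 < 0.05$ to
every planted variant.  The truth object records the sharing map.

**Chromatin.** Each variant receives a 100 bp enhancer interval with
probability = background rate (default 0.15), raised by the enrichment
fold at foreground variants; variant spacing (1 kb) guarantees an interval
covers only its own variant, and a per-chromosome "repressed" blanket
makes every variant annotated in at least one state.  Fold x background
must not exceed 1.

**Seeds.** All randomness flows from one master seed through
`child_seed(seed, stream)` (a fixed congruential mix modulo $2^{31}-1$):
genotypes, expression, chromatin, ASE and each exon's permutation stream
are separately reproducible, and identical (config, seed) pairs give
bitwise-identical outputs, files included.

# Numerical choices and degenerate inputs

* Dosage columns are declared untestable when their residual sum of
  squares after covariate projection falls below $10^{-10}$ times the
  column's raw sum of squares.
* The collinearity tolerance in the conditional test is $r^2 > 0.999$.
* Hardy-Weinberg uses an exact conditional test (sum of genotype-table
  probabilities not exceeding the observed one, no mid-p), computed on
  rounded dosages because HWE is a statement about genotype classes;
  regression always uses unrounded dosages.  Monomorphic tables give
  p = 1.
* Missing dosages surviving QC are mean-imputed, which preserves each
  variant's allele frequency and the regression design mean exactly.
* Constant expression vectors are an error at the transform (such exons
  must be filtered); all-zero-deviation ASE sites give p = 1.
* Empirical p-values, resampling p-values and permutation counts all use
  the $(r+1)/(n+1)$ convention.

# Problem sizes in the test suite

The property checks run at the sizes the designs call for: 1000 random
regression designs against the normal-equations oracle; an all-null
calibration study of 200 samples x 200 exons x 50 variants per window plus
20 replicate studies with 10% planted effects for realized FDR; 100
replicates for effect-size recovery; 80/60 replicates for the two
colocalization arms; exhaustive enumeration sweeps for the exact tests
(all Hardy-Weinberg tables to n = 50, all 2x2 tables to n = 12 plus random
tables to n = 200, all sign assignments to n = 12); 2000 foreground
variants for enrichment recovery.  The `analysis/` scripts run a smaller
narrative cohort (150 donors, 60 genes) whose purpose is illustration, not
power.

# Known limitations

* PEER's Bayesian factor posterior is intentionally replaced by truncated
  SVD; where PEER's shrinkage materially changes factor counts, results
  can differ in the number of effective covariates, not in the pipeline
  contract ("regress out k latent covariates").
* The conditional gate inherits winner's-curse anti-conservatism when the
  lead only imperfectly tags the causal variant (quantified above); a
  Bayesian colocalization posterior is out of scope by design.
* LD is computed from the analysis cohort, not an external reference
  panel; with ~100-200 samples, realized $r^2$ around the 0.8 threshold
  carries sampling noise of a few hundredths.
* The exon filter's two published variants (zero-count and
  non-zero-fraction) are both implemented because the reference procedure
  states both; the default follows the methods-text form.
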