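---
title: "ptQTL: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ptQTL: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are.  It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The two phenotype models

### Editing: binomial GLM on allele counts

A-to-I editing is read out as A-to-G mismatches; the natural datum at a
site is the pair (edited reads, total reads) per donor, and the edit rate
is their ratio.  Modelling the counts directly — a binomial GLM on
(edited, total − edited) with a logit link — uses the read-depth
information that a linear model on rates would discard: a donor with 200
reads pins the rate down far better than one with 12.

Site discovery requires, per donor, at least 10 total reads with at least
2 edited reads, and retains a site when at least 85% of donors qualify.
All three thresholds are inclusive ("at least"), and the supporting-donor
set is kept *per site*: downstream fits use exactly those donors, because
the covered donors legitimately differ between sites.  The candidate cis
window is ±100 kb around the site, restricted to variants inside the
site's gene: the working mechanism is perturbation of the folded mRNA, so
variants outside the transcript are not tested by default
(`same_gene = FALSE` lifts this).

The dosage coefficient is the per-minor-allele log-odds of editing, tested
by a Wald statistic.  Two numerical choices:

* **t reference, df = n − p.**  The Wald z is compared to a t distribution
  rather than a normal.  At cohort scale (n ≈ 80) the normal reference is
  measurably anti-conservative; the t reference brings the null rejection
  rate at α = 0.05 to the nominal level (the acceptance suite measures
  this on 500 null pairs).
* **Binomial, not quasi-binomial, by default.**  The plain binomial
  likelihood is the stated model.  Real editing counts can be
  over-dispersed (the generator's beta-binomial mode emulates this), which
  inflates binomial Wald tests; `robust = TRUE` switches to a sandwich
  variance.  It is off by default and is the right switch when the
  dispersion diagnostic in the tests is relevant to your data.

Genotype-class filtering keeps a variant only with ≥ 2 heterozygotes and
either 0 or ≥ 2 homozygous-minor donors, computed on the site's supporting
donors with rounded dosages (dosages more than 0.45 from an integer are
treated as missing for counting only; association tests use the continuous
dosage).

### APA: EMMAX-style mixed model on normalized PAU

Poly(A) usage (PAU) of a 3'UTR isoform is its count share of its gene's
isoform total; shares sum to one per gene and donor before filtering and
are deliberately *not* renormalized afterwards, so a retained isoform's
PAU keeps its original meaning.  For genes with exactly two isoforms the
shares are complementary (PAU₁ = 1 − PAU₂), so one of the two is dropped
at random under a fixed seed to avoid counting the same signal twice.

"Quantile normalization" of phenotypes is implemented as a per-isoform
rank-based inverse-normal transform (ties averaged, missing excluded),
the standard choice for Gaussian-LMM QTL phenotypes; a donor-level
across-sample quantile normalization is available as
`normalizePAU(method = "quantile")`.  Isoforms with fewer than 10
non-missing donors or constant values are flagged ineligible.

The association model is a linear mixed model with the IBS kinship
`K[j,j'] = mean over variants of (2 − |d_j − d_j'|)/2` as the random-effect
covariance, fitted EMMAX-style: REML variance components once per
phenotype under the covariates-only null (via the spectral decomposition
of K), then fixed-weight generalized least squares per variant.  Two
points deserve emphasis:

* **Exact OLS collapse.**  The Wald variance is rescaled by the
  full-model weighted residual sum of squares, so with K = I the test is
  *identical* to `lm()` — coefficient, standard error and p-value — which
  the test suite asserts to 1e-8.
* **Boundary screen on σ²ᵤ.**  An IBS kinship contains an identity-scale
  component (every donor shares both alleles with itself), so for an iid
  phenotype the pair (σ²ᵤ, σ²ₑ) lies on a nearly flat likelihood ridge and
  raw REML wanders along it.  The fit therefore keeps the random effect
  only when its REML gain over the σ²ᵤ = 0 boundary clears a 50:50
  χ²₀/χ²₁ mixture threshold at α = 0.1; otherwise it collapses to OLS and
  flags `at_boundary`.  Genuine relatedness (the twin design in the
  acceptance suite) clears the threshold by a wide margin, while iid
  phenotypes collapse in the large majority of runs.

Cis windows are ±25 kb around *either* UTR end (the union of the two
anchor windows; boundaries inclusive).  Leave-one-chromosome-out kinship
is the default in the pipeline driver, so the tested variant never
contributes to the error covariance it is tested against.

## Hierarchical eigenMT-FDR

Per phenotype, the minimum nominal p is Bonferroni-adjusted by the
effective number of independent cis tests: consecutive windows of ≤ 200
variants, eigendecomposition of each window's variant correlation matrix,
eigenvalues counted until 99% of the variance is explained, summed and
clamped to [1, M].  Windows are non-overlapping and no merging refinement
is applied, so the count is conservative (never smaller than a merged
estimate).  Across phenotypes, Benjamini–Hochberg on the locally adjusted
p-values at 5% defines the significant set; the primary variant is the
smallest nominal p, ties broken by distance to the anchor and then by
genomic position (deterministic output).

## Downstream statistics

**π1.**  π0 is estimated on the λ grid 0.05…0.95 (step 0.05) as
`#{p > λ} / (m (1 − λ))`, smoothed with a cubic smoothing spline (df = 3)
and read off at λ = 0.95, clamped to [0, 1]; π1 = 1 − π0.  Like every
estimator of this family it is biased downward when the non-null p-value
distribution has appreciable mass near 1; the recovery evaluation
therefore uses z-score-derived non-null p-values (two-sided p of N(4, 1)
draws), which is how replication p-values of real effects behave.

**Structure enrichment.**  Each significant variant is matched to
non-significant variants within ±50% *relative* tolerance on MAF and on
absolute distance to the edit site — the only reading under which each
feature's matching window is well defined per variant; the tolerance is a
parameter.  Permutations draw one matched control per significant variant
without replacement within a permutation, independently across
permutations.  The default p compares permutation counts to the observed
count with ≥: the strict > variant (available as `strict = "greater"`) is
anti-conservative when counts tie, and the ≥ form is what the calibration
evaluation shows to be nominal.  The add-one corrected
(1 + #exceeding)/(1 + n_perm) is reported alongside.

**Colocalization.**  GWAS index variants are greedily LD-pruned
(p < 5e-8, keep while r² < 0.2 with everything kept).  A (GWAS index, QTL
index) pair with r² > 0.8 is tested by refitting the QTL model with the
GWAS index dosage as an extra covariate; "no longer significant" is
operationalized as conditional p ≥ 0.05 (configurable — no threshold is
canonical).  Identical variants are collinear by construction and called
colocalized with a flag; non-identical but perfectly collinear designs
are flagged with no p.

**Mediation.**  The three candidate structures (forward X→M→Y,
independent X→M plus X→Y, reactive X→Y→M) are each scored by the BIC of
their joint Gaussian likelihood after residualizing all variables on the
covariates; `exp(−ΔBIC/2)` weights are normalized and labelled
approximate posterior probabilities.

## What the generator emulates — and what it does not

The defaults encode the study conditions the package is calibrated under:
80 donors, ~400 biallelic variants in LD blocks of 10, MAF in
[0.05, 0.5], 200 edit sites with mean coverage 50 (negative binomial,
size 5), 10% causal sites with a logit effect of 1, a donor-level
global-editing latent factor (SD 0.5) and a two-level batch (FACS-sorter)
effect (SD 0.25), multinomial isoform counts at gene depth ~200 with a
logistic-scale effect of 1 on the longest isoform, and GWAS cohorts of
2,000 donors drawn from the same haplotype pool.

Haplotypes follow a first-order Markov chain along each LD block: exact
Bernoulli(MAF) marginals, adjacent-variant correlation 0.85 within a
block, independence across blocks.  (A two-ancestral-haplotype copying
scheme was considered and rejected: with only two founders the per-site
frequency spectrum collapses and an arbitrary MAF range cannot be
respected.)  Relatedness is induced by duplicating one haplotype between
donor pairs.  Coverage is negative binomial (size 5) as a realistic
RNA-seq depth dispersion; the beta-binomial edit-count mode is
parameterized by the intraclass correlation ρ and reduces exactly to
binomial at ρ = 0.

Not emulated: read-level artifacts (mapping bias, strand errors),
population-genetic realism beyond block LD (no allele-frequency spectrum,
no recombination maps), genuinely multi-causal cis architecture, and the
correlation structure of real annotation categories.  Passing tests
therefore demonstrate the *statistical* operating characteristics of the
methods under their assumed generative models, not robustness to every
artifact of real sequencing data.

## Problem sizes

The simulation studies use: 500 site–variant pairs for null calibration;
20 replicates of 120 sites (10% causal, β = 1.5) for FDR; 200 causal
sites for effect recovery; 100 twin-design replicates × 5 variants for
the LMM/OLS comparison; mixtures of 5,000 p-values for π1; 200 null and
100 planted datasets × 200 permutations (40 significant / 400
non-significant variants each) for enrichment; 50 replicates per
colocalization scenario; 100 triplets for mediation.  These sizes give
standard errors comfortably inside the assertion bands while keeping a
full run in minutes on one CPU.

## Known limitations

* The binomial edQTL model understates uncertainty under strong
  overdispersion unless `robust = TRUE`.
* σ²ᵤ from an IBS kinship is only weakly identified in unstructured
  cohorts (see the boundary screen above); its value should not be
  interpreted as heritability.
* The eigenMT count is conservative by construction; extremely long LD
  stretches spanning window boundaries are counted more than once.
* Conditional colocalization is a decision procedure, not a posterior
  probability; it inherits the resolution limits of single-variant
  conditioning in tight LD.
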