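# Simulation-study drivers: each function generates data under known truth
# with the synthetic-data module, runs the matching inference path, and
# returns the operating characteristic (type-I error, FDR, bias, power,
# discrimination rate).  Problem sizes default to desk scale; the methods
# vignette states the rationale.

#' Type-I error of the binomial edQTL test under the null
#'
#' Simulates editing data with no genetic effect and no confounders
#' (beta = 0, no latent factor, no batch effect, pure binomial counts) and
#' fits the binomial GLM for each site against its anchor cis variant with
#' genotype MDS covariates.  Returns the empirical rejection rate at
#' nominal alpha.
#'
#' @param n_pairs number of site-variant pairs (default 500).
#' @param n_donors,mean_coverage study conditions (defaults 80, 50).
#' @param alpha nominal level (default 0.05).
#' @param seed integer seed.
#' @return list: rejection_rate, n_tests.
#' @export
evalTypeIError <- function(n_pairs = 500, n_donors = 80, mean_coverage = 50,
                           alpha = 0.05, seed = 1) {
  cfg <- simConfig(n_donors = n_donors, n_edit_sites = n_pairs,
                   frac_edit_qtl = 0, mean_coverage = mean_coverage,
                   global_factor_sd = 0, batch_effect_sd = 0,
                   overdispersion_rho = 0, seed = seed)
  geno <- simulateGenotypes(cfg)
  sim <- simulateEditing(geno, cfg)
  ed <- editedCounts(sim$edex); tt <- totalCounts(sim$edex)
  dose <- dosageMatrix(geno)
  cov <- genotypeMDS(geno, 3)
  pvals <- vapply(rownames(sim$edex), function(s) {
    v <- sim$truth$anchor_variant[s]
    fitBinomialEdQTL(ed[s, ], tt[s, ], dose[v, ], cov)$p
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  list(rejection_rate = mean(pvals < alpha), n_tests = length(pvals))
}

#' Empirical FDR of the hierarchical eigenMT-FDR edQTL pipeline
#'
#' Replicated simulations with a stated fraction of non-null edit sites;
#' each replicate runs discovery and the full cis scan with eigenMT-FDR
#' correction.  The empirical FDR is the pooled fraction of significant
#' sites that were not simulated as causal; power is the pooled fraction of
#' causal sites declared significant.
#'
#' @param n_reps replicates (default 20).
#' @param n_sites edit sites per replicate (default 120).
#' @param frac_causal non-null fraction (default 0.1).
#' @param beta planted logit effect (default 1.5).
#' @param alpha global FDR level (default 0.05).
#' @param seed integer seed.
#' @return list: fdr, power, n_significant, n_reps.
#' @export
evalFDR <- function(n_reps = 20, n_sites = 120, frac_causal = 0.1,
                    beta = 1.5, alpha = 0.05, seed = 1) {
  fp <- tp <- nc <- 0
  for (r in seq_len(n_reps)) {
    cfg <- simConfig(n_edit_sites = n_sites, frac_edit_qtl = frac_causal,
                     beta_edit = beta, seed = seed + 97L * r)
    geno <- simulateGenotypes(cfg)
    sim <- simulateEditing(geno, cfg)
    edex <- discoverEditSites(sim$edex)
    scan <- mapEdQTL(edex, geno, batch = sim$truth$batch, alpha = alpha)
    if (is.null(scan$phenotypes)) next
    sig <- scan$phenotypes$phenotype_id[scan$phenotypes$significant]
    causal <- sim$truth$causal$phenotype_id
    fp <- fp + sum(!sig %in% causal)
    tp <- tp + sum(sig %in% causal)
    nc <- nc + sum(causal %in% scan$phenotypes$phenotype_id)
  }
  list(fdr = if (fp + tp > 0) fp / (fp + tp) else 0,
       power = if (nc > 0) tp / nc else NA_real_,
       n_significant = fp + tp, n_reps = n_reps)
}

#' Recovery bias of a planted logit editing effect
#'
#' All sites carry a cis effect of \code{beta}; each causal pair is refit
#' with the binomial GLM under the standard covariates (3 genotype MDS, the
#' batch factor, 1 global-editing PC).  Returns the bias of the mean
#' estimate.
#'
#' @param n_sites causal sites (default 200).
#' @param beta planted logit effect (default 1).
#' @param n_donors,mean_coverage study conditions (defaults 80, 50).
#' @param seed integer seed.
#' @return list: mean_beta, bias (mean_beta - beta), mean_abs_error, n.
#' @export
evalEffectRecovery <- function(n_sites = 200, beta = 1, n_donors = 80,
                               mean_coverage = 50, seed = 1) {
  cfg <- simConfig(n_donors = n_donors, n_edit_sites = n_sites,
                   frac_edit_qtl = 1, beta_edit = beta,
                   mean_coverage = mean_coverage, seed = seed)
  geno <- simulateGenotypes(cfg)
  sim <- simulateEditing(geno, cfg)
  rates <- editRates(sim$edex)
  cov <- buildCovariates(geno, pheno = rates, n_mds = 3, n_pcs = 1,
                         batch = sim$truth$batch)
  ed <- editedCounts(sim$edex); tt <- totalCounts(sim$edex)
  dose <- dosageMatrix(geno)
  bhat <- vapply(seq_len(nrow(sim$truth$causal)), function(i) {
    s <- sim$truth$causal$phenotype_id[i]
    v <- sim$truth$causal$variant_id[i]
    fitBinomialEdQTL(ed[s, ], tt[s, ], dose[v, ], cov)$beta
  }, numeric(1))
  bhat <- bhat[!is.na(bhat)]
  list(mean_beta = mean(bhat), bias = mean(bhat) - beta,
       mean_abs_error = mean(abs(bhat - beta)), n = length(bhat))
}

#' Type-I error of LMM vs OLS under planted relatedness
#'
#' A monozygotic-twin design: every donor is duplicated, the phenotype is a
#' strong family effect (variance 0.8) plus individual noise (0.2), and no
#' variant has a true effect.  Random variants are tested per replicate
#' with ordinary least squares and with the IBS-kinship LMM; returns both
#' empirical rejection rates at alpha = 0.05.  OLS ignores the duplicated
#' information and inflates; the LMM absorbs it through the kinship random
#' effect.
#'
#' @param n_sims replicates (default 100).
#' @param n_families donor families (each contributing a twin pair;
#'   default 40).
#' @param tests_per_sim variants tested per replicate (default 5).
#' @param seed integer seed.
#' @return list: alpha_ols, alpha_lmm, n_tests.
#' @export
evalLmmVsOls <- function(n_sims = 100, n_families = 40, tests_per_sim = 5,
                         seed = 1) {
  set.seed(seed)
  pol <- plm <- NULL
  for (s in seq_len(n_sims)) {
    cfg <- simConfig(seed = seed + 1000L + s, n_donors = n_families,
                     n_variants = 200)
    g0 <- simulateGenotypes(cfg)
    d <- dosageMatrix(g0)[, rep(seq_len(n_families), each = 2)]
    colnames(d) <- sprintf("D%03d", seq_len(2 * n_families))
    g <- GenotypeMatrix(d, SummarizedExperiment::rowRanges(g0))
    K <- computeIBSKinship(g)
    fam <- rnorm(n_families, 0, sqrt(0.8))[rep(seq_len(n_families), each = 2)]
    y <- fam + rnorm(2 * n_families, 0, sqrt(0.2))
    vs <- sample(rownames(d)[apply(d, 1, sd) > 0], tests_per_sim)
    for (v in vs) {
      x <- d[v, ]
      pol <- c(pol, summary(lm(y ~ x))$coefficients["x", 4])
      plm <- c(plm, fitLmmApaQTL(y, x, kinship = K)$p)
    }
  }
  list(alpha_ols = mean(pol < 0.05), alpha_lmm = mean(plm < 0.05),
       n_tests = length(pol))
}

#' pi1 recovery on known p-value mixtures
#'
#' Draws n p-values as a mixture of pi1 Beta(0.1, 1) non-nulls and
#' (1 - pi1) uniforms for each true pi1, and estimates pi1 back.
#'
#' @param truths true non-null fractions (default 0, 0.3, 0.6).
#' @param n p-values per mixture (default 5000).
#' @param seed integer seed.
#' @return data.frame: truth, estimate, abs_error.
#' @export
evalPi1Recovery <- function(truths = c(0, 0.3, 0.6), n = 5000, seed = 11) {
  set.seed(seed)
  est <- vapply(truths, function(tr) {
    k <- round(tr * n)
    # non-null p-values behave like replication tests of real effects:
    # two-sided p of a z-score centered at 4
    p <- c(2 * pnorm(-abs(rnorm(k, 4, 1))), runif(n - k))
    pi1Estimate(p)$pi1
  }, numeric(1))
  data.frame(truth = truths, estimate = est, abs_error = abs(est - truths))
}

.enrichDataset <- function(n_sig, n_nonsig, stem_factor, seed) {
  set.seed(seed)
  cats <- c("stem", "hairpin loop", "interior loop", "bulge", "multiloop",
            "exterior")
  base <- c(0.20, 0.18, 0.18, 0.12, 0.12, 0.20)
  pstem <- base
  pstem[1] <- min(stem_factor * base[1], 0.9)
  pstem[-1] <- base[-1] * (1 - pstem[1]) / (1 - base[1])
  n <- n_sig + n_nonsig
  annot <- data.frame(
    variant_id = sprintf("v%04d", seq_len(n)),
    structure = c(sample(cats, n_sig, TRUE, pstem),
                  sample(cats, n_nonsig, TRUE, base)),
    dist_to_site = runif(n, 1, 800),
    maf = runif(n, 0.05, 0.5), stringsAsFactors = FALSE)
  list(sig = annot$variant_id[seq_len(n_sig)],
       nonsig = annot$variant_id[n_sig + seq_len(n_nonsig)],
       annot = annot)
}

#' Calibration and power of the matched-permutation structure enrichment
#'
#' Null calibration: datasets with structure categories assigned
#' independently of significance; the stem-category rejection rate at 0.05
#' should match the nominal level.  Power: datasets with a stem-probability
#' factor planted among significant variants; reports the detection rate
#' (stem p below 0.05).
#'
#' @param n_null,n_power dataset counts (defaults 200, 100).
#' @param n_perm permutations per dataset (default 200).
#' @param n_sig,n_nonsig set sizes per dataset (defaults 40, 400).
#' @param stem_factor planted enrichment factor (default 3).
#' @param seed integer seed.
#' @return list: null_rejection_rate, power_detect_rate.
#' @export
evalEnrichmentCalibration <- function(n_null = 200, n_power = 100,
                                      n_perm = 200, n_sig = 40,
                                      n_nonsig = 400, stem_factor = 3,
                                      seed = 1) {
  run <- function(factor_, n_data, off) {
    vapply(seq_len(n_data), function(i) {
      d <- .enrichDataset(n_sig, n_nonsig, factor_, seed + off + i)
      en <- suppressWarnings(
        structureEnrichment(d$sig, d$nonsig, d$annot, n_perm = n_perm,
                            seed = seed + off + i))
      en$p[en$category == "stem"]
    }, numeric(1))
  }
  p_null <- run(1, n_null, 10000L)
  p_pow <- run(stem_factor, n_power, 20000L)
  list(null_rejection_rate = mean(p_null < 0.05, na.rm = TRUE),
       power_detect_rate = mean(p_pow < 0.05, na.rm = TRUE))
}

#' Discrimination of the conditional colocalization procedure
#'
#' Per replicate: simulate genotypes and editing with strong causal
#' effects, map edQTLs, simulate a GWAS under the stated scenario on an
#' independent cohort from the same haplotype pool, derive LD-pruned GWAS
#' index variants, and run the LD-thresholded conditional colocalization.
#' A replicate counts as colocalized when any call is colocalized.
#'
#' @param scenario "shared" or "distinct".
#' @param n_sims replicates (default 50).
#' @param seed integer seed.
#' @return list: coloc_rate, n_informative (replicates with at least one
#'   significant QTL and one GWAS index variant).
#' @export
evalColocDiscrimination <- function(scenario = c("shared", "distinct"),
                                    n_sims = 50, seed = 1) {
  scenario <- match.arg(scenario)
  hits <- logical(0); informative <- 0L
  for (s in seq_len(n_sims)) {
    cfg <- simConfig(n_variants = 120, ld_block_size = 6, n_edit_sites = 15,
                     frac_edit_qtl = 0.2, beta_edit = 1.5,
                     gwas_scenario = scenario, n_gwas_donors = 1500,
                     gwas_beta = 0.5, seed = seed + 313L * s)
    geno <- simulateGenotypes(cfg)
    sim <- simulateEditing(geno, cfg)
    edex <- discoverEditSites(sim$edex)
    scan <- mapEdQTL(edex, geno, batch = sim$truth$batch)
    if (is.null(scan$primary) || !nrow(scan$primary)) {
      hits <- c(hits, FALSE); next
    }
    # the shared trait must share a causal variant with a *discovered* QTL
    # (colocalization only ever pairs GWAS hits with significant phenotypes);
    # the distinct trait must be unlinked from every causal variant
    qc <- if (scenario == "shared")
      sim$truth$causal$variant_id[sim$truth$causal$phenotype_id %in%
                                    scan$primary$phenotype_id]
    else sim$truth$causal$variant_id
    if (!length(qc)) { hits <- c(hits, FALSE); next }
    gw <- tryCatch(simulateGWAS(geno, cfg, qtl_causal = qc),
                   error = function(e) NULL)
    if (is.null(gw)) { hits <- c(hits, FALSE); next }
    idx <- gwasIndexVariants(gw$summary, geno)
    if (!length(idx)) { hits <- c(hits, FALSE); next }
    informative <- informative + 1L
    refit <- edQTLRefitter(edex, geno, scan$covariates)
    calls <- conditionalColocalization(
      scan$primary[, c("phenotype_id", "variant_id")], idx, geno, refit)
    hits <- c(hits, nrow(calls) > 0 && any(calls$verdict == "colocalized"))
  }
  list(coloc_rate = mean(hits), n_informative = informative)
}

#' Recovery rate of the forward mediation model
#'
#' Generates variant-mediator-expression triplets under the forward model
#' (X -> M -> Y with strong effects) and reports how often the forward
#' model receives the top BIC weight.
#'
#' @param n_sims replicates (default 100).
#' @param n donors per replicate (default 80).
#' @param effect path coefficient (default 0.7).
#' @param seed integer seed.
#' @return list: forward_top_rate, n_sims.
#' @export
evalMediationRecovery <- function(n_sims = 100, n = 80, effect = 0.7,
                                  seed = 1) {
  set.seed(seed)
  top <- vapply(seq_len(n_sims), function(i) {
    x <- rbinom(n, 2, 0.3)
    m <- effect * x + rnorm(n)
    y <- effect * m + rnorm(n)
    w <- mediationTriplet(x, m, y)$weights
    names(w)[which.max(w)] == "forward"
  }, logical(1))
  list(forward_top_rate = mean(top), n_sims = n_sims)
}
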