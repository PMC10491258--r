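test_that("genotype simulation is deterministic and respects dosage/MAF bounds", {
  cfg <- simConfig(n_donors = 50, n_variants = 100, seed = 3)
  g1 <- simulateGenotypes(cfg)
  g2 <- simulateGenotypes(cfg)
  expect_identical(dosageMatrix(g1), dosageMatrix(g2))
  expect_true(all(dosageMatrix(g1) %in% 0:2))
  expect_true(all(variantMAF(g1) <= 0.5))
  expect_error(simConfig(n_donors = 2), "n_donors")
  expect_error(simConfig(maf_range = c(0.2, 0.6)), "maf_range")
})

test_that("forced MAF 0.5 is realized up to binomial sampling error", {
  cfg <- simConfig(n_donors = 200, n_variants = 100, ld_block_size = 1,
                   maf_range = c(0.5, 0.5), seed = 5)
  g <- simulateGenotypes(cfg)
  f <- rowMeans(dosageMatrix(g)) / 2
  # per-site allele count is Binomial(400, 0.5): 4.5 sd ~ 0.11
  expect_true(all(abs(f - 0.5) < 0.12))
})

test_that("ld_block_size 1 gives uncorrelated variants; blocks give LD", {
  cfg <- simConfig(n_donors = 200, n_variants = 500, ld_block_size = 1,
                   seed = 2)
  g <- simulateGenotypes(cfg)
  C <- cor(t(dosageMatrix(g)))
  off <- abs(C[upper.tri(C)])
  expect_lt(mean(off, na.rm = TRUE), 0.1)

  cfg2 <- simConfig(n_donors = 200, n_variants = 100, ld_block_size = 10,
                    seed = 2)
  g2 <- simulateGenotypes(cfg2)
  d2 <- dosageMatrix(g2)
  sim <- S4Vectors::metadata(g2)$sim
  adj <- vapply(seq_len(nrow(d2) - 1), function(v) {
    if (sim$block[v] != sim$block[v + 1]) return(NA_real_)
    suppressWarnings(abs(cor(d2[v, ], d2[v + 1, ])))
  }, numeric(1))
  expect_gt(mean(adj, na.rm = TRUE), 0.5)
})

test_that("haplotype duplication elevates IBS for related pairs", {
  cfg <- simConfig(n_donors = 40, n_variants = 300,
                   frac_related_pairs = 0.5, seed = 9)
  g <- simulateGenotypes(cfg)
  K <- computeIBSKinship(g)
  rel <- S4Vectors::metadata(g)$sim$related_pairs
  krel <- K[rel]
  kun <- K[upper.tri(K)]
  kun <- kun[!kun %in% krel]
  expect_gt(mean(krel), mean(kun) + 0.05)
})

test_that("null editing data show no genotype-rate association", {
  cfg <- simConfig(n_edit_sites = 200, frac_edit_qtl = 0, beta_edit = 0,
                   global_factor_sd = 0, batch_effect_sd = 0, seed = 4)
  g <- simulateGenotypes(cfg)
  sim <- simulateEditing(g, cfg)
  r <- editRates(sim$edex)
  dose <- dosageMatrix(g)
  slopes <- vapply(rownames(r), function(s) {
    x <- dose[sim$truth$anchor_variant[s], ]
    if (sd(x) == 0) return(NA_real_)
    coef(lm(r[s, ] ~ x))[2]
  }, numeric(1))
  expect_lt(abs(mean(slopes, na.rm = TRUE)), 0.01)
  expect_true(all(editedCounts(sim$edex) <= totalCounts(sim$edex)))
})

test_that("planted editing effect is recovered by a binomial refit", {
  cfg <- simConfig(n_edit_sites = 60, frac_edit_qtl = 1, beta_edit = 1,
                   seed = 6)
  g <- simulateGenotypes(cfg)
  sim <- simulateEditing(g, cfg)
  cov <- buildCovariates(g, pheno = editRates(sim$edex), n_mds = 3,
                         n_pcs = 1, batch = sim$truth$batch)
  ed <- editedCounts(sim$edex); tt <- totalCounts(sim$edex)
  dose <- dosageMatrix(g)
  bhat <- vapply(seq_len(nrow(sim$truth$causal)), function(i)
    fitBinomialEdQTL(ed[sim$truth$causal$phenotype_id[i], ],
                     tt[sim$truth$causal$phenotype_id[i], ],
                     dose[sim$truth$causal$variant_id[i], ], cov)$beta,
    numeric(1))
  expect_lt(abs(mean(bhat, na.rm = TRUE) - 1), 0.15)
})

test_that("beta-binomial counts are overdispersed relative to binomial", {
  dispersion <- function(rho) {
    cfg <- simConfig(n_edit_sites = 100, frac_edit_qtl = 0,
                     global_factor_sd = 0, batch_effect_sd = 0,
                     overdispersion_rho = rho, seed = 8)
    g <- simulateGenotypes(cfg)
    sim <- simulateEditing(g, cfg)
    ed <- editedCounts(sim$edex); tt <- totalCounts(sim$edex)
    mean(vapply(seq_len(nrow(ed)), function(i) {
      use <- tt[i, ] > 0
      ph <- sum(ed[i, use]) / sum(tt[i, use])
      sum((ed[i, use] - tt[i, use] * ph)^2 /
            (tt[i, use] * ph * (1 - ph))) / (sum(use) - 1)
    }, numeric(1)))
  }
  expect_gt(dispersion(0.3), 1.5)
  expect_lt(abs(dispersion(0) - 1), 0.2)
})

test_that("APA counts conserve gene depth and carry the planted effect", {
  cfg <- simConfig(n_apa_genes = 40, frac_apa_qtl = 0, beta_apa = 0,
                   seed = 10)
  g <- simulateGenotypes(cfg)
  sim <- simulateAPA(g, cfg)
  cts <- isoformCounts(sim$apex)
  expect_true(all(cts >= 0))
  expect_true(all(cts == round(cts)))
  # null: PAU of the longest isoform uncorrelated with its anchor dosage
  apex <- computePAU(sim$apex)
  pau <- SummarizedExperiment::assay(apex, "pau")
  rd <- SummarizedExperiment::rowData(apex)
  dose <- dosageMatrix(g)
  rs <- vapply(unique(rd$gene_id), function(gid) {
    ii <- which(rd$gene_id == gid)
    target <- ii[which.max(rd$utr_length[ii])]
    x <- dose[sim$truth$anchor_variant[gid], ]
    if (sd(x) == 0) return(NA_real_)
    suppressWarnings(cor(pau[target, ], x, use = "complete.obs"))
  }, numeric(1))
  expect_lt(mean(abs(rs), na.rm = TRUE), 0.12)
})

test_that("planted APA effect sign is recovered by the LMM in most genes", {
  cfg <- simConfig(n_apa_genes = 100, isoforms_per_gene = c(2, 2),
                   frac_apa_qtl = 1, beta_apa = 1, seed = 12)
  g <- simulateGenotypes(cfg)
  sim <- simulateAPA(g, cfg)
  apex <- normalizePAU(computePAU(sim$apex))
  npau <- SummarizedExperiment::assay(apex, "npau")
  K <- computeIBSKinship(g)
  dose <- dosageMatrix(g)
  tr <- sim$truth$causal
  tr <- tr[tr$phenotype_id %in% rownames(npau), ]
  signs <- vapply(seq_len(nrow(tr)), function(i) {
    f <- fitLmmApaQTL(npau[tr$phenotype_id[i], ],
                      dose[tr$variant_id[i], ], kinship = K)
    !is.na(f$beta) && f$beta > 0
  }, logical(1))
  expect_gt(mean(signs), 0.95)
})

test_that("GWAS scenarios satisfy their significance contracts", {
  cfg <- simConfig(gwas_scenario = "null", n_gwas_donors = 800, seed = 14)
  g <- simulateGenotypes(cfg)
  gw0 <- simulateGWAS(g, cfg)
  expect_true(all(gw0$summary$p >= 5e-8, na.rm = TRUE))
  expect_lt(abs(mean(gw0$summary$beta, na.rm = TRUE)), 0.02)

  cfg2 <- simConfig(gwas_scenario = "shared", seed = 14)
  sim <- simulateEditing(g, cfg2)
  gw <- simulateGWAS(g, cfg2, qtl_causal = sim$truth$causal$variant_id)
  expect_lt(gw$summary$p[gw$summary$variant_id == gw$causal_variant], 5e-8)

  cfg3 <- simConfig(gwas_scenario = "distinct", seed = 14)
  gw3 <- simulateGWAS(g, cfg3, qtl_causal = sim$truth$causal$variant_id)
  r2 <- vapply(sim$truth$causal$variant_id,
               function(v) ldR2(g, gw3$causal_variant, v), numeric(1))
  expect_true(all(r2 < 0.2, na.rm = TRUE))

  # distinct impossible when every variant is linked to the causal one
  cfg4 <- simConfig(n_variants = 8, ld_block_size = 8, ld_rho = 0.98,
                    maf_range = c(0.4, 0.5), gwas_scenario = "distinct",
                    seed = 15)
  g4 <- simulateGenotypes(cfg4)
  expect_error(simulateGWAS(g4, cfg4, qtl_causal = rownames(g4)),
               "distinct scenario impossible")
})

test_that("annotations partition sites and plant stem enrichment", {
  cfg <- simConfig(n_edit_sites = 100, n_variants = 600, seed = 16)
  g <- simulateGenotypes(cfg)
  sim <- simulateEditing(g, cfg)
  causal <- sample(rownames(g), 300)
  ann1 <- simulateAnnotations(sim$edex, g, cfg, stem_enrichment = 1,
                              causal_variants = causal)
  si <- siteInfo(ann1$edex)
  expect_true(all(!is.na(si$region)))
  expect_true(all(table(si$site_id) == 1))
  a1 <- ann1$variant_annot
  r_caus <- mean(a1$structure[a1$variant_id %in% causal] == "stem")
  r_non <- mean(a1$structure[!a1$variant_id %in% causal] == "stem")
  expect_lt(abs(r_caus - r_non), 0.12)

  ann3 <- simulateAnnotations(sim$edex, g, cfg, stem_enrichment = 3,
                              causal_variants = causal)
  a3 <- ann3$variant_annot
  r_caus3 <- mean(a3$structure[a3$variant_id %in% causal] == "stem")
  r_non3 <- mean(a3$structure[!a3$variant_id %in% causal] == "stem")
  # planted stem probability is exactly 3x the baseline
  expect_gt(r_caus3 / r_non3, 2.2)
  expect_lt(r_caus3 / r_non3, 3.8)
})
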