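test_that("cis windows are inclusive and respect the same-gene rule", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(1100000, 1100001, 900000),
                                                width = 1),
                               ref = "A", alt = "G")
  names(gr) <- paste0("v", 1:3)
  dos <- matrix(rep(c(0, 1, 2, 1), 3), 3, 4, byrow = TRUE,
                dimnames = list(names(gr), paste0("D", 1:4)))
  g <- GenotypeMatrix(dos, gr)
  anchors <- data.frame(phenotype_id = "s1", chrom = "chr1", pos = 1000000,
                        gene_start = 950000, gene_end = 1200000)
  pr <- cisPairs(anchors, g, window = 100000, same_gene = TRUE)
  expect_true("v1" %in% pr$variant_id)        # exactly at the boundary
  expect_false("v2" %in% pr$variant_id)       # one bp beyond
  expect_false("v3" %in% pr$variant_id)       # in window, outside the gene
  pr2 <- cisPairs(anchors, g, window = 100000, same_gene = FALSE)
  expect_true("v3" %in% pr2$variant_id)
  # APA dual anchor: 20 kb downstream of utr_end qualifies via the end
  a2 <- data.frame(phenotype_id = "iso", chrom = "chr1",
                   start = 1000000, end = 1080000)
  pr3 <- cisPairs(a2, g, window = 25000)
  expect_true("v1" %in% pr3$variant_id)       # 20 kb past the end anchor
  expect_warning(cisPairs(data.frame(phenotype_id = "x", chrom = NA,
                                     pos = NA), g, window = 1000),
                 "lacks coordinates")
})

test_that("genotype-class filter keeps het >= 2 and hom-minor 0 or >= 2", {
  mk <- function(dos) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, width = 1),
                                 ref = "A", alt = "G")
    names(gr) <- "v1"
    GenotypeMatrix(matrix(dos, 1, dimnames = list("v1", paste0("D", seq_along(dos)))), gr)
  }
  expect_true(filterVariantsByGenotypeClass(mk(c(0, 0, 0, 1, 1, 0))))
  expect_false(filterVariantsByGenotypeClass(mk(c(0, 0, 0, 1, 1, 2))))
  expect_false(filterVariantsByGenotypeClass(mk(c(0, 1, 2, 2, 2, 2, 2, 0))))
  expect_true(filterVariantsByGenotypeClass(mk(c(0, 1, 1, 2, 2, 0))))
  # dosages are hardened on the phenotype's donor subset only
  g8 <- mk(c(0, 0, 1, 1, 2, 2, 0, 0))
  expect_false(filterVariantsByGenotypeClass(g8, donors = paste0("D", 1:5)))
})

test_that("binomial edQTL fit matches an independent Newton IRLS oracle", {
  set.seed(1)
  n <- 20
  g <- rbinom(n, 2, 0.4)
  tot <- rnbinom(n, mu = 40, size = 5) + 5L
  p <- plogis(-1 + 0.8 * g)
  ed <- rbinom(n, tot, p)
  cv <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "c1"))
  fit <- fitBinomialEdQTL(ed, tot, g, cv)
  X <- cbind(1, g, cv)
  oracle <- newtonBinomOracle(X, ed, tot)
  expect_equal(fit$beta, unname(oracle[2]), tolerance = 1e-6)
  # exact null: identical counts across donors give beta 0
  f0 <- fitBinomialEdQTL(rep(5, 12), rep(10, 12), rep(0:2, 4))
  expect_lt(abs(f0$beta), 1e-8)
  expect_gt(f0$p, 0.99)
  # degenerate designs are skips, not crashes
  expect_equal(fitBinomialEdQTL(ed, tot, rep(1, n))$reason, "monomorphic")
  expect_false(fitBinomialEdQTL(ed[1:5], tot[1:5], g[1:5])$converged)
})

test_that("IBS kinship equals the brute-force pairwise mean", {
  set.seed(7)
  dos <- matrix(sample(0:2, 60 * 8, TRUE), 60, 8,
                dimnames = list(sprintf("v%02d", 1:60), paste0("D", 1:8)))
  gr <- GenomicRanges::GRanges(rep(c("chr1", "chr2"), each = 30),
                               IRanges::IRanges(rep(seq_len(30) * 100, 2),
                                                width = 1),
                               ref = "A", alt = "G")
  names(gr) <- rownames(dos)
  g <- GenotypeMatrix(dos, gr)
  K <- suppressWarnings(computeIBSKinship(g))
  Kb <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    Kb[i, j] <- mean((2 - abs(dos[, i] - dos[, j])) / 2)
  expect_equal(unname(K), Kb, tolerance = 1e-12)
  expect_true(all(diag(K) == 1))
  # identical donors -> 1; everywhere-opposite dosages -> 0
  expect_equal(mean((2 - abs(rep(0, 5) - rep(2, 5))) / 2), 0)
  # LOCO excludes the stated chromosome
  Kl <- suppressWarnings(computeIBSKinship(g, loco_chrom = "chr1"))
  Kb2 <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    Kb2[i, j] <- mean((2 - abs(dos[31:60, i] - dos[31:60, j])) / 2)
  expect_equal(unname(Kl), Kb2, tolerance = 1e-12)
})

test_that("LMM with identity kinship reproduces OLS exactly", {
  set.seed(21)
  n <- 50
  g <- rbinom(n, 2, 0.3)
  cv <- matrix(rnorm(2 * n), n, dimnames = list(NULL, c("c1", "c2")))
  y <- 0.3 * g + cv[, 1] + rnorm(n)
  fit <- fitLmmApaQTL(y, g, cv, kinship = diag(n))
  ols <- summary(lm(y ~ g + cv))$coefficients["g", ]
  expect_equal(fit$beta, unname(ols["Estimate"]), tolerance = 1e-8)
  expect_equal(fit$se, unname(ols["Std. Error"]), tolerance = 1e-8)
  expect_equal(fit$p, unname(ols["Pr(>|t|)"]), tolerance = 1e-8)
})

test_that("LMM GLS coefficients match a direct matrix-inverse oracle", {
  set.seed(22)
  n <- 40
  A <- matrix(rnorm(n * 5), n, 5)
  K <- tcrossprod(A) / 5 + diag(n)
  K <- K / mean(diag(K))
  g <- rbinom(n, 2, 0.4)
  u <- drop(t(chol(K)) %*% rnorm(n))
  y <- 0.5 * g + u + rnorm(n, 0, 0.5)
  fit <- fitLmmApaQTL(y, g, kinship = K)
  # closed-form GLS with the same fitted variance components
  Sigma <- fit$sigma_u2 * K + fit$sigma_e2 * diag(n)
  X <- cbind(1, g)
  b <- solve(t(X) %*% solve(Sigma, X), t(X) %*% solve(Sigma, y))
  expect_equal(fit$beta, b[2], tolerance = 1e-8)
})

test_that("variance component is near zero for iid phenotypes on structured K", {
  set.seed(23)
  cfg <- simConfig(n_donors = 80, n_variants = 200,
                   frac_related_pairs = 0.5, seed = 23)
  g <- simulateGenotypes(cfg)
  K <- computeIBSKinship(g)
  frac_small <- mean(vapply(1:100, function(i) {
    y <- rnorm(80)
    f <- fitLmmApaQTL(y, dosageMatrix(g)[1, ], kinship = K)
    f$sigma_u2 < 0.05 * var(y)
  }, logical(1)))
  expect_gte(frac_small, 0.9)
})

test_that("phenotype PCs capture dominant structure and are orthogonal", {
  set.seed(24)
  u <- rnorm(30)
  pheno <- outer(rnorm(15), u) + matrix(rnorm(450, 0, 1e-3), 15, 30)
  colnames(pheno) <- paste0("D", 1:30)
  sc <- phenotypePCs(pheno, 3)
  tot <- sum(apply(t(pheno), 2, var))
  expect_gt(var(sc[, 1]) / tot, 0.99)
  gram <- crossprod(sc)
  expect_lt(max(abs(gram[upper.tri(gram)])) / max(diag(gram)), 1e-8)
  expect_equal(ncol(phenotypePCs(pheno, 0)), 0)
})

test_that("covariate-PC optimization helps with a planted confounder and breaks ties low", {
  expect_equal(optimizeCovariates(function(k) 5, c(0, 1, 2))$k, 0)
  expect_equal(optimizeCovariates(function(k) k, c(0))$k, 0)
  cfg <- simConfig(n_edit_sites = 60, frac_edit_qtl = 0.25, beta_edit = 1.2,
                   global_factor_sd = 2, batch_effect_sd = 0, seed = 25)
  g <- simulateGenotypes(cfg)
  sim <- simulateEditing(g, cfg)
  edex <- discoverEditSites(sim$edex)
  # robust (sandwich) tests so that the uncontrolled latent factor costs
  # power instead of miscalibrating the binomial Wald test
  counts <- vapply(c(0, 1), function(k) {
    s <- mapEdQTL(edex, g, n_pheno_pcs = k, robust = TRUE)
    if (is.null(s$phenotypes)) 0L else sum(s$phenotypes$significant)
  }, integer(1))
  expect_gt(counts[2], counts[1])
  opt <- optimizeCovariates(function(k) counts[k + 1], c(0, 1))
  expect_gte(opt$k, 1)
})

test_that("eigenMT effective tests match the eigen-count oracle and bounds", {
  set.seed(3)
  G <- matrix(rbinom(50 * 200, 2, 0.4), 50, 200)
  expect_equal(eigenMTMeff(G), meffOracle(G))
  # duplicated single variant collapses to one test
  dup <- G[rep(1, 20), ]
  expect_equal(eigenMTMeff(dup), 1)
  expect_equal(eigenMTMeff(G[1, , drop = FALSE]), 1)
  # duplicating every column (variant rows stay; donors duplicated) and
  # duplicating all variant rows changes m_eff by < 10%
  m1 <- eigenMTMeff(G)
  m2 <- eigenMTMeff(G[rep(seq_len(50), each = 2), ])
  expect_lt(abs(m2 - m1) / m1, 0.1)
  expect_gte(m1, 1)
  expect_lte(m1, nrow(G))
  # windowing: per-window counting still within [1, M]
  m3 <- eigenMTMeff(G, window = 7)
  expect_gte(m3, 1)
  expect_lte(m3, nrow(G))
})

test_that("hierarchical FDR adjusts locally then applies BH globally", {
  rec <- data.frame(phenotype_id = "p1", p_min = 0.001, m_eff = 10)
  out <- hierarchicalFDR(rec)
  expect_equal(out$p_local, 0.01)
  expect_equal(out$q_global, 0.01)
  expect_true(out$significant)
  expect_equal(hierarchicalFDR(data.frame(phenotype_id = "p", p_min = 0.2,
                                          m_eff = 10))$p_local, 1)
  set.seed(26)
  rec2 <- data.frame(phenotype_id = paste0("p", 1:40),
                     p_min = runif(40, 0, 0.2),
                     m_eff = sample(1:20, 40, TRUE))
  out2 <- hierarchicalFDR(rec2)
  expect_equal(out2$q_global, bhOracle(out2$p_local))
})

test_that("primary selection breaks ties by distance then position", {
  a <- data.frame(phenotype_id = "p", variant_id = c("a", "b", "c"),
                  p_nominal = c(0.01, 0.001, 0.05),
                  distance = c(1, 2, 3), pos = 1:3)
  expect_equal(selectPrimary(a)$variant_id, "b")
  b <- data.frame(phenotype_id = "p", variant_id = c("far", "near"),
                  p_nominal = 0.001, distance = c(50000, 5000),
                  pos = c(9, 1))
  expect_equal(selectPrimary(b)$variant_id, "near")
  cc <- data.frame(phenotype_id = "p", variant_id = c("hi", "lo"),
                   p_nominal = 0.001, distance = 100, pos = c(900, 100))
  expect_equal(selectPrimary(cc)$variant_id, "lo")
})
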