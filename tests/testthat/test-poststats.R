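test_that("pi1 hits the extremes and recovers a known beta-uniform mixture", {
  expect_gte(pi1Estimate(rep(1e-8, 500))$pi1, 0.95)
  grid <- seq(1e-4, 1, length.out = 5000)  # exact uniform grid of p-values
  expect_lte(pi1Estimate(grid)$pi1, 0.05)
  set.seed(11)
  p <- c(rbeta(1500, 0.1, 1), runif(3500))
  expect_lt(abs(pi1Estimate(p)$pi1 - 0.3), 0.07)
})

test_that("pi1 lookup warns on few pairs and handles empty overlap", {
  disc <- data.frame(phenotype_id = paste0("p", 1:10),
                     variant_id = paste0("v", 1:10))
  repl <- data.frame(phenotype_id = paste0("p", 1:10),
                     variant_id = paste0("v", 1:10),
                     p_nominal = rep(1e-6, 10))
  expect_warning(r <- pi1Overlap(disc, repl), "fewer than 50")
  expect_gt(r$pi1, 0.9)
  none <- data.frame(phenotype_id = "x", variant_id = "y", p_nominal = 0.5)
  expect_message(r0 <- pi1Overlap(disc, none), "no matched")
  expect_true(is.na(r0$pi1))
})

test_that("structure enrichment flags extreme enrichment and is stable under identity", {
  annot <- data.frame(
    variant_id = c(paste0("s", 1:10), paste0("n", 1:50)),
    structure = c(rep("stem", 10),
                  rep(c("exterior", "bulge"), 25)),
    dist_to_site = rep(100, 60), maf = rep(0.3, 60))
  res <- structureEnrichment(paste0("s", 1:10), paste0("n", 1:50), annot,
                             n_perm = 200, seed = 1, strict = "greater")
  stem <- res[res$category == "stem", ]
  expect_equal(stem$p, 0)
  expect_equal(stem$p_add1, 1 / 201)
  # identical composition: p near 1/2
  set.seed(2)
  cats <- sample(c("stem", "bulge", "exterior"), 300, TRUE)
  annot2 <- data.frame(variant_id = paste0("v", 1:300),
                       structure = cats,
                       dist_to_site = runif(300, 1, 800),
                       maf = runif(300, 0.1, 0.5))
  r2 <- suppressWarnings(
    structureEnrichment(paste0("v", 1:40), paste0("v", 41:300), annot2,
                        n_perm = 400, seed = 3))
  expect_true(all(r2$p > 0.05 & r2$p < 0.98))
  # relabeling a non-tested category leaves the stem row unchanged
  annot3 <- annot2
  annot3$structure[annot3$structure == "bulge"] <- "multiloop"
  r3 <- suppressWarnings(
    structureEnrichment(paste0("v", 1:40), paste0("v", 41:300), annot3,
                        n_perm = 400, seed = 3))
  expect_equal(r2[r2$category == "stem", ],
               r3[r3$category == "stem", ], ignore_attr = TRUE)
  # unmatched significant variants are excluded with a warning
  annot4 <- annot2
  annot4$maf[1] <- 0.0001
  expect_warning(structureEnrichment(paste0("v", 1:5), paste0("v", 41:300),
                                     annot4, n_perm = 50, seed = 4),
                 "no MAF/distance-matched")
})

test_that("ld r2 matches direct correlation and flags monomorphic variants", {
  dos <- rbind(v1 = c(0, 0, 1, 1, 2, 2),
               v2 = c(0, 0, 1, 1, 2, 2),
               v3 = c(1, 1, 1, 1, 1, 1),
               v4 = c(0, 2, 0, 2, 0, 2))
  colnames(dos) <- paste0("D", 1:6)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:4 * 100, width = 1),
                               ref = "A", alt = "G")
  names(gr) <- rownames(dos)
  g <- GenotypeMatrix(dos, gr)
  expect_equal(ldR2(g, "v1", "v2"), 1)
  expect_equal(ldR2(g, "v1", "v4"), cor(dos[1, ], dos[4, ])^2,
               tolerance = 1e-12)
  expect_true(is.na(ldR2(g, "v1", "v3")))
})

test_that("greedy GWAS index pruning keeps the strongest variant per LD clump", {
  # construct dosages with engineered correlations via orthonormal scores
  set.seed(5)
  Z <- qr.Q(qr(matrix(rnorm(60 * 3), 60, 3)))
  a <- Z[, 1]
  b <- sqrt(0.5) * Z[, 1] + sqrt(0.5) * Z[, 2]   # r2(A,B) = 0.5
  cc <- sqrt(0.1) * Z[, 1] + sqrt(0.9) * Z[, 3]  # r2(A,C) = 0.1
  # rescale into [0, 2] (correlations are scale/shift invariant)
  resc <- function(x) 2 * (x - min(x)) / (max(x) - min(x))
  dos <- rbind(A = resc(a), B = resc(b), C = resc(cc))
  colnames(dos) <- paste0("D", 1:60)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:3 * 1000, width = 1),
                               ref = "A", alt = "G")
  names(gr) <- rownames(dos)
  g <- GenotypeMatrix(dos, gr)
  r_ab <- ldR2(g, "A", "B"); r_ac <- ldR2(g, "A", "C")
  expect_gt(r_ab, 0.2)
  expect_lt(r_ac, 0.2)
  gwas <- data.frame(variant_id = c("A", "B", "C"), pos = 1:3 * 1000,
                     p = c(1e-12, 1e-10, 1e-9))
  kept <- gwasIndexVariants(gwas, g, p_thresh = 5e-8, prune_r2 = 0.2)
  expect_equal(kept, c("A", "C"))
  # duplicated variant: only the smaller p survives
  dos2 <- rbind(X = dos["A", ], Y = dos["A", ])
  gr2 <- gr[1:2]; names(gr2) <- c("X", "Y")
  g2 <- GenotypeMatrix(dos2, gr2)
  gwas2 <- data.frame(variant_id = c("X", "Y"), pos = c(1, 2),
                      p = c(1e-9, 1e-12))
  expect_equal(gwasIndexVariants(gwas2, g2), "Y")
  # uncorrelated pair: both kept; nothing significant: empty set
  expect_length(gwasIndexVariants(data.frame(variant_id = "A", pos = 1,
                                             p = 0.5), g), 0)
})

test_that("conditional colocalization verdict logic follows the thresholds", {
  dos <- rbind(q = c(0, 0, 1, 1, 2, 2, 0, 1),
               w = c(0, 0, 1, 1, 2, 2, 0, 1),
               z = c(2, 0, 1, 2, 0, 1, 2, 0))
  colnames(dos) <- paste0("D", 1:8)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:3 * 50, width = 1),
                               ref = "A", alt = "G")
  names(gr) <- rownames(dos)
  g <- GenotypeMatrix(dos, gr)
  qtl <- data.frame(phenotype_id = "ph", variant_id = "q")
  # same variant: collinear but colocalized
  same <- conditionalColocalization(qtl, "q", g, refit = function(...) 0.5)
  expect_equal(same$verdict, "colocalized")
  expect_true(same$collinear)
  # r2 = 1 but distinct id: refit returns NA -> collinear verdict
  coll <- conditionalColocalization(qtl, "w", g,
                                    refit = function(...) NA_real_)
  expect_equal(coll$verdict, "collinear")
  # conditional p decides the call
  expect_equal(conditionalColocalization(qtl, "w", g,
                                         refit = function(...) 0.5)$verdict,
               "colocalized")
  expect_equal(conditionalColocalization(qtl, "w", g,
                                         refit = function(...) 1e-6)$verdict,
               "not_colocalized")
  # no pair above the r2 threshold: empty call list
  none <- conditionalColocalization(qtl, "z", g, refit = function(...) 0.5)
  expect_equal(nrow(none), 0)
})

test_that("mediation weights are normalized and generative models are recovered", {
  set.seed(6)
  x <- rbinom(100, 2, 0.4)
  m <- 0.8 * x + rnorm(100)
  y <- 0.8 * m + rnorm(100)
  res <- mediationTriplet(x, m, y)
  expect_equal(sum(res$weights), 1)
  expect_true(all(res$weights >= 0 & res$weights <= 1))
  expect_equal(names(which.max(res$weights)), "forward")
  # independent-model generation: X drives both M and Y, no M-Y path
  top_ind <- colMeans(t(vapply(1:40, function(i) {
    xi <- rbinom(80, 2, 0.4)
    mediationTriplet(xi, 0.8 * xi + rnorm(80),
                     0.8 * xi + rnorm(80))$weights
  }, numeric(3))))
  expect_equal(names(which.max(top_ind)), "independent")
  expect_error(mediationTriplet(x[1:10], m[1:10], y[1:10]), "30 complete")
  degen <- mediationTriplet(x, rep(1, 100), y)
  expect_true(all(is.na(degen$weights)))
})

test_that("distance profiles are strand-aware with exhaustive splice minima", {
  genes <- data.frame(gene_id = c("gf", "gr"), start = c(1000, 1000),
                      end = c(5000, 5000), strand = c("+", "-"))
  vars <- data.frame(variant_id = c("atTSS", "up500", "revUp"),
                     gene_id = c("gf", "gf", "gr"),
                     pos = c(1000, 500, 5500))
  d <- distanceProfiles(vars, genes)
  expect_equal(d$dist_tss[d$variant_id == "atTSS"], 0)
  expect_equal(d$dist_tss[d$variant_id == "up500"], -500)
  expect_equal(d$dist_tss[d$variant_id == "revUp"], -500)  # minus strand
  introns <- data.frame(gene_id = "gf", intron_start = c(1500, 3000),
                        intron_end = c(2000, 4000))
  v2 <- data.frame(variant_id = "mid", gene_id = "gf", pos = 2600)
  d2 <- distanceProfiles(v2, genes, introns)
  expect_equal(d2$dist_splice, min(abs(2600 - c(1500, 2000, 3000, 4000))))
  # no introns: missing splice distance
  expect_true(is.na(distanceProfiles(v2, genes,
                                     introns[0, ])$dist_splice))
})
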