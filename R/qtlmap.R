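#' Candidate cis phenotype-variant pairs
#'
#' Editing phenotypes are anchored at the edit site: variants within
#' \code{window} bp of the site and (when \code{same_gene}) inside the
#' harboring gene's span are tested.  APA phenotypes are anchored at both
#' 3'UTR ends: variants within \code{window} bp of either the start or the
#' end qualify.  All boundaries are inclusive.
#'
#' @param anchors data.frame with \code{phenotype_id}, \code{chrom} and
#'   either \code{pos} (single anchor; editing) or \code{start}/\code{end}
#'   (dual anchors; APA).  For \code{same_gene = TRUE} it must also carry
#'   \code{gene_start} and \code{gene_end}.
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param window cis window half-width in bp (100000 for editing, 25000 for
#'   APA by default in the pipeline drivers).
#' @param same_gene restrict to variants within the phenotype's gene span.
#' @return data.frame: phenotype_id, variant_id, distance (bp to the nearest
#'   anchor).
#' @export
cisPairs <- function(anchors, geno, window, same_gene = FALSE) {
  stopifnot(window > 0)
  vi <- variantInfo(geno)
  dual <- all(c("start", "end") %in% names(anchors))
  if (!dual && !"pos" %in% names(anchors))
    stop("anchors need either 'pos' or 'start'/'end' columns")
  out <- vector("list", nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    if (is.na(a$chrom) || (dual && (is.na(a$start) || is.na(a$end))) ||
        (!dual && is.na(a$pos))) {
      warning("phenotype ", a$phenotype_id, " lacks coordinates; skipped")
      next
    }
    sel <- vi$chrom == a$chrom
    if (dual) {
      dist <- pmin(abs(vi$pos - a$start), abs(vi$pos - a$end))
    } else {
      dist <- abs(vi$pos - a$pos)
    }
    sel <- sel & dist <= window
    if (same_gene)
      sel <- sel & vi$pos >= a$gene_start & vi$pos <= a$gene_end
    if (any(sel))
      out[[i]] <- data.frame(phenotype_id = a$phenotype_id,
                             variant_id = vi$variant_id[sel],
                             distance = dist[sel], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(phenotype_id = character(), variant_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  res
}

#' Genotype-class variant filter
#'
#' Keeps a variant when, among the stated donors (dosages hardened by
#' rounding; dosages further than \code{max_uncertainty} from an integer are
#' treated as missing), there are at least two heterozygotes and either at
#' least two or zero homozygous-minor donors.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param donors donor ids defining the phenotype's supporting subset
#'   (default all donors).
#' @param variant_ids variants to assess (default all).
#' @param max_uncertainty imputed-dosage distance from the nearest integer
#'   beyond which a donor is excluded (default 0.45).
#' @return named logical vector over \code{variant_ids}.
#' @export
filterVariantsByGenotypeClass <- function(geno, donors = colnames(geno),
                                          variant_ids = rownames(geno),
                                          max_uncertainty = 0.45) {
  d <- dosageMatrix(geno)[variant_ids, donors, drop = FALSE]
  hard <- round(d)
  hard[abs(d - hard) > max_uncertainty] <- NA
  apply(hard, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(FALSE)
    minor_hom <- if (mean(x) / 2 > 0.5) 0 else 2
    n_het <- sum(x == 1)
    n_hom_minor <- sum(x == minor_hom)
    n_het >= 2 && (n_hom_minor == 0 || n_hom_minor >= 2)
  })
}

#' Binomial GLM edQTL test for one site-variant pair
#'
#' Logistic regression of aggregated (edited, unedited) read counts on the
#' variant dosage plus covariates, fitted by iteratively reweighted least
#' squares; the per-minor-allele log-odds (beta) is tested with a Wald test.
#' An optional overdispersion-robust sandwich variance is available for
#' count data with extra-binomial variation (off by default).
#'
#' @param edited,total integer vectors over donors.
#' @param dosage numeric dosage vector over the same donors.
#' @param covariates numeric matrix (donors x q) or NULL.
#' @param robust use a heteroskedasticity-robust (sandwich) variance for the
#'   Wald test.
#' @return list: beta, se, p, n, converged, reason (NA when fitted).
#' @export
fitBinomialEdQTL <- function(edited, total, dosage, covariates = NULL,
                             robust = FALSE) {
  ok <- !is.na(edited) & !is.na(total) & !is.na(dosage) & total > 0
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & complete.cases(covariates)
  }
  skip <- function(reason) list(beta = NA_real_, se = NA_real_, p = NA_real_,
                                n = sum(ok), converged = FALSE,
                                reason = reason)
  if (sum(ok) < 10) return(skip("fewer than 10 covered donors"))
  g <- dosage[ok]
  if (sd(g) == 0) return(skip("monomorphic"))
  y <- cbind(edited[ok], total[ok] - edited[ok])
  Xm <- cbind(`(Intercept)` = 1, g = g,
              if (!is.null(covariates)) covariates[ok, , drop = FALSE])
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(Xm, y, family = binomial(),
                                    control = glm.control(epsilon = 1e-10,
                                                          maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(skip("fit error"))
  if (!fit$converged) return(skip("non-convergence"))
  cf <- fit$coefficients
  if (is.na(cf["g"]) || abs(cf["g"]) > 15)
    return(skip("separation"))
  w <- fit$weights
  bread <- tryCatch(chol2inv(chol(crossprod(Xm * sqrt(w)))),
                    error = function(e) NULL)
  if (is.null(bread)) return(skip("singular design"))
  if (robust) {
    # HC sandwich on the binomial score: bread (X'WX)^-1, meat X' diag(s^2) X
    r <- fit$residuals * w  # working residuals * IRLS weights = scores
    V <- bread %*% crossprod(Xm * r) %*% bread
    se <- sqrt(diag(V))[2L]
  } else {
    se <- sqrt(diag(bread))[2L]
  }
  # Wald test with a t reference (df = n - p): closer to nominal than the
  # normal reference at cohort-scale n
  z <- cf["g"] / se
  df_ <- sum(ok) - ncol(Xm)
  list(beta = unname(cf["g"]), se = unname(se),
       p = unname(2 * pt(-abs(z), df = df_)), n = sum(ok), converged = TRUE,
       reason = NA_character_)
}

#' Identity-by-state kinship matrix
#'
#' K[j, j'] is the mean over variants of (2 - |d_j - d_j'|) / 2, i.e. the
#' average fraction of alleles shared by state; 1 for identical hardened
#' dosage vectors.  With \code{loco_chrom} set, variants on that chromosome
#' are excluded (leave-one-chromosome-out), avoiding proximal contamination
#' when the kinship enters the mixed-model error covariance.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param loco_chrom chromosome to leave out, or NULL.
#' @return symmetric donors x donors matrix.
#' @export
computeIBSKinship <- function(geno, loco_chrom = NULL) {
  d <- dosageMatrix(geno)
  if (!is.null(loco_chrom)) {
    chrom <- as.character(GenomicRanges::seqnames(
      SummarizedExperiment::rowRanges(geno)))
    d <- d[chrom != loco_chrom, , drop = FALSE]
  }
  M <- nrow(d)
  if (M < 50) warning("fewer than 50 variants: IBS kinship may be unstable")
  # sum over variants of |d_j - d_j'| via dosage-class indicators
  ind <- lapply(0:2, function(v) (abs(d - v) < 0.5) + 0)
  sumabs <- matrix(0, ncol(d), ncol(d))
  for (u in 0:2) for (v in 0:2) if (u != v)
    sumabs <- sumabs + abs(u - v) * crossprod(ind[[u + 1]], ind[[v + 1]])
  K <- (2 * M - sumabs) / (2 * M)
  dimnames(K) <- list(colnames(d), colnames(d))
  K
}

# Spectral REML for the one-random-effect mixed model y = Xb + u + e,
# cov = sigma_u^2 K + sigma_e^2 I.  Returns the rotation and variance
# components estimated under the covariates-only null (EMMAX stage 1).
.lmmNull <- function(y, X, K) {
  n <- length(y)
  eig <- eigen(K, symmetric = TRUE)
  dvals <- pmax(eig$values, 0)
  if (min(eig$values) < -1e-6 * max(abs(eig$values)))
    stop("kinship matrix is not positive semi-definite after shift")
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  p <- ncol(X)
  reml <- function(log_lambda) {
    lambda <- exp(log_lambda)
    w <- lambda * dvals + 1
    fit <- lm.wfit(Xt, yt, w = 1 / w)
    rss <- sum(fit$residuals^2 / w)
    s2 <- rss / (n - p)
    XtWX <- crossprod(Xt / sqrt(w))
    -0.5 * ((n - p) * log(s2) + sum(log(w)) +
              determinant(XtWX, logarithm = TRUE)$modulus)
  }
  opt <- optimize(reml, c(log(1e-6), log(1e6)), maximum = TRUE)
  lambda <- exp(opt$maximum)
  # Boundary screen: with an IBS kinship, K has an identity-scale component
  # (self-sharing), so under iid noise (sigma_u2, sigma_e2) sit on a flat
  # likelihood ridge.  Keep the random effect only when the REML gain over
  # the OLS boundary clears a 50:50 chi-square mixture threshold (alpha 0.1);
  # otherwise collapse to sigma_u2 = 0.
  ll0 <- reml(log(1e-8))
  if (2 * (opt$objective - ll0) < qchisq(0.8, df = 1)) lambda <- 0
  w <- lambda * dvals + 1
  fit <- lm.wfit(Xt, yt, w = 1 / w)
  sigma_e2 <- sum(fit$residuals^2 / w) / (n - p)
  list(U = U, d = dvals, yt = yt, lambda = lambda,
       sigma_e2 = sigma_e2, sigma_u2 = lambda * sigma_e2,
       at_boundary = lambda == 0)
}

#' EMMAX-style linear mixed-model apaQTL test
#'
#' Two-stage fit: (1) variance components (sigma_u^2, sigma_e^2) of the error
#' covariance sigma_u^2 K + sigma_e^2 I are estimated once per phenotype by
#' REML under the covariates-only null, using the spectral decomposition of
#' K; (2) each variant is tested by generalized least squares with those
#' weights held fixed.  The Wald variance is rescaled by the full-model
#' weighted residual sum of squares, so with K = I the test collapses
#' exactly to ordinary least squares.  A boundary estimate sigma_u^2 = 0 is
#' flagged, not an error.
#'
#' @param y normalized phenotype vector over donors.
#' @param dosage variant dosage vector.
#' @param covariates donors x q matrix or NULL.
#' @param kinship donors x donors PSD matrix (e.g.
#'   \code{\link{computeIBSKinship}}).
#' @return list: beta, se, p, n, sigma_u2, sigma_e2, heritability (ratio
#'   sigma_u2 / (sigma_u2 + sigma_e2)), at_boundary.
#' @export
fitLmmApaQTL <- function(y, dosage, covariates = NULL, kinship) {
  ok <- !is.na(y) & !is.na(dosage)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & complete.cases(covariates)
  }
  y <- y[ok]; g <- dosage[ok]
  K <- kinship[ok, ok, drop = FALSE]
  X0 <- cbind(`(Intercept)` = rep(1, length(y)),
              if (!is.null(covariates)) covariates[ok, , drop = FALSE])
  null <- .lmmNull(y, X0, K)
  tst <- .lmmTest(null, X0, g)
  c(tst, list(sigma_u2 = null$sigma_u2, sigma_e2 = null$sigma_e2,
              heritability = null$sigma_u2 /
                (null$sigma_u2 + null$sigma_e2),
              at_boundary = null$at_boundary))
}

.lmmTest <- function(null, X0, g) {
  n <- length(null$yt)
  if (sd(g) == 0)
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, n = n,
                reason = "monomorphic"))
  X <- cbind(X0, g = g)
  Xt <- crossprod(null$U, X)
  w <- null$lambda * null$d + 1
  fit <- lm.wfit(Xt, null$yt, w = 1 / w)
  p_full <- ncol(X)
  rss <- sum(fit$residuals^2 / w)
  s2 <- rss / (n - p_full)
  XtWX_inv <- chol2inv(chol(crossprod(Xt / sqrt(w))))
  se <- sqrt(s2 * diag(XtWX_inv))
  j <- p_full
  tval <- fit$coefficients[j] / se[j]
  list(beta = unname(fit$coefficients[j]), se = unname(se[j]),
       p = unname(2 * pt(-abs(tval), df = n - p_full)), n = n,
       reason = NA_character_)
}

#' Phenotype principal components
#'
#' Top-k PC scores of the centered phenotype matrix (edit rates or
#' normalized PAU), used as covariates capturing global unmeasured technical
#' variation.  Missing entries are imputed at the phenotype mean before the
#' decomposition.
#'
#' @param pheno phenotypes x donors matrix.
#' @param k number of components (0 returns a zero-column matrix).
#' @return donors x k matrix of scores.
#' @export
phenotypePCs <- function(pheno, k) {
  donors <- colnames(pheno)
  if (k <= 0)
    return(matrix(numeric(0), nrow = ncol(pheno), ncol = 0,
                  dimnames = list(donors, NULL)))
  stopifnot(k < min(dim(pheno)))
  m <- t(pheno)  # donors x phenotypes
  mu <- colMeans(m, na.rm = TRUE)
  for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mu[j]
  keep <- apply(m, 2, sd) > 0
  pr <- stats::prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  sc <- pr$x[, seq_len(min(k, ncol(pr$x))), drop = FALSE]
  rownames(sc) <- donors
  colnames(sc) <- paste0("phenoPC", seq_len(ncol(sc)))
  sc
}

#' Genotype MDS covariates
#'
#' Top axes from classical multidimensional scaling of the IBS distance
#' (1 - K), representing population structure; the first three axes are the
#' default population-stratification covariates of both QTL models.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param k number of axes (default 3).
#' @return donors x k matrix.
#' @export
genotypeMDS <- function(geno, k = 3) {
  K <- computeIBSKinship(geno)
  mds <- cmdscale(as.dist(1 - K), k = k)
  colnames(mds) <- paste0("MDS", seq_len(ncol(mds)))
  mds
}

#' Choose the phenotype-PC count maximizing discovery
#'
#' Runs the full scan for every candidate k and picks the k with the most
#' phenotypes significant at the hierarchical FDR threshold; ties go to the
#' smallest k.
#'
#' @param scan_fun function(k) returning the count of significant
#'   phenotypes.
#' @param k_grid integer vector of candidate PC counts.
#' @return list: k (chosen), counts (named vector over the grid).
#' @export
optimizeCovariates <- function(scan_fun, k_grid) {
  stopifnot(length(k_grid) > 0)
  counts <- vapply(k_grid, function(k) as.numeric(scan_fun(k)), numeric(1))
  names(counts) <- as.character(k_grid)
  k_sorted <- sort(k_grid)
  counts_sorted <- counts[as.character(k_sorted)]
  best <- k_sorted[which.max(counts_sorted)]  # ties -> smallest k
  list(k = best, counts = counts)
}

#' Effective number of independent cis tests (eigenMT)
#'
#' Cis variants are partitioned into consecutive windows of at most
#' \code{window} variants; in each window the eigenvalues of the variant
#' correlation matrix are counted (descending) until their cumulative share
#' reaches \code{var_explained}.  The per-window counts are summed and
#' clamped to [1, M].  Windows are non-overlapping, so the estimate is
#' conservative (never smaller than a merged-window refinement would give).
#'
#' @param G cis genotype submatrix, variants x donors.
#' @param window variants per window (default 200).
#' @param var_explained cumulative variance threshold (default 0.99).
#' @return effective test count m_eff.
#' @export
eigenMTMeff <- function(G, window = 200, var_explained = 0.99) {
  G <- as.matrix(G)
  M <- nrow(G)
  stopifnot(M >= 1)
  nz <- apply(G, 1, sd) > 0
  if (!all(nz)) G <- G[nz, , drop = FALSE]
  if (nrow(G) == 0) return(1)
  idx <- split(seq_len(nrow(G)), (seq_len(nrow(G)) - 1L) %/% window)
  meff <- sum(vapply(idx, function(ii) {
    sub <- G[ii, , drop = FALSE]
    if (nrow(sub) == 1L) return(1)
    C <- suppressWarnings(cor(t(sub)))
    C[is.na(C)] <- 0; diag(C) <- 1
    ev <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    sum(cumsum(ev) / sum(ev) < var_explained) + 1
  }, numeric(1)))
  min(max(meff, 1), M)
}

#' Hierarchical eigenMT-FDR multiple-testing correction
#'
#' Stage 1 adjusts each phenotype's minimum nominal p locally by its
#' effective number of independent cis tests (Bonferroni-style, clamped at
#' 1); stage 2 applies Benjamini-Hochberg across phenotypes' locally
#' adjusted p-values.  Phenotypes with global q below \code{alpha} are
#' significant.
#'
#' @param records data.frame with columns \code{phenotype_id}, \code{p_min},
#'   \code{m_eff}.
#' @param alpha global FDR level (default 0.05).
#' @return the input with \code{p_local}, \code{q_global},
#'   \code{significant} columns added.
#' @export
hierarchicalFDR <- function(records, alpha = 0.05) {
  stopifnot(all(c("phenotype_id", "p_min", "m_eff") %in% names(records)))
  records$p_local <- pmin(1, records$m_eff * records$p_min)
  records$q_global <- p.adjust(records$p_local, method = "BH")
  records$significant <- !is.na(records$q_global) & records$q_global < alpha
  records
}

#' Primary variant per significant phenotype
#'
#' The primary QTL variant is the variant with the smallest nominal p for
#' the phenotype; ties are broken by smaller distance to the phenotype
#' anchor, then by smaller genomic position.
#'
#' @param assoc data.frame with \code{phenotype_id}, \code{variant_id},
#'   \code{p_nominal}, \code{distance}, \code{pos}.
#' @return one row per phenotype (the primary association).
#' @export
selectPrimary <- function(assoc) {
  take <- function(df) {
    df <- df[order(df$p_nominal, df$distance, df$pos), , drop = FALSE]
    df[1, , drop = FALSE]
  }
  out <- do.call(rbind, lapply(split(assoc, assoc$phenotype_id), take))
  rownames(out) <- NULL
  out
}
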