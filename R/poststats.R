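#' Estimate pi1 (fraction of non-null tests) from a p-value vector
#'
#' The null fraction pi0 is estimated from the p-value histogram over the
#' lambda grid 0.05, 0.10, ..., 0.95 -- pi0(lambda) = #\{p > lambda\} /
#' (m (1 - lambda)) -- smoothed with a natural cubic spline (df = 3) and
#' evaluated at the largest lambda, then clamped to [0, 1].  pi1 = 1 - pi0.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return list: pi1, pi0, n.
#' @export
pi1Estimate <- function(p) {
  p <- p[!is.na(p)]
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  fit <- smooth.spline(lambda, pi0l, df = 3)
  pi0 <- predict(fit, x = max(lambda))$y
  pi0 <- min(max(pi0, 0), 1)
  list(pi1 = 1 - pi0, pi0 = pi0, n = m)
}

#' pi1 sharing of discovery QTLs in a replication scan
#'
#' Looks up each discovery (phenotype, variant) primary pair's nominal
#' p-value in the replication association table and estimates the fraction
#' of non-null replication associations (pi1).
#'
#' @param discovery data.frame with \code{phenotype_id}, \code{variant_id}
#'   (the discovery primary pairs).
#' @param replication data.frame with \code{phenotype_id},
#'   \code{variant_id}, \code{p_nominal} (the replication scan).
#' @return list: pi1, pi0, n_pairs (matched pairs used).
#' @export
pi1Overlap <- function(discovery, replication) {
  m <- merge(discovery[, c("phenotype_id", "variant_id")],
             replication[, c("phenotype_id", "variant_id", "p_nominal")],
             by = c("phenotype_id", "variant_id"))
  pvals <- m$p_nominal[!is.na(m$p_nominal)]
  if (!length(pvals)) {
    message("no matched discovery pairs found in the replication scan")
    return(list(pi1 = NA_real_, pi0 = NA_real_, n_pairs = 0L))
  }
  if (length(pvals) < 50)
    warning("fewer than 50 matched pairs: pi1 estimate may be unstable")
  est <- pi1Estimate(pvals)
  list(pi1 = est$pi1, pi0 = est$pi0, n_pairs = length(pvals))
}

#' Permutation enrichment of significant QTL variants in structure categories
#'
#' For each RNA secondary-structure category, the observed count of
#' significant variants in the category is compared with a permutation null:
#' in each permutation, one non-significant variant is drawn (without
#' replacement within the permutation) per significant variant, matched on
#' MAF and absolute distance to the edit site within a +/-\code{match_tol}
#' relative tolerance on each feature.  The enrichment p is the fraction of
#' permutations whose in-category count reaches the observed count
#' (">=", the standard permutation p, calibrated under the null; the strict
#' ">" variant is available but anti-conservative when counts tie),
#' reported alongside the add-one-corrected (1 + #exceeding) / (1 + n_perm).
#'
#' @param sig,nonsig character vectors of significant and non-significant
#'   variant ids.
#' @param annot data.frame: variant_id, structure, dist_to_site, maf.
#' @param n_perm number of permutations (default 1000).
#' @param match_tol relative matching tolerance (default 0.5).
#' @param seed integer seed.
#' @param strict "geq" (default) or "greater" (the count must strictly
#'   exceed the observed one).
#' @return data.frame: category, observed, n_sig_used, p, p_add1.
#' @export
structureEnrichment <- function(sig, nonsig, annot, n_perm = 1000,
                                match_tol = 0.5, seed = 1,
                                strict = c("geq", "greater")) {
  strict <- match.arg(strict)
  stopifnot(length(sig) > 0, length(nonsig) > 0)
  rownames(annot) <- annot$variant_id
  miss <- setdiff(c(sig, nonsig), annot$variant_id)
  if (length(miss)) stop("annotations missing for variants: ",
                         paste(head(miss), collapse = ", "))
  as_ <- annot[sig, ]; an_ <- annot[nonsig, ]
  cats <- sort(unique(annot$structure))
  # eligible matched candidates per significant variant
  elig <- lapply(seq_len(nrow(as_)), function(i) {
    dm <- abs(an_$maf - as_$maf[i]) <= match_tol * as_$maf[i]
    dd <- abs(abs(an_$dist_to_site) - abs(as_$dist_to_site[i])) <=
      match_tol * abs(as_$dist_to_site[i])
    which(dm & dd)
  })
  none <- lengths(elig) == 0
  if (any(none)) {
    warning(sum(none), " significant variant(s) had no MAF/distance-matched ",
            "candidate within the tolerance and were excluded; consider ",
            "widening match_tol")
    elig <- elig[!none]
    as_ <- as_[!none, , drop = FALSE]
  }
  if (!nrow(as_)) {
    warning("no significant variants could be matched; enrichment p missing")
    return(data.frame(category = cats, observed = NA_integer_,
                      n_sig_used = 0L, p = NA_real_, p_add1 = NA_real_))
  }
  observed <- table(factor(as_$structure, levels = cats))
  ns <- nrow(as_)
  ord <- order(lengths(elig))  # scarcest first so greedy sampling completes
  struct_ns <- an_$structure
  set.seed(seed)
  greater <- matrix(0L, n_perm, length(cats),
                    dimnames = list(NULL, cats))
  for (b in seq_len(n_perm)) {
    used <- rep(FALSE, nrow(an_))
    pick <- integer(ns)
    for (i in ord) {
      cand <- elig[[i]][!used[elig[[i]]]]
      if (!length(cand)) cand <- elig[[i]]  # matched pool exhausted: reuse
      pick[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
      used[pick[i]] <- TRUE
    }
    greater[b, ] <- tabulate(factor(struct_ns[pick], levels = cats),
                             nbins = length(cats))
  }
  cmp <- if (strict == "greater") sweep(greater, 2, as.integer(observed), ">")
         else sweep(greater, 2, as.integer(observed), ">=")
  n_greater <- colSums(cmp)
  data.frame(category = cats, observed = as.integer(observed),
             n_sig_used = ns, p = n_greater / n_perm,
             p_add1 = (1 + n_greater) / (1 + n_perm),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Squared LD between two variants
#'
#' Squared Pearson correlation of the dosage vectors over the stated donors;
#' NA when either variant is monomorphic in the subset.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param a,b variant ids.
#' @param donors donor subset (default all).
#' @return r-squared in [0, 1] or NA.
#' @export
ldR2 <- function(geno, a, b, donors = colnames(geno)) {
  d <- dosageMatrix(geno)[c(a, b), donors, drop = FALSE]
  if (sd(d[1, ]) == 0 || sd(d[2, ]) == 0) return(NA_real_)
  cor(d[1, ], d[2, ])^2
}

#' LD-pruned GWAS index variants
#'
#' Genome-wide significant variants (p below \code{p_thresh}) are greedily
#' pruned: sorted by ascending p (ties by genomic position), a variant is
#' kept iff its r-squared with every already-kept variant is below
#' \code{prune_r2}.
#'
#' @param gwas data.frame: variant_id, pos, p.
#' @param geno a \linkS4class{GenotypeMatrix} serving as the LD reference.
#' @param p_thresh significance threshold (default 5e-8).
#' @param prune_r2 LD pruning threshold (default 0.2).
#' @return character vector of index variant ids (possibly empty).
#' @export
gwasIndexVariants <- function(gwas, geno, p_thresh = 5e-8, prune_r2 = 0.2) {
  sig <- gwas[!is.na(gwas$p) & gwas$p < p_thresh, , drop = FALSE]
  if (!nrow(sig)) return(character())
  sig <- sig[order(sig$p, sig$pos), , drop = FALSE]
  kept <- character()
  for (v in sig$variant_id) {
    r2 <- vapply(kept, function(k) ldR2(geno, v, k), numeric(1))
    if (!length(kept) || all(is.na(r2) | r2 < prune_r2)) kept <- c(kept, v)
  }
  kept
}

#' Conditional colocalization of QTL and GWAS signals
#'
#' Each (GWAS index, QTL index) pair in LD r-squared above \code{pair_r2} is
#' assessed by refitting the QTL model for the phenotype with the GWAS index
#' variant's dosage added as a covariate.  The pair is called colocalized
#' when the QTL index variant's conditional p is at least \code{cond_alpha}
#' (the association is no longer significant once the GWAS signal is
#' conditioned out).  Identical variants give a collinear design and are
#' called colocalized with a \code{collinear} flag; a non-identical but
#' perfectly collinear design is flagged collinear with no p.
#'
#' @param qtl_index data.frame: phenotype_id, variant_id (QTL index variants
#'   of significant phenotypes).
#' @param gwas_index character vector of GWAS index variant ids.
#' @param geno a \linkS4class{GenotypeMatrix} (LD reference).
#' @param refit function(phenotype_id, qtl_variant, condition_variant)
#'   returning the conditional nominal p of the QTL variant (NA on singular
#'   design); see \code{\link{edQTLRefitter}}.
#' @param pair_r2 LD pairing threshold (default 0.8).
#' @param cond_alpha conditional significance threshold (default 0.05).
#' @return data.frame of calls: gwas_index, phenotype_id, qtl_index, r2,
#'   p_conditional, verdict, collinear.
#' @export
conditionalColocalization <- function(qtl_index, gwas_index, geno, refit,
                                      pair_r2 = 0.8, cond_alpha = 0.05) {
  calls <- list()
  for (g in gwas_index) {
    for (i in seq_len(nrow(qtl_index))) {
      q <- qtl_index$variant_id[i]
      ph <- qtl_index$phenotype_id[i]
      r2 <- if (identical(q, g)) 1 else ldR2(geno, q, g)
      if (is.na(r2) || r2 <= pair_r2) next
      if (identical(q, g)) {
        calls[[length(calls) + 1L]] <- data.frame(
          gwas_index = g, phenotype_id = ph, qtl_index = q, r2 = 1,
          p_conditional = NA_real_, verdict = "colocalized",
          collinear = TRUE, stringsAsFactors = FALSE)
        next
      }
      p <- refit(ph, q, g)
      if (is.na(p)) {
        verdict <- "collinear"; coll <- TRUE
      } else {
        verdict <- if (p >= cond_alpha) "colocalized" else "not_colocalized"
        coll <- FALSE
      }
      calls[[length(calls) + 1L]] <- data.frame(
        gwas_index = g, phenotype_id = ph, qtl_index = q, r2 = r2,
        p_conditional = p, verdict = verdict, collinear = coll,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(gwas_index = character(), phenotype_id = character(),
                      qtl_index = character(), r2 = numeric(),
                      p_conditional = numeric(), verdict = character(),
                      collinear = logical(), stringsAsFactors = FALSE))
  do.call(rbind, calls)
}

#' Refit closure for conditional edQTL colocalization
#'
#' Builds the \code{refit} function consumed by
#' \code{\link{conditionalColocalization}}: a binomial edQTL refit of the
#' phenotype on its QTL index variant with the conditioning variant's dosage
#' appended to the covariates.  Returns NA when the two dosage vectors are
#' perfectly collinear.
#'
#' @param edex an \linkS4class{EditingExperiment}.
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param covariates donors x q covariate matrix (rownames = donor ids) or
#'   NULL.
#' @return function(phenotype_id, qtl_variant, condition_variant) -> p.
#' @export
edQTLRefitter <- function(edex, geno, covariates = NULL) {
  ed <- editedCounts(edex); tt <- totalCounts(edex)
  dose <- dosageMatrix(geno)
  donors <- intersect(colnames(edex), colnames(geno))
  function(phenotype_id, qtl_variant, condition_variant) {
    g <- dose[qtl_variant, donors]
    gc_ <- dose[condition_variant, donors]
    if (sd(g) == 0 || sd(gc_) == 0) return(NA_real_)
    if (abs(cor(g, gc_)) > 1 - 1e-10) return(NA_real_)
    cv <- cbind(if (!is.null(covariates)) covariates[donors, , drop = FALSE],
                cond = gc_)
    fit <- fitBinomialEdQTL(ed[phenotype_id, donors], tt[phenotype_id, donors],
                            g, cv)
    fit$p
  }
}

#' Mediation model comparison for a variant-mediator-expression triplet
#'
#' Fits three Gaussian regression systems relating variant dosage (X), a
#' post-transcriptional mediator (M: edit rate or PAU) and gene expression
#' (Y): forward (X -> M -> Y: M ~ X and Y ~ M), independent (X -> M and
#' X -> Y, M excluded from Y), and reactive (X -> Y -> M: Y ~ X and M ~ Y).
#' All variables are first residualized on the covariates.  Each system is
#' scored by the BIC of its joint likelihood; normalized
#' \code{exp(-deltaBIC / 2)} weights are reported as approximate posterior
#' model probabilities.
#'
#' @param dosage,mediator,expression numeric vectors over donors.
#' @param covariates donors x q matrix or NULL.
#' @return list: weights (named, sum to 1), bic (named), n; NULL components
#'   replaced by NA when the mediator or outcome has zero variance.
#' @export
mediationTriplet <- function(dosage, mediator, expression,
                             covariates = NULL) {
  ok <- complete.cases(dosage, mediator, expression)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & complete.cases(covariates)
  }
  if (sum(ok) < 30) stop("fewer than 30 complete cases")
  x <- dosage[ok]; m <- mediator[ok]; y <- expression[ok]
  if (sd(m) == 0 || sd(y) == 0)
    return(list(weights = setNames(rep(NA_real_, 3),
                                   c("forward", "independent", "reactive")),
                bic = NULL, n = sum(ok)))
  if (!is.null(covariates)) {
    C <- covariates[ok, , drop = FALSE]
    x <- lm(x ~ C)$residuals
    m <- lm(m ~ C)$residuals
    y <- lm(y ~ C)$residuals
  }
  bic2 <- function(f1, f2) stats::BIC(f1) + stats::BIC(f2)
  bic <- c(forward = bic2(lm(m ~ x), lm(y ~ m)),
           independent = bic2(lm(m ~ x), lm(y ~ x)),
           reactive = bic2(lm(y ~ x), lm(m ~ y)))
  w <- exp(-(bic - min(bic)) / 2)
  list(weights = w / sum(w), bic = bic, n = sum(ok))
}

#' Distances of primary QTL variants to gene landmarks
#'
#' Signed strand-aware distances to the transcription start site (TSS) and
#' termination site (TTS) -- upstream of the landmark is negative -- and the
#' unsigned shortest distance to any annotated intron boundary (splice
#' site).  Genes without introns yield a missing splice distance.
#'
#' @param variants data.frame: variant_id, gene_id, pos.
#' @param genes data.frame: gene_id, start, end, strand ("+" or "-").
#' @param introns data.frame: gene_id, intron_start, intron_end (or NULL).
#' @return data.frame: variant_id, gene_id, dist_tss, dist_tts, dist_splice.
#' @export
distanceProfiles <- function(variants, genes, introns = NULL) {
  gm <- genes[match(variants$gene_id, genes$gene_id), ]
  fwd <- gm$strand == "+"
  tss <- ifelse(fwd, gm$start, gm$end)
  tts <- ifelse(fwd, gm$end, gm$start)
  sign_ <- ifelse(fwd, 1, -1)
  out <- data.frame(variant_id = variants$variant_id,
                    gene_id = variants$gene_id,
                    dist_tss = sign_ * (variants$pos - tss),
                    dist_tts = sign_ * (variants$pos - tts),
                    dist_splice = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(introns) && nrow(introns)) {
    for (i in seq_len(nrow(out))) {
      b <- introns[introns$gene_id == out$gene_id[i], ]
      if (nrow(b)) {
        bounds <- c(b$intron_start, b$intron_end)
        out$dist_splice[i] <- min(abs(variants$pos[i] - bounds))
      }
    }
  }
  out
}
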