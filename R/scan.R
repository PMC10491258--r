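#' Assemble donor-level covariates for a QTL scan
#'
#' Binds genotype MDS axes (population structure), an optional batch factor
#' (one-hot, reference level dropped) and phenotype principal components
#' into one donors x q matrix, keeping only full-rank columns after
#' intercept augmentation.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param pheno phenotypes x donors matrix used for the PCs (or NULL).
#' @param n_mds genotype MDS axes (default 3).
#' @param n_pcs phenotype PCs (default 0).
#' @param batch named factor/character vector of batch labels per donor, or
#'   NULL.
#' @return donors x q numeric matrix (0 columns allowed).
#' @export
buildCovariates <- function(geno, pheno = NULL, n_mds = 3, n_pcs = 0,
                            batch = NULL) {
  donors <- colnames(geno)
  parts <- list()
  if (n_mds > 0) parts$mds <- genotypeMDS(geno, k = n_mds)[donors, ,
                                                           drop = FALSE]
  if (!is.null(batch)) {
    b <- factor(batch[donors])
    if (nlevels(b) > 1) {
      mm <- stats::model.matrix(~b)[, -1, drop = FALSE]
      colnames(mm) <- paste0("batch", levels(b)[-1])
      rownames(mm) <- donors
      parts$batch <- mm
    }
  }
  if (!is.null(pheno) && n_pcs > 0)
    parts$pcs <- phenotypePCs(pheno[, donors, drop = FALSE], n_pcs)
  if (!length(parts))
    return(matrix(numeric(0), length(donors), 0,
                  dimnames = list(donors, NULL)))
  X <- do.call(cbind, parts)
  qr_ <- qr(cbind(1, X))
  keep <- qr_$pivot[seq_len(qr_$rank)] - 1L
  keep <- keep[keep > 0]
  X[, sort(keep), drop = FALSE]
}

#' Map cis edQTLs with a binomial GLM and eigenMT-FDR correction
#'
#' For every discovered edit site: candidate variants are the cis window
#' (default +/-100 kb, same gene), restricted to the site's supporting
#' donors and to variants passing the genotype-class filter; each pair is
#' tested with \code{\link{fitBinomialEdQTL}}; the per-site minimum p is
#' locally adjusted by \code{\link{eigenMTMeff}} and phenotypes are
#' corrected globally with \code{\link{hierarchicalFDR}}; primary variants
#' are chosen per significant site.
#'
#' @param edex an \linkS4class{EditingExperiment}, ideally after
#'   \code{\link{discoverEditSites}} (otherwise every donor with coverage
#'   supports every site).
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param window cis half-window in bp (default 100000).
#' @param same_gene restrict variants to the site's gene span (default
#'   TRUE).
#' @param n_geno_mds genotype MDS covariates (default 3).
#' @param n_pheno_pcs global-editing PCs (default 1).
#' @param batch optional named batch labels per donor.
#' @param covariates optional pre-built donors x q covariate matrix
#'   (overrides the MDS/PC/batch assembly).
#' @param alpha global FDR level (default 0.05).
#' @param robust sandwich-variance Wald tests (default FALSE).
#' @return list: associations (all tested pairs), phenotypes (per-site
#'   p_min, m_eff, p_local, q_global, significant), primary (one row per
#'   significant site), covariates, params.
#' @export
mapEdQTL <- function(edex, geno, window = 1e5, same_gene = TRUE,
                     n_geno_mds = 3, n_pheno_pcs = 1, batch = NULL,
                     covariates = NULL, alpha = 0.05, robust = FALSE) {
  stopifnot(is(edex, "EditingExperiment"), is(geno, "GenotypeMatrix"))
  donors <- intersect(colnames(edex), colnames(geno))
  rates <- editRates(edex)
  if (is.null(covariates))
    covariates <- buildCovariates(geno, pheno = rates, n_mds = n_geno_mds,
                                  n_pcs = n_pheno_pcs, batch = batch)
  si <- siteInfo(edex)
  anchors <- data.frame(phenotype_id = si$site_id, chrom = si$chrom,
                        pos = si$pos, gene_start = si$gene_start,
                        gene_end = si$gene_end, stringsAsFactors = FALSE)
  pairs <- cisPairs(anchors, geno, window = window, same_gene = same_gene)
  support <- S4Vectors::metadata(edex)$support
  ed <- editedCounts(edex); tt <- totalCounts(edex)
  dose <- dosageMatrix(geno)
  vi <- variantInfo(geno)
  assoc <- list(); recs <- list()
  for (ph in unique(pairs$phenotype_id)) {
    dsub <- if (!is.null(support) && ph %in% names(support))
      intersect(support[[ph]], donors) else donors
    pv <- pairs[pairs$phenotype_id == ph, , drop = FALSE]
    keep <- filterVariantsByGenotypeClass(geno, dsub, pv$variant_id)
    pv <- pv[keep, , drop = FALSE]
    if (!nrow(pv)) next
    fits <- lapply(pv$variant_id, function(v)
      fitBinomialEdQTL(ed[ph, dsub], tt[ph, dsub], dose[v, dsub],
                       covariates[dsub, , drop = FALSE], robust = robust))
    df <- data.frame(phenotype_id = ph, variant_id = pv$variant_id,
                     chrom = vi$chrom[match(pv$variant_id, vi$variant_id)],
                     pos = vi$pos[match(pv$variant_id, vi$variant_id)],
                     distance = pv$distance,
                     beta = vapply(fits, `[[`, numeric(1), "beta"),
                     se = vapply(fits, `[[`, numeric(1), "se"),
                     p_nominal = vapply(fits, `[[`, numeric(1), "p"),
                     reason = vapply(fits, `[[`, character(1), "reason"),
                     stringsAsFactors = FALSE)
    assoc[[ph]] <- df
    pmin_ <- suppressWarnings(min(df$p_nominal, na.rm = TRUE))
    if (is.finite(pmin_)) {
      meff <- eigenMTMeff(dose[df$variant_id[!is.na(df$p_nominal)], dsub,
                               drop = FALSE])
      recs[[ph]] <- data.frame(phenotype_id = ph, p_min = pmin_,
                               m_eff = meff, n_variants = nrow(df),
                               n_donors = length(dsub),
                               stringsAsFactors = FALSE)
    }
  }
  associations <- do.call(rbind, c(assoc, list(make.row.names = FALSE)))
  phenotypes <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  primary <- NULL
  if (!is.null(phenotypes) && nrow(phenotypes)) {
    phenotypes <- hierarchicalFDR(phenotypes, alpha = alpha)
    sig <- phenotypes$phenotype_id[phenotypes$significant]
    if (length(sig)) {
      primary <- selectPrimary(
        associations[associations$phenotype_id %in% sig &
                       !is.na(associations$p_nominal), , drop = FALSE])
      associations$is_primary <- paste(associations$phenotype_id,
                                       associations$variant_id) %in%
        paste(primary$phenotype_id, primary$variant_id)
    } else associations$is_primary <- FALSE
  }
  list(associations = associations, phenotypes = phenotypes,
       primary = primary, covariates = covariates,
       params = list(window = window, same_gene = same_gene, alpha = alpha,
                     n_geno_mds = n_geno_mds, n_pheno_pcs = n_pheno_pcs,
                     robust = robust))
}

#' Map cis apaQTLs with a kinship-aware linear mixed model
#'
#' For every QTL-eligible normalized PAU phenotype: candidate variants lie
#' within \code{window} bp of either 3'UTR end; variants pass the
#' genotype-class filter; each is tested with the EMMAX-style LMM
#' (\code{\link{fitLmmApaQTL}} internals) using an IBS kinship matrix,
#' leave-one-chromosome-out when \code{loco}.  Hierarchical eigenMT-FDR and
#' primary selection as in \code{\link{mapEdQTL}}.
#'
#' @param apex an \linkS4class{APAExperiment} after \code{\link{computePAU}},
#'   \code{\link{filterIsoforms}}, \code{\link{normalizePAU}}.
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param window cis half-window in bp (default 25000).
#' @param loco leave-one-chromosome-out kinship (default TRUE).
#' @param kinship optional precomputed kinship (disables LOCO).
#' @param n_geno_mds,n_pheno_pcs,batch,covariates,alpha as in
#'   \code{\link{mapEdQTL}} (default 2 phenotype PCs).
#' @return list as in \code{\link{mapEdQTL}}, with per-phenotype variance
#'   components added to \code{phenotypes}.
#' @export
mapApaQTL <- function(apex, geno, window = 25000, loco = TRUE,
                      kinship = NULL, n_geno_mds = 3, n_pheno_pcs = 2,
                      batch = NULL, covariates = NULL, alpha = 0.05) {
  stopifnot(is(apex, "APAExperiment"),
            "npau" %in% SummarizedExperiment::assayNames(apex))
  donors <- intersect(colnames(apex), colnames(geno))
  npau <- SummarizedExperiment::assay(apex, "npau")
  rd <- SummarizedExperiment::rowData(apex)
  eligible <- if ("qtl_eligible" %in% colnames(rd)) rd$qtl_eligible else
    rep(TRUE, nrow(apex))
  if (is.null(covariates))
    covariates <- buildCovariates(geno, pheno = npau, n_mds = n_geno_mds,
                                  n_pcs = n_pheno_pcs, batch = batch)
  ii <- isoformInfo(apex)
  anchors <- data.frame(phenotype_id = ii$isoform_id, chrom = ii$chrom,
                        start = ii$utr_start, end = ii$utr_end,
                        stringsAsFactors = FALSE)
  anchors <- anchors[eligible, , drop = FALSE]
  pairs <- cisPairs(anchors, geno, window = window, same_gene = FALSE)
  if (is.null(kinship) && !loco) kinship <- computeIBSKinship(geno)
  kin_by_chrom <- list()
  dose <- dosageMatrix(geno)
  vi <- variantInfo(geno)
  assoc <- list(); recs <- list()
  for (ph in unique(pairs$phenotype_id)) {
    y <- npau[ph, donors]
    dsub <- donors[!is.na(y)]
    pv <- pairs[pairs$phenotype_id == ph, , drop = FALSE]
    keep <- filterVariantsByGenotypeClass(geno, dsub, pv$variant_id)
    pv <- pv[keep, , drop = FALSE]
    if (!nrow(pv)) next
    chrom <- ii$chrom[match(ph, ii$isoform_id)]
    if (is.null(kinship)) {
      if (is.null(kin_by_chrom[[chrom]]))
        kin_by_chrom[[chrom]] <- computeIBSKinship(geno, loco_chrom = chrom)
      K <- kin_by_chrom[[chrom]]
    } else K <- kinship
    X0 <- cbind(`(Intercept)` = rep(1, length(dsub)),
                covariates[dsub, , drop = FALSE])
    null <- .lmmNull(y[dsub], X0, K[dsub, dsub])
    fits <- lapply(pv$variant_id, function(v)
      .lmmTest(null, X0, dose[v, dsub]))
    df <- data.frame(phenotype_id = ph, variant_id = pv$variant_id,
                     chrom = vi$chrom[match(pv$variant_id, vi$variant_id)],
                     pos = vi$pos[match(pv$variant_id, vi$variant_id)],
                     distance = pv$distance,
                     beta = vapply(fits, `[[`, numeric(1), "beta"),
                     se = vapply(fits, `[[`, numeric(1), "se"),
                     p_nominal = vapply(fits, `[[`, numeric(1), "p"),
                     reason = vapply(fits, `[[`, character(1), "reason"),
                     stringsAsFactors = FALSE)
    assoc[[ph]] <- df
    pmin_ <- suppressWarnings(min(df$p_nominal, na.rm = TRUE))
    if (is.finite(pmin_)) {
      meff <- eigenMTMeff(dose[df$variant_id[!is.na(df$p_nominal)], dsub,
                               drop = FALSE])
      recs[[ph]] <- data.frame(phenotype_id = ph, p_min = pmin_,
                               m_eff = meff, n_variants = nrow(df),
                               n_donors = length(dsub),
                               sigma_u2 = null$sigma_u2,
                               sigma_e2 = null$sigma_e2,
                               at_boundary = null$at_boundary,
                               stringsAsFactors = FALSE)
    }
  }
  associations <- do.call(rbind, c(assoc, list(make.row.names = FALSE)))
  phenotypes <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  primary <- NULL
  if (!is.null(phenotypes) && nrow(phenotypes)) {
    phenotypes <- hierarchicalFDR(phenotypes, alpha = alpha)
    sig <- phenotypes$phenotype_id[phenotypes$significant]
    if (length(sig)) {
      primary <- selectPrimary(
        associations[associations$phenotype_id %in% sig &
                       !is.na(associations$p_nominal), , drop = FALSE])
      associations$is_primary <- paste(associations$phenotype_id,
                                       associations$variant_id) %in%
        paste(primary$phenotype_id, primary$variant_id)
    } else associations$is_primary <- FALSE
  }
  list(associations = associations, phenotypes = phenotypes,
       primary = primary, covariates = covariates,
       params = list(window = window, loco = loco, alpha = alpha,
                     n_geno_mds = n_geno_mds, n_pheno_pcs = n_pheno_pcs))
}
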