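#' Simulation configuration
#'
#' Holds every parameter of the synthetic-data generator.  Defaults encode the
#' study conditions the package is calibrated under: ~80 donors, mean read
#' coverage 50 at edit sites, MAF >= 0.01, LD blocks of 10 variants, a
#' logit-scale cis effect of 1 at 10 percent of edit sites.
#'
#' @slot n_donors number of donors.
#' @slot n_variants number of biallelic variants.
#' @slot ld_block_size variants per LD block (1 = independent variants).
#' @slot ld_rho adjacent-variant haplotype correlation within a block.
#' @slot maf_range numeric(2), minor-allele-frequency range in (0, 0.5].
#' @slot n_edit_sites number of candidate edit sites.
#' @slot frac_edit_qtl fraction of edit sites with a cis genetic effect.
#' @slot beta_edit logit-scale effect per minor allele at causal sites.
#' @slot mean_coverage mean read coverage per site per donor.
#' @slot overdispersion_rho beta-binomial intraclass correlation in [0, 1);
#'   0 reduces exactly to binomial sampling.
#' @slot global_factor_sd logit-scale SD of the global-editing latent factor.
#' @slot batch_effect_sd logit-scale SD of the batch (FACS sorter) effect.
#' @slot n_apa_genes number of genes with 3'UTR isoforms.
#' @slot isoforms_per_gene integer(2) range of isoforms per gene.
#' @slot beta_apa logistic-scale effect on the target isoform's log-odds.
#' @slot frac_apa_qtl fraction of genes with an APA genetic effect.
#' @slot apa_mean_depth mean gene-level 3'UTR read depth per donor.
#' @slot apa_noise_sd logistic-normal donor noise SD for isoform usage.
#' @slot frac_related_pairs fraction of donor pairs sharing a haplotype.
#' @slot gwas_scenario one of "shared", "distinct", "null".
#' @slot n_gwas_donors GWAS sample size (independent donor draw).
#' @slot gwas_beta per-allele effect on the simulated GWAS trait.
#' @slot seed integer root seed; fixed seed implies identical outputs.
#' @export
setClass("SimConfig", representation(
  n_donors = "integer", n_variants = "integer", ld_block_size = "integer",
  ld_rho = "numeric", maf_range = "numeric", n_edit_sites = "integer",
  frac_edit_qtl = "numeric", beta_edit = "numeric", mean_coverage = "numeric",
  overdispersion_rho = "numeric", global_factor_sd = "numeric",
  batch_effect_sd = "numeric", n_apa_genes = "integer",
  isoforms_per_gene = "integer", beta_apa = "numeric", frac_apa_qtl = "numeric",
  apa_mean_depth = "numeric", apa_noise_sd = "numeric",
  frac_related_pairs = "numeric", gwas_scenario = "character",
  n_gwas_donors = "integer", gwas_beta = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@n_donors < 4L) msg <- c(msg, "n_donors must be >= 4")
  if (object@n_variants < 1L) msg <- c(msg, "n_variants must be >= 1")
  if (object@ld_block_size < 1L) msg <- c(msg, "ld_block_size must be >= 1")
  if (length(object@maf_range) != 2L || any(object@maf_range <= 0) ||
      any(object@maf_range > 0.5) || diff(object@maf_range) < 0)
    msg <- c(msg, "maf_range must be increasing within (0, 0.5]")
  fr <- c(object@frac_edit_qtl, object@frac_apa_qtl, object@frac_related_pairs)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (object@overdispersion_rho < 0 || object@overdispersion_rho >= 1)
    msg <- c(msg, "overdispersion_rho must lie in [0, 1)")
  if (!object@gwas_scenario %in% c("shared", "distinct", "null"))
    msg <- c(msg, "gwas_scenario must be shared, distinct or null")
  if (object@ld_rho < 0 || object@ld_rho >= 1)
    msg <- c(msg, "ld_rho must lie in [0, 1)")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @rdname SimConfig-class
#' @param n_donors,n_variants,ld_block_size,ld_rho,maf_range See slots.
#' @param n_edit_sites,frac_edit_qtl,beta_edit,mean_coverage See slots.
#' @param overdispersion_rho,global_factor_sd,batch_effect_sd See slots.
#' @param n_apa_genes,isoforms_per_gene,beta_apa,frac_apa_qtl See slots.
#' @param apa_mean_depth,apa_noise_sd,frac_related_pairs See slots.
#' @param gwas_scenario,n_gwas_donors,gwas_beta,seed See slots.
#' @return A validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(n_donors = 80, n_variants = 400, ld_block_size = 10,
                      ld_rho = 0.85, maf_range = c(0.05, 0.5),
                      n_edit_sites = 200, frac_edit_qtl = 0.1, beta_edit = 1.0,
                      mean_coverage = 50, overdispersion_rho = 0,
                      global_factor_sd = 0.5, batch_effect_sd = 0.25,
                      n_apa_genes = 100, isoforms_per_gene = c(2, 4),
                      beta_apa = 1.0, frac_apa_qtl = frac_edit_qtl,
                      apa_mean_depth = 200, apa_noise_sd = 0.5,
                      frac_related_pairs = 0, gwas_scenario = "null",
                      n_gwas_donors = 2000, gwas_beta = 0.4, seed = 1) {
  new("SimConfig",
      n_donors = as.integer(n_donors), n_variants = as.integer(n_variants),
      ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
      maf_range = as.numeric(maf_range),
      n_edit_sites = as.integer(n_edit_sites), frac_edit_qtl = frac_edit_qtl,
      beta_edit = beta_edit, mean_coverage = mean_coverage,
      overdispersion_rho = overdispersion_rho,
      global_factor_sd = global_factor_sd, batch_effect_sd = batch_effect_sd,
      n_apa_genes = as.integer(n_apa_genes),
      isoforms_per_gene = as.integer(isoforms_per_gene), beta_apa = beta_apa,
      frac_apa_qtl = frac_apa_qtl, apa_mean_depth = apa_mean_depth,
      apa_noise_sd = apa_noise_sd, frac_related_pairs = frac_related_pairs,
      gwas_scenario = gwas_scenario, n_gwas_donors = as.integer(n_gwas_donors),
      gwas_beta = gwas_beta, seed = as.integer(seed))
}

# Haplotypes are drawn from a first-order Markov chain along each LD block:
# exact Bernoulli(maf) marginals per site, correlation ld_rho between adjacent
# sites within a block, independence across blocks.  Gives hard {0,1} alleles
# and geometric LD decay.
.simHaplotypes <- function(n_hap, freq, block, rho) {
  V <- length(freq)
  H <- matrix(0L, n_hap, V)
  for (v in seq_len(V)) {
    if (v == 1L || block[v] != block[v - 1L]) {
      H[, v] <- rbinom(n_hap, 1L, freq[v])
    } else {
      fp <- freq[v - 1L]; fv <- freq[v]
      p <- fv + rho * sqrt(fv * (1 - fv) / (fp * (1 - fp))) * (H[, v - 1L] - fp)
      H[, v] <- rbinom(n_hap, 1L, pmin(pmax(p, 0), 1))
    }
  }
  H
}

#' Simulate LD-structured donor genotypes
#'
#' Variants are laid out on two chromosomes at 2 kb spacing and grouped into
#' consecutive LD blocks.  Donor haplotypes follow a Markov haplotype model
#' (see \code{\link{simConfig}}); relatedness is induced by duplicating one
#' haplotype between donor pairs, which elevates their IBS sharing.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A \linkS4class{GenotypeMatrix}; its metadata records the generative
#'   allele frequencies, block structure and related donor pairs, which
#'   \code{\link{simulateGWAS}} reuses to draw an independent cohort from the
#'   same haplotype pool.
#' @export
simulateGenotypes <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed + 11L)
  V <- config@n_variants; N <- config@n_donors
  chrom <- rep(c("chr1", "chr2"), c(ceiling(V / 2), floor(V / 2)))
  idx_in_chrom <- c(seq_len(sum(chrom == "chr1")),
                    seq_len(sum(chrom == "chr2")))
  pos <- idx_in_chrom * 2000L  # positions restart per chromosome
  block <- paste0(chrom, "_b", (idx_in_chrom - 1L) %/% config@ld_block_size)
  freq <- runif(V, config@maf_range[1], config@maf_range[2])
  H <- .simHaplotypes(2L * N, freq, block, config@ld_rho)
  related <- NULL
  n_rel <- floor(config@frac_related_pairs * N / 2)
  if (n_rel > 0) {
    # donors (1,2), (3,4), ... : second of each pair inherits the first's
    # maternal haplotype genome-wide
    a <- seq(1L, by = 2L, length.out = n_rel)
    H[2L * (a + 1L) - 1L, ] <- H[2L * a - 1L, ]
    related <- cbind(a, a + 1L)
  }
  dos <- t(H[seq(1L, 2L * N, 2L), , drop = FALSE] +
           H[seq(2L, 2L * N, 2L), , drop = FALSE])
  ref <- sample(c("A", "C", "G", "T"), V, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                character(1))
  vid <- sprintf("var%04d", seq_len(V))
  dimnames(dos) <- list(vid, sprintf("D%03d", seq_len(N)))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                               ref = ref, alt = unname(alt))
  names(gr) <- vid
  GenotypeMatrix(dos, gr,
                 metadata = list(sim = list(freq = freq, block = block,
                                            rho = config@ld_rho,
                                            related_pairs = related,
                                            config_seed = config@seed)))
}

.rbetabinom <- function(n, size, prob, rho) {
  if (rho <= 0) return(rbinom(n, size, prob))
  s <- (1 - rho) / rho
  p <- rbeta(n, pmax(prob * s, 1e-8), pmax((1 - prob) * s, 1e-8))
  rbinom(n, size, p)
}

#' Simulate an RNA-editing count dataset with planted cis effects
#'
#' Each edit site i in donor j edits at rate
#' \code{plogis(alpha_i + beta * g_ij + global_factor_sd * u_j + batch_j)}:
#' a site-level baseline, a per-minor-allele logit effect at causal sites, a
#' donor-level global-editing latent factor, and a two-level batch (FACS
#' sorter) effect.  Total coverage is negative binomial (size 5) around
#' \code{mean_coverage}; edited reads are binomial, or beta-binomial when
#' \code{overdispersion_rho > 0}.
#'
#' @param geno a \linkS4class{GenotypeMatrix} from
#'   \code{\link{simulateGenotypes}}.
#' @param config the same \linkS4class{SimConfig}.
#' @return list with elements \code{edex} (an
#'   \linkS4class{EditingExperiment}) and \code{truth} (causal
#'   site/variant/beta table, latent factor values, batch labels).
#' @export
simulateEditing <- function(geno, config) {
  stopifnot(is(geno, "GenotypeMatrix"), nrow(geno) > 0)
  set.seed(config@seed + 22L)
  N <- ncol(geno); S <- config@n_edit_sites
  vi <- variantInfo(geno)
  anchor <- sample(nrow(vi), S, replace = TRUE)
  spos <- pmax(vi$pos[anchor] + sample(-10000:10000, S, replace = TRUE), 1L)
  schrom <- vi$chrom[anchor]
  gene_start <- pmax(spos - 50000L, 1L)
  gene_end <- spos + 50000L
  sid <- sprintf("site%04d", seq_len(S))
  n_causal <- round(config@frac_edit_qtl * S)
  causal <- sort(sample(S, n_causal))
  if (n_causal > 0 && config@frac_edit_qtl > 0 && nrow(vi) == 0)
    stop("no variants available for causal cis assignment")
  beta <- numeric(S); beta[causal] <- config@beta_edit
  alpha <- rnorm(S, qlogis(0.15), 0.8)
  u <- rnorm(N)
  batch <- rep_len(c("batchA", "batchB"), N)
  beff <- setNames(rnorm(2, 0, config@batch_effect_sd),
                   c("batchA", "batchB"))
  G <- dosageMatrix(geno)[anchor, , drop = FALSE]
  eta <- alpha + beta * G +
    matrix(config@global_factor_sd * u + beff[batch], S, N, byrow = TRUE)
  p <- plogis(eta)
  total <- matrix(rnbinom(S * N, size = 5, mu = config@mean_coverage), S, N)
  edited <- matrix(.rbetabinom(S * N, as.vector(total), as.vector(p),
                               config@overdispersion_rho), S, N)
  dimnames(total) <- dimnames(edited) <- list(sid, colnames(geno))
  sites <- GenomicRanges::GRanges(schrom, IRanges::IRanges(spos, width = 1L),
                                  strand = "+",
                                  ref = "A", alt = "G",
                                  gene_id = sprintf("geneE%04d", seq_len(S)),
                                  gene_start = gene_start,
                                  gene_end = gene_end,
                                  region = NA_character_, alu = NA)
  names(sites) <- sid
  truth <- list(
    causal = data.frame(phenotype_id = sid[causal],
                        variant_id = vi$variant_id[anchor[causal]],
                        beta = beta[causal], stringsAsFactors = FALSE),
    anchor_variant = setNames(vi$variant_id[anchor], sid),
    latent = setNames(u, colnames(geno)),
    batch = setNames(batch, colnames(geno)))
  edex <- EditingExperiment(edited, total, sites,
                            metadata = list(batch = truth$batch))
  list(edex = edex, truth = truth)
}

#' Simulate a 3'UTR isoform count dataset with planted APA effects
#'
#' Per gene, isoform usage follows a logistic-normal model: baseline isoform
#' log-weights plus donor noise; at causal genes, the longest isoform's
#' log-odds shift by \code{beta_apa} per minor allele of a cis variant.
#' Gene-level depth is negative binomial around \code{apa_mean_depth} and
#' isoform counts are multinomial given that depth, so per-gene counts sum
#' exactly to the drawn depth.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param config the same \linkS4class{SimConfig}.
#' @return list with elements \code{apex} (an \linkS4class{APAExperiment})
#'   and \code{truth}.
#' @export
simulateAPA <- function(geno, config) {
  stopifnot(is(geno, "GenotypeMatrix"), nrow(geno) > 0)
  set.seed(config@seed + 33L)
  N <- ncol(geno); G <- config@n_apa_genes
  vi <- variantInfo(geno)
  anchor <- sample(nrow(vi), G, replace = TRUE)
  krange <- config@isoforms_per_gene[1]:config@isoforms_per_gene[2]
  k <- krange[sample.int(length(krange), G, replace = TRUE)]
  n_causal <- round(config@frac_apa_qtl * G)
  causal_gene <- sort(sample(G, n_causal))
  dose <- dosageMatrix(geno)
  rows <- list(); cnt <- list(); truth_rows <- list()
  for (g in seq_len(G)) {
    gid <- sprintf("geneA%04d", g)
    utr_start <- pmax(vi$pos[anchor[g]] + sample(-5000:5000, 1L), 1L)
    lens <- sort(sample(300:3000, k[g]))
    iso_id <- sprintf("%s.iso%d", gid, seq_len(k[g]))
    w <- rnorm(k[g], 0, 1)
    bet <- if (g %in% causal_gene) config@beta_apa else 0
    gdose <- dose[anchor[g], ]
    eta <- matrix(w, k[g], N) +
      matrix(rnorm(k[g] * N, 0, config@apa_noise_sd), k[g], N)
    eta[k[g], ] <- eta[k[g], ] + bet * gdose  # effect on longest isoform
    pr <- apply(eta, 2, function(e) exp(e - max(e)) / sum(exp(e - max(e))))
    pr <- matrix(pr, k[g], N)  # apply() drops dims for single-isoform genes
    depth <- rnbinom(N, size = 5, mu = config@apa_mean_depth)
    cmat <- vapply(seq_len(N),
                   function(j) rmultinom(1, depth[j], pr[, j])[, 1],
                   numeric(k[g]))
    cmat <- matrix(cmat, k[g], N, dimnames = list(iso_id, colnames(geno)))
    has_pas <- runif(k[g]) < 0.8
    rows[[g]] <- data.frame(
      isoform_id = iso_id, gene_id = gid, chrom = vi$chrom[anchor[g]],
      utr_start = utr_start, utr_end = utr_start + lens, strand = "+",
      utr_length = lens,
      pas_start = ifelse(has_pas, utr_start + lens - 30L, NA_integer_),
      pas_end = ifelse(has_pas, utr_start + lens - 25L, NA_integer_),
      stringsAsFactors = FALSE)
    cnt[[g]] <- cmat
    if (g %in% causal_gene)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        phenotype_id = iso_id[k[g]], gene_id = gid,
        variant_id = vi$variant_id[anchor[g]], beta = bet,
        stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, rows)
  counts <- do.call(rbind, cnt)
  gr <- GenomicRanges::GRanges(meta$chrom,
                               IRanges::IRanges(meta$utr_start, meta$utr_end),
                               strand = meta$strand,
                               gene_id = meta$gene_id,
                               utr_length = meta$utr_length,
                               pas_start = meta$pas_start,
                               pas_end = meta$pas_end)
  names(gr) <- meta$isoform_id
  truth <- list(causal = if (length(truth_rows)) do.call(rbind, truth_rows)
                         else data.frame(phenotype_id = character(),
                                         gene_id = character(),
                                         variant_id = character(),
                                         beta = numeric()),
                anchor_variant = setNames(vi$variant_id[anchor],
                                          sprintf("geneA%04d", seq_len(G))))
  list(apex = APAExperiment(counts, gr), truth = truth)
}

#' Simulate GWAS summary statistics on an independent cohort
#'
#' Draws \code{n_gwas_donors} new donors from the same haplotype pool as
#' \code{geno} (same allele frequencies, LD blocks and haplotype correlation),
#' simulates a quantitative trait, and returns marginal per-variant summary
#' statistics.  Scenarios: \code{"shared"} -- the GWAS causal variant is a QTL
#' causal variant; \code{"distinct"} -- the causal variant has r-squared < 0.2
#' with every QTL causal variant; \code{"null"} -- no causal variant, with
#' rejection sampling guaranteeing no p below 5e-8.
#'
#' @param geno a \linkS4class{GenotypeMatrix} from
#'   \code{\link{simulateGenotypes}}.
#' @param config the same \linkS4class{SimConfig}.
#' @param qtl_causal character vector of QTL causal variant ids (required for
#'   the shared and distinct scenarios).
#' @return list with \code{summary} (data.frame: variant_id, chrom, pos, a1,
#'   a2, beta, se, p) and \code{causal_variant} (id or NA).
#' @export
simulateGWAS <- function(geno, config, qtl_causal = NULL) {
  stopifnot(is(geno, "SummarizedExperiment") || is(geno, "GenotypeMatrix"))
  sim <- S4Vectors::metadata(geno)$sim
  if (is.null(sim)) stop("geno lacks simulation metadata; use simulateGenotypes")
  set.seed(config@seed + 44L)
  vi <- variantInfo(geno)
  scen <- config@gwas_scenario
  causal <- NA_character_
  if (scen %in% c("shared", "distinct")) {
    if (is.null(qtl_causal) || !length(qtl_causal))
      stop("qtl_causal is required for scenario '", scen, "'")
    if (scen == "shared") {
      qc <- intersect(qtl_causal, vi$variant_id)
      if (!length(qc)) stop("no QTL causal variant present in the genotypes")
      causal <- qc[which.max(vi$maf[match(qc, vi$variant_id)])]
    } else {
      dose <- dosageMatrix(geno)
      qc <- intersect(qtl_causal, rownames(dose))
      r2max <- apply(dose, 1, function(x) {
        if (sd(x) == 0) return(1)
        max(vapply(qc, function(q) {
          if (sd(dose[q, ]) == 0) return(1)
          cor(x, dose[q, ])^2
        }, numeric(1)))
      })
      ok <- which(r2max < 0.2 & vi$maf >= 0.1)
      if (!length(ok))
        stop("distinct scenario impossible: no variant with r2 < 0.2 to all ",
             "QTL causal variants (LD blocks too large?)")
      causal <- vi$variant_id[sample(ok, 1L)]
    }
  }
  n <- config@n_gwas_donors
  for (try in 1:50) {
    H <- .simHaplotypes(2L * n, sim$freq, sim$block, sim$rho)
    Gm <- H[seq(1L, 2L * n, 2L), , drop = FALSE] +
          H[seq(2L, 2L * n, 2L), , drop = FALSE]
    colnames(Gm) <- vi$variant_id
    y <- rnorm(n)
    if (!is.na(causal)) y <- y + config@gwas_beta * Gm[, causal]
    gc_ <- scale(Gm, scale = FALSE)
    yc <- y - mean(y)
    ssg <- colSums(gc_^2)
    ssg[ssg == 0] <- NA
    bhat <- colSums(gc_ * yc) / ssg
    rss <- sum(yc^2) - bhat^2 * ssg
    se <- sqrt(rss / (n - 2) / ssg)
    pv <- 2 * pt(-abs(bhat / se), df = n - 2)
    if (scen != "null" || all(pv >= 5e-8, na.rm = TRUE)) break
  }
  if (scen == "null" && any(pv < 5e-8, na.rm = TRUE))
    stop("failed to draw a null GWAS without genome-wide significant hits")
  list(summary = data.frame(variant_id = vi$variant_id, chrom = vi$chrom,
                            pos = vi$pos, a1 = vi$alt, a2 = vi$ref,
                            beta = unname(bhat), se = unname(se),
                            p = unname(pv), stringsAsFactors = FALSE),
       causal_variant = causal)
}

#' Simulate site and variant annotations
#'
#' Assigns each edit site a genomic region class, an Alu flag and its gene id,
#' and each variant an RNA secondary-structure category plus its distance to
#' the nearest edit site and MAF.  A stem-enrichment factor > 1 inflates the
#' probability that \code{causal_variants} fall in the "stem" category
#' (renormalized), planting a detectable enrichment.
#'
#' @param edex an \linkS4class{EditingExperiment}.
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param config a \linkS4class{SimConfig}.
#' @param stem_enrichment multiplicative stem-probability factor for causal
#'   variants (1 = no enrichment).
#' @param causal_variants character vector of causal variant ids.
#' @return list with \code{edex} (regions/alu filled in) and
#'   \code{variant_annot} (variant_id, structure, dist_to_site, maf).
#' @export
simulateAnnotations <- function(edex, geno, config, stem_enrichment = 1,
                                causal_variants = character()) {
  set.seed(config@seed + 55L)
  S <- nrow(edex)
  regions <- c("intron", "3UTR", "CDS", "5UTR", "noncoding")
  rprob <- c(0.50, 0.25, 0.10, 0.05, 0.10)
  rr <- SummarizedExperiment::rowRanges(edex)
  S4Vectors::mcols(rr)$region <- sample(regions, S, TRUE, rprob)
  S4Vectors::mcols(rr)$alu <- runif(S) < 0.75
  SummarizedExperiment::rowRanges(edex) <- rr
  cats <- c("stem", "hairpin loop", "interior loop", "bulge", "multiloop",
            "exterior")
  base <- c(0.20, 0.18, 0.18, 0.12, 0.12, 0.20)
  vgr <- SummarizedExperiment::rowRanges(geno)
  hits <- GenomicRanges::distanceToNearest(vgr, rr)
  dist <- rep(NA_integer_, length(vgr))
  dist[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  vid <- names(vgr)
  is_causal <- vid %in% causal_variants
  # stem probability scales by the factor directly (capped), the remaining
  # categories share the leftover mass, so the realized causal/baseline stem
  # ratio equals the factor
  pcaus <- base
  pcaus[1] <- min(stem_enrichment * base[1], 0.9)
  pcaus[-1] <- base[-1] * (1 - pcaus[1]) / (1 - base[1])
  struct <- character(length(vid))
  struct[!is_causal] <- sample(cats, sum(!is_causal), TRUE, base)
  if (any(is_causal))
    struct[is_causal] <- sample(cats, sum(is_causal), TRUE, pcaus)
  list(edex = edex,
       variant_annot = data.frame(variant_id = vid, structure = struct,
                                  dist_to_site = dist,
                                  maf = variantMAF(geno),
                                  stringsAsFactors = FALSE))
}
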