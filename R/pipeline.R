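#' Pipeline run configuration
#'
#' Bundles the settings of an end-to-end run.  Defaults reproduce the
#' package's standard analysis settings: +/-100 kb same-gene cis window for
#' editing, +/-25 kb dual-anchor window for APA, discovery thresholds 10
#' total / 2 edited reads in at least 85 percent of donors, genotype-class
#' filter, 3 genotype MDS covariates, global FDR 5 percent.
#'
#' @param sim a \linkS4class{SimConfig} describing the synthetic inputs.
#' @param cell_type free-text label (e.g. "progenitor", "neuron").
#' @param out_dir output directory, or NULL for no file output.
#' @param ed_window,apa_window cis half-windows in bp.
#' @param min_total,min_edited,min_donor_frac edit-site discovery
#'   thresholds.
#' @param apa_min_count,apa_min_donor_frac isoform filter thresholds.
#' @param n_geno_mds genotype MDS covariates.
#' @param ed_pc_grid,apa_pc_grid phenotype-PC candidate grids; a length-1
#'   grid skips the optimization scan.
#' @param use_batch include the simulated batch factor as a covariate.
#' @param alpha global FDR level.
#' @param loco leave-one-chromosome-out kinship for the APA LMM.
#' @return a validated run-configuration list (class \code{ptqtl_config}).
#' @export
runConfig <- function(sim = simConfig(), cell_type = "progenitor",
                      out_dir = NULL, ed_window = 1e5, apa_window = 25000,
                      min_total = 10, min_edited = 2, min_donor_frac = 0.85,
                      apa_min_count = 10, apa_min_donor_frac = 0.10,
                      n_geno_mds = 3, ed_pc_grid = 1, apa_pc_grid = 2,
                      use_batch = TRUE, alpha = 0.05, loco = TRUE) {
  stopifnot(is(sim, "SimConfig"), ed_window > 0, apa_window > 0,
            alpha > 0, alpha < 1)
  cfg <- list(sim = sim, cell_type = cell_type, out_dir = out_dir,
              ed_window = ed_window, apa_window = apa_window,
              min_total = min_total, min_edited = min_edited,
              min_donor_frac = min_donor_frac,
              apa_min_count = apa_min_count,
              apa_min_donor_frac = apa_min_donor_frac,
              n_geno_mds = n_geno_mds, ed_pc_grid = ed_pc_grid,
              apa_pc_grid = apa_pc_grid, use_batch = use_batch,
              alpha = alpha, loco = loco)
  class(cfg) <- "ptqtl_config"
  cfg
}

.configHash <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL  # where results land does not change what they are
  cfg$sim <- lapply(slotNames(config$sim),
                    function(s) methods::slot(config$sim, s))
  digest::digest(cfg)
}

.writeBundle <- function(bundle, config, stage_counts, out_dir, prefix) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- .configHash(config)
  wr <- function(df, name) {
    if (is.null(df)) return()
    path <- file.path(out_dir, paste0(prefix, "_", name, ".tsv"))
    con <- file(path, "w")
    writeLines(paste0("# config_hash=", h), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  wr(bundle$associations, "associations")
  wr(bundle$phenotypes, "phenotypes")
  wr(bundle$primary, "primary")
  manifest <- list(package_version = as.character(utils::packageVersion("ptQTL")),
                   config_hash = h, cell_type = config$cell_type,
                   seed = config$sim@seed, stage_counts = stage_counts,
                   params = bundle$params)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(prefix, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Run the end-to-end edQTL pipeline on synthetic data
#'
#' Simulates genotypes and edit counts from \code{config$sim}, then runs
#' discovery, covariate assembly (with optional phenotype-PC optimization),
#' the binomial GLM cis scan and hierarchical eigenMT-FDR correction, and
#' primary-variant selection.  Result tables plus a manifest (config hash,
#' seed, record counts at every filter stage) are written under
#' \code{config$out_dir} when set.
#'
#' @param config a \code{\link{runConfig}} list.
#' @return list: geno, edex, truth, scan (from \code{\link{mapEdQTL}}),
#'   chosen_pcs, stage_counts.
#' @export
runEdQTLPipeline <- function(config) {
  stopifnot(inherits(config, "ptqtl_config"))
  geno <- simulateGenotypes(config$sim)
  edsim <- simulateEditing(geno, config$sim)
  edex0 <- edsim$edex
  edex <- discoverEditSites(edex0, min_total = config$min_total,
                            min_edited = config$min_edited,
                            min_donor_frac = config$min_donor_frac)
  batch <- if (config$use_batch) S4Vectors::metadata(edex0)$batch else NULL
  run_k <- function(k) mapEdQTL(edex, geno, window = config$ed_window,
                                same_gene = TRUE,
                                n_geno_mds = config$n_geno_mds,
                                n_pheno_pcs = k, batch = batch,
                                alpha = config$alpha)
  if (length(config$ed_pc_grid) > 1) {
    opt <- optimizeCovariates(function(k) {
      s <- run_k(k)
      if (is.null(s$phenotypes)) 0 else sum(s$phenotypes$significant)
    }, config$ed_pc_grid)
    k <- opt$k
  } else k <- config$ed_pc_grid[1]
  scan <- run_k(k)
  stage_counts <- list(
    sites_simulated = nrow(edex0), sites_discovered = nrow(edex),
    pairs_tested = if (is.null(scan$associations)) 0L
                   else nrow(scan$associations),
    phenotypes_tested = if (is.null(scan$phenotypes)) 0L
                        else nrow(scan$phenotypes),
    phenotypes_significant = if (is.null(scan$phenotypes)) 0L
                             else sum(scan$phenotypes$significant))
  .writeBundle(scan, config, stage_counts, config$out_dir,
               paste0(config$cell_type, "_edqtl"))
  list(geno = geno, edex = edex, truth = edsim$truth, scan = scan,
       chosen_pcs = k, stage_counts = stage_counts)
}

#' Run the end-to-end apaQTL pipeline on synthetic data
#'
#' Simulates genotypes and isoform counts, computes and filters PAU,
#' normalizes phenotypes, then runs the kinship-aware LMM cis scan (LOCO
#' IBS kinship) with hierarchical eigenMT-FDR correction.
#'
#' @param config a \code{\link{runConfig}} list.
#' @return list: geno, apex, truth, scan (from \code{\link{mapApaQTL}}),
#'   chosen_pcs, stage_counts.
#' @export
runApaQTLPipeline <- function(config) {
  stopifnot(inherits(config, "ptqtl_config"))
  geno <- simulateGenotypes(config$sim)
  apasim <- simulateAPA(geno, config$sim)
  apex0 <- computePAU(apasim$apex)
  apex <- filterIsoforms(apex0, min_count = config$apa_min_count,
                         min_donor_frac = config$apa_min_donor_frac,
                         seed = config$sim@seed + 7L)
  apex <- normalizePAU(apex)
  run_k <- function(k) mapApaQTL(apex, geno, window = config$apa_window,
                                 loco = config$loco,
                                 n_geno_mds = config$n_geno_mds,
                                 n_pheno_pcs = k, alpha = config$alpha)
  if (length(config$apa_pc_grid) > 1) {
    opt <- optimizeCovariates(function(k) {
      s <- run_k(k)
      if (is.null(s$phenotypes)) 0 else sum(s$phenotypes$significant)
    }, config$apa_pc_grid)
    k <- opt$k
  } else k <- config$apa_pc_grid[1]
  scan <- run_k(k)
  stage_counts <- list(
    isoforms_simulated = nrow(apasim$apex),
    isoforms_after_filter = nrow(apex),
    pairs_tested = if (is.null(scan$associations)) 0L
                   else nrow(scan$associations),
    phenotypes_tested = if (is.null(scan$phenotypes)) 0L
                        else nrow(scan$phenotypes),
    phenotypes_significant = if (is.null(scan$phenotypes)) 0L
                             else sum(scan$phenotypes$significant))
  .writeBundle(scan, config, stage_counts, config$out_dir,
               paste0(config$cell_type, "_apaqtl"))
  list(geno = geno, apex = apex, truth = apasim$truth, scan = scan,
       chosen_pcs = k, stage_counts = stage_counts)
}

#' Validate input concordance before a QTL run
#'
#' Checks donor-id concordance between genotypes, phenotypes and
#' covariates (fatal on phenotype donors absent from the genotypes),
#' coordinate sanity (positive 1-based positions, non-empty intervals) and
#' per-donor missingness.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param phenotype an \linkS4class{EditingExperiment} or
#'   \linkS4class{APAExperiment}.
#' @param covariates optional donors x q matrix with donor rownames.
#' @return list report: donors_shared, warnings (character vector),
#'   missingness (per-donor fraction of missing phenotype values).
#' @export
validateInputs <- function(geno, phenotype, covariates = NULL) {
  warnings_ <- character()
  gd <- colnames(geno); pd <- colnames(phenotype)
  missing_donors <- setdiff(pd, gd)
  if (length(missing_donors))
    stop("phenotype donor(s) absent from genotypes: ",
         paste(missing_donors, collapse = ", "))
  if (!is.null(covariates)) {
    mc <- setdiff(pd, rownames(covariates))
    if (length(mc))
      stop("phenotype donor(s) absent from covariates: ",
           paste(mc, collapse = ", "))
  }
  if (any(GenomicRanges::start(SummarizedExperiment::rowRanges(geno)) < 1))
    warnings_ <- c(warnings_, "variant position < 1 (positions are 1-based)")
  rr <- SummarizedExperiment::rowRanges(phenotype)
  if (any(GenomicRanges::width(rr) < 1))
    warnings_ <- c(warnings_, "empty phenotype interval (start > end)")
  pm <- if (is(phenotype, "EditingExperiment")) editRates(phenotype)
        else SummarizedExperiment::assay(phenotype, 1)
  miss <- colMeans(is.na(pm))
  for (w in warnings_) warning(w)
  list(donors_shared = intersect(gd, pd), warnings = warnings_,
       missingness = miss)
}
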