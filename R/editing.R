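#' Per-site per-donor edit rates
#'
#' Edit rate = edited reads / total reads at the site in that donor; donors
#' with zero coverage get \code{NA}, never 0/0.
#'
#' @param x an \linkS4class{EditingExperiment}.
#' @return numeric matrix (sites x donors) with values in [0, 1] or NA.
#' @export
editRates <- function(x) {
  stopifnot(is(x, "EditingExperiment"))
  ed <- editedCounts(x)
  tt <- totalCounts(x)
  r <- ed / tt
  r[tt == 0] <- NA_real_
  r
}

#' Discover well-supported edit sites
#'
#' A donor supports a site when its coverage is at least \code{min_total}
#' reads with at least \code{min_edited} edited reads.  A site is retained
#' when the fraction of supporting donors is at least \code{min_donor_frac}
#' (boundaries inclusive).  The per-site supporting-donor sets are kept:
#' downstream QTL fits use exactly these donors, which can differ between
#' sites.
#'
#' @param x an \linkS4class{EditingExperiment}.
#' @param min_total minimum total reads per donor (default 10).
#' @param min_edited minimum edited reads per donor (default 2).
#' @param min_donor_frac minimum supporting-donor fraction (default 0.85).
#' @return The retained \linkS4class{EditingExperiment}; its metadata gains
#'   \code{support}, a named list of supporting-donor id vectors, and
#'   \code{discovery_params}.
#' @export
discoverEditSites <- function(x, min_total = 10, min_edited = 2,
                              min_donor_frac = 0.85) {
  stopifnot(is(x, "EditingExperiment"),
            min_total > 0, min_edited > 0, min_donor_frac > 0)
  if (nrow(x) == 0) return(x)
  ed <- editedCounts(x); tt <- totalCounts(x)
  supp <- tt >= min_total & ed >= min_edited
  frac <- rowMeans(supp)
  keep <- frac >= min_donor_frac
  out <- x[keep, ]
  sup_sets <- lapply(which(keep), function(i) colnames(x)[supp[i, ]])
  names(sup_sets) <- rownames(x)[keep]
  md <- S4Vectors::metadata(out)
  md$support <- sup_sets
  md$discovery_params <- list(min_total = min_total, min_edited = min_edited,
                              min_donor_frac = min_donor_frac)
  S4Vectors::metadata(out) <- md
  out
}

#' Validate edit sites against DNA-level allele counts
#'
#' Sites that are genuine RNA edits should show exclusively the unedited
#' (reference) allele in DNA-derived reads (e.g. ATAC-seq).  For each site
#' the unedited-allele fraction is pooled over donors; a site is
#' \code{"validated"} when that fraction reaches \code{min_fraction},
#' \code{"suspect_genomic"} when edited-allele DNA evidence is present, and
#' \code{"no_coverage"} when no DNA reads cover the site (excluded from the
#' validated-percentage denominator).
#'
#' @param dna data.frame with columns \code{site_id}, \code{ref_reads},
#'   \code{alt_reads} (pooled or per-donor rows; rows are summed per site).
#' @param site_ids character vector of sites to assess.
#' @param min_fraction validation threshold on the unedited fraction
#'   (default 1: no edited-allele read tolerated).
#' @param min_depth minimum pooled DNA depth to call a verdict (default 1).
#' @return data.frame: site_id, ref_reads, alt_reads, unedited_fraction,
#'   verdict; attribute \code{percent_validated} gives the percentage of
#'   covered sites validated.
#' @export
validateWithDNA <- function(dna, site_ids, min_fraction = 1, min_depth = 1) {
  agg <- stats::aggregate(cbind(ref_reads, alt_reads) ~ site_id, data = dna,
                          FUN = sum)
  m <- merge(data.frame(site_id = site_ids, stringsAsFactors = FALSE), agg,
             by = "site_id", all.x = TRUE)
  m$ref_reads[is.na(m$ref_reads)] <- 0
  m$alt_reads[is.na(m$alt_reads)] <- 0
  depth <- m$ref_reads + m$alt_reads
  m$unedited_fraction <- ifelse(depth > 0, m$ref_reads / depth, NA_real_)
  m$verdict <- ifelse(depth < min_depth, "no_coverage",
               ifelse(m$unedited_fraction >= min_fraction, "validated",
                      "suspect_genomic"))
  covered <- m$verdict != "no_coverage"
  attr(m, "percent_validated") <-
    if (any(covered)) 100 * mean(m$verdict[covered] == "validated") else NA_real_
  m
}

#' Alu editing index (AEI)
#'
#' Global per-sample editing summary: 100 times the pooled fraction of edited
#' (G) reads among all adenosine-position reads (A + G) across Alu regions.
#' Pooling is read-weighted, not region-averaged.
#'
#' @param aei data.frame with columns \code{sample}, \code{region},
#'   \code{a_reads} (unedited A) and \code{g_reads} (edited G).
#' @return named numeric vector of AEI percentages per sample; samples with
#'   zero pooled coverage get NA with a warning.
#' @export
computeAEI <- function(aei) {
  stopifnot(all(c("sample", "a_reads", "g_reads") %in% names(aei)),
            all(aei$a_reads >= 0), all(aei$g_reads >= 0))
  g <- tapply(aei$g_reads, aei$sample, sum)
  a <- tapply(aei$a_reads, aei$sample, sum)
  tot <- a + g
  if (any(tot == 0)) warning("sample(s) with zero Alu coverage: AEI is NA")
  out <- ifelse(tot > 0, 100 * g / tot, NA_real_)
  setNames(as.numeric(out), names(g))
}

#' Local sequence-motif enrichment around edit sites
#'
#' Computes per-position per-base log2 enrichment of the flanking sequence
#' composition over a background composition, with a pseudo-count of one
#' observation per cell.  Positions are labeled relative to the edited base
#' (0), e.g. the canonical A-to-I signature is G enrichment at -1 and G
#' depletion at +1.
#'
#' @param seqs character vector or \code{DNAStringSet} of equal-length
#'   sequences centered on the edit site (odd length).
#' @param background named base frequencies (A, C, G, T); defaults to the
#'   pooled composition of \code{seqs}.
#' @return matrix positions x bases of log2 enrichments.
#' @export
motifProfile <- function(seqs, background = NULL) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("all flanking sequences must have equal length")
  if (w %% 2L == 0L) stop("sequences must be centered (odd length)")
  bases <- c("A", "C", "G", "T")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  n <- nrow(mat)
  counts <- vapply(seq_len(w),
                   function(p) table(factor(mat[, p], levels = bases)),
                   numeric(4))
  counts <- t(counts)  # positions x bases
  if (is.null(background)) {
    bg <- colSums(counts) / sum(counts)
  } else {
    bg <- background[bases] / sum(background[bases])
  }
  freq <- (counts + 1) / (n + 4)
  enr <- log2(sweep(freq, 2, bg, "/"))
  rel <- seq_len(w) - (w + 1L) / 2L
  dimnames(enr) <- list(as.character(rel), bases)
  enr
}

#' Overlap enrichment of a site set in reference site sets
#'
#' For each reference set, builds the 2x2 table (query-and-ref, query-only,
#' ref-only, neither) over a stated universe and tests association by
#' two-sided Fisher's exact test (default) or chi-square, with
#' Benjamini-Hochberg adjustment across reference sets.
#'
#' @param query character vector of query site ids.
#' @param reference named list of reference site-id vectors.
#' @param universe total number of sites in the universe (must be at least
#'   the size of the union of query and each reference set).
#' @param method "fisher" or "chisq".
#' @return data.frame: set, overlap, query_only, ref_only, neither,
#'   odds_ratio, p, padj.
#' @export
overlapEnrichment <- function(query, reference, universe,
                              method = c("fisher", "chisq")) {
  method <- match.arg(method)
  stopifnot(is.list(reference), length(names(reference)) == length(reference))
  res <- lapply(names(reference), function(nm) {
    ref <- reference[[nm]]
    if (universe < length(union(query, ref)))
      stop("universe smaller than the union of query and reference set '",
           nm, "'")
    a <- length(intersect(query, ref))
    b <- length(setdiff(query, ref))
    cc <- length(setdiff(ref, query))
    d <- universe - a - b - cc
    if (length(query) == 0) {
      return(data.frame(set = nm, overlap = 0L, query_only = 0L,
                        ref_only = cc, neither = d, odds_ratio = 0,
                        p = 1, stringsAsFactors = FALSE))
    }
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    if (method == "fisher") {
      ft <- fisher.test(tab)
      or <- unname(ft$estimate); pv <- ft$p.value
    } else {
      or <- if (b * cc > 0) (a * d) / (b * cc) else Inf
      pv <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    }
    data.frame(set = nm, overlap = a, query_only = b, ref_only = cc,
               neither = d, odds_ratio = or, p = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- p.adjust(out$p, method = "BH")
  out
}
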