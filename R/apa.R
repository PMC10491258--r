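#' Poly(A) usage (PAU) per isoform
#'
#' PAU of a 3'UTR isoform in a donor is its count divided by the summed
#' counts of all isoforms of the same gene in that donor; missing (NA) when
#' the gene's total is zero.  Pre-filter PAU values sum to one per gene and
#' donor by construction.
#'
#' @param apex an \linkS4class{APAExperiment}.
#' @return the object with a \code{"pau"} assay added.
#' @export
computePAU <- function(apex) {
  stopifnot(is(apex, "APAExperiment"))
  cts <- isoformCounts(apex)
  gene <- SummarizedExperiment::rowData(apex)$gene_id
  totals <- rowsum(cts, gene)[gene, , drop = FALSE]
  pau <- cts / totals
  pau[totals == 0] <- NA_real_
  SummarizedExperiment::assay(apex, "pau") <- pau
  apex
}

#' Filter lowly expressed and complementary 3'UTR isoforms
#'
#' Keeps isoforms supported by at least \code{min_count} reads in at least
#' \code{min_donor_frac} of donors (raw counts).  For genes left with exactly
#' two isoforms the two PAU values are complementary, so exactly one is kept,
#' chosen uniformly at random under \code{seed}; the dropped twin is recorded
#' in the metadata (\code{dropped_twin}).  Post-filter PAU values are never
#' renormalized.
#'
#' @param apex an \linkS4class{APAExperiment} (after
#'   \code{\link{computePAU}}).
#' @param min_count minimum read count (default 10).
#' @param min_donor_frac minimum fraction of donors (default 0.10).
#' @param seed integer seed for the two-isoform choice.
#' @return the filtered \linkS4class{APAExperiment}.
#' @export
filterIsoforms <- function(apex, min_count = 10, min_donor_frac = 0.10,
                           seed) {
  stopifnot(is(apex, "APAExperiment"), !missing(seed))
  cts <- isoformCounts(apex)
  keep <- rowMeans(cts >= min_count) >= min_donor_frac
  out <- apex[keep, ]
  gene <- SummarizedExperiment::rowData(out)$gene_id
  tab <- table(gene)
  two <- names(tab)[tab == 2L]
  dropped <- data.frame(gene_id = character(), kept = character(),
                        dropped = character(), stringsAsFactors = FALSE)
  if (length(two)) {
    set.seed(seed)
    drop_ids <- character()
    for (g in two) {
      ids <- rownames(out)[gene == g]
      pick <- sample(2L, 1L)
      drop_ids <- c(drop_ids, ids[-pick])
      dropped <- rbind(dropped,
                       data.frame(gene_id = g, kept = ids[pick],
                                  dropped = ids[-pick],
                                  stringsAsFactors = FALSE))
    }
    out <- out[!rownames(out) %in% drop_ids, ]
  }
  md <- S4Vectors::metadata(out)
  md$dropped_twin <- dropped
  md$filter_params <- list(min_count = min_count,
                           min_donor_frac = min_donor_frac, seed = seed)
  S4Vectors::metadata(out) <- md
  out
}

.inverseNormal <- function(v) {
  ok <- !is.na(v)
  n <- sum(ok)
  out <- rep(NA_real_, length(v))
  if (n == 0) return(out)
  if (sd(v[ok]) == 0) {
    out[ok] <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  r <- rank(v[ok], ties.method = "average")
  out[ok] <- qnorm((r - 0.5) / n)
  out
}

#' Normalize PAU phenotypes for QTL mapping
#'
#' Default is a per-isoform rank-based inverse-normal transform across donors
#' (ties get average ranks, missing values are excluded), yielding
#' approximately standard-normal phenotypes as assumed by the Gaussian mixed
#' model.  \code{method = "quantile"} instead maps every donor's PAU
#' distribution onto their common average distribution (across-sample
#' quantile normalization).  Isoforms with fewer than \code{min_donors}
#' non-missing values, or constant values, are flagged ineligible for QTL
#' testing (\code{rowData()$qtl_eligible}).
#'
#' @param apex an \linkS4class{APAExperiment} with a \code{"pau"} assay.
#' @param method "inverse_normal" (default) or "quantile".
#' @param min_donors minimum non-missing donors per isoform (default 10).
#' @return the object with an \code{"npau"} assay and eligibility flags.
#' @export
normalizePAU <- function(apex, method = c("inverse_normal", "quantile"),
                         min_donors = 10) {
  method <- match.arg(method)
  stopifnot("pau" %in% SummarizedExperiment::assayNames(apex))
  pau <- SummarizedExperiment::assay(apex, "pau")
  if (method == "inverse_normal") {
    npau <- t(apply(pau, 1, .inverseNormal))
  } else {
    ranks <- apply(pau, 2, rank, ties.method = "min", na.last = "keep")
    sorted <- apply(pau, 2, sort, na.last = TRUE)
    target <- rowMeans(sorted, na.rm = TRUE)
    npau <- apply(ranks, 2, function(r) target[r])
  }
  dimnames(npau) <- dimnames(pau)
  nonmiss <- rowSums(!is.na(pau))
  constant <- apply(pau, 1, function(v) {
    v <- v[!is.na(v)]; length(v) > 0 && sd(v) == 0
  })
  eligible <- nonmiss >= min_donors & !constant
  SummarizedExperiment::assay(apex, "npau") <- npau
  rd <- SummarizedExperiment::rowData(apex)
  rd$qtl_eligible <- eligible
  rd$degenerate_phenotype <- constant
  SummarizedExperiment::rowData(apex) <- rd
  apex
}

#' Classify 3'UTR lengthening vs shortening
#'
#' Given per-isoform signed change calls ("up", "down", "none") within each
#' gene: \code{lengthening} when the gene's longest isoform is up,
#' \code{shortening} when the shortest is up, \code{ambiguous} when both are
#' up, \code{internal} when only a middle isoform is up, and \code{NA} when
#' no isoform is up.
#'
#' @param gene_id,utr_length,change parallel vectors over isoforms.
#' @return data.frame: gene_id, label.
#' @export
classifyUTRChange <- function(gene_id, utr_length, change) {
  stopifnot(length(gene_id) == length(utr_length),
            length(gene_id) == length(change),
            all(change %in% c("up", "down", "none")))
  res <- lapply(split(seq_along(gene_id), gene_id), function(idx) {
    len <- utr_length[idx]; chg <- change[idx]
    up <- chg == "up"
    if (!any(up)) return(NA_character_)
    longest_up <- any(up & len == max(len))
    shortest_up <- any(up & len == min(len))
    if (longest_up && shortest_up) "ambiguous"
    else if (longest_up) "lengthening"
    else if (shortest_up) "shortening"
    else "internal"
  })
  data.frame(gene_id = names(res), label = unlist(res),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Canonical polyadenylation-signal hexamers (DNA alphabet)
#' @return character vector of the 12 canonical PAS hexamers.
#' @export
canonicalPASMotifs <- function() {
  c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AATACA", "CATAAA",
    "AATATA", "GATAAA", "AATGAA", "AATAGA", "ACTAAA", "AAGAAA")
}

#' Flag variants disrupting polyadenylation signal motifs
#'
#' A variant is flagged when its affected interval (position through
#' position + nchar(ref) - 1, so indels are intervals, not points)
#' intersects an annotated PAS hexamer interval.  When the hexamer sequence
#' context is provided, the ref- and alt-allele versions of the hexamer are
#' checked against the canonical motif set to call whether the alternate
#' allele destroys, restores or leaves the motif.
#'
#' @param variants data.frame: variant_id, chrom, pos (1-based), ref, alt.
#' @param pas data.frame: isoform_id, chrom, pas_start, pas_end (1-based
#'   inclusive) and optionally \code{pas_seq}, the hexamer carrying the
#'   reference allele.
#' @param motifs motif set (DNA alphabet); default the 12 canonical hexamers.
#' @return data.frame of variant x PAS hits: variant_id, isoform_id, motif
#'   (RNA alphabet), and when sequence is available \code{allele_effect} in
#'   \{"destroys", "restores", "neutral"\}.  Variants with no hit are
#'   returned with \code{pas_hit = FALSE}.
#' @export
pasDisruption <- function(variants, pas, motifs = canonicalPASMotifs()) {
  pas <- pas[!is.na(pas$pas_start) & !is.na(pas$pas_end), , drop = FALSE]
  vgr <- GenomicRanges::GRanges(
    variants$chrom,
    IRanges::IRanges(variants$pos,
                     variants$pos + pmax(nchar(variants$ref), 1L) - 1L))
  pgr <- GenomicRanges::GRanges(pas$chrom,
                                IRanges::IRanges(pas$pas_start, pas$pas_end))
  ov <- GenomicRanges::findOverlaps(vgr, pgr)
  hit <- rep(FALSE, nrow(variants))
  hit[S4Vectors::queryHits(ov)] <- TRUE
  out <- data.frame(variant_id = variants$variant_id, pas_hit = hit,
                    isoform_id = NA_character_, motif = NA_character_,
                    allele_effect = NA_character_, stringsAsFactors = FALSE)
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    out$isoform_id[qh] <- pas$isoform_id[sh]
    seqs <- if ("pas_seq" %in% names(pas)) toupper(pas$pas_seq[sh]) else
      rep(NA_character_, length(sh))
    for (k in seq_along(qh)) {
      i <- qh[k]; j <- sh[k]
      refseq <- seqs[k]
      motif <- NA_character_; eff <- NA_character_
      if (!is.na(refseq)) {
        off <- variants$pos[i] - pas$pas_start[j] + 1L
        altseq <- refseq
        if (off >= 1 && off <= nchar(refseq) &&
            nchar(variants$ref[i]) == 1L && nchar(variants$alt[i]) == 1L)
          substr(altseq, off, off) <- toupper(variants$alt[i])
        ref_in <- refseq %in% motifs
        alt_in <- altseq %in% motifs
        eff <- if (ref_in && !alt_in) "destroys"
               else if (!ref_in && alt_in) "restores" else "neutral"
        motif <- if (ref_in) refseq else if (alt_in) altseq else NA_character_
      }
      out$motif[i] <- if (!is.na(motif)) chartr("T", "U", motif) else motif
      out$allele_effect[i] <- eff
    }
  }
  out
}
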