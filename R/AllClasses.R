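#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData rowRanges
#' @importFrom S4Vectors metadata mcols
#' @importFrom BiocGenerics strand
#' @importFrom stats anova aov as.dist binomial chisq.test cmdscale coef
#'   complete.cases cor fisher.test glm glm.control lm lm.wfit logLik optimize
#'   p.adjust pchisq plogis pnorm predict pt qlogis qnorm quantile rbeta rbinom
#'   rmultinom rnbinom rnorm runif sd setNames smooth.spline var
#' @importFrom utils head read.delim write.table
NULL

#' Donor genotype dosage matrix
#'
#' A \linkS4class{RangedSummarizedExperiment} holding a variants x donors
#' dosage matrix (assay \code{"dosage"}, values in \{0,1,2\} or [0,2] for
#' imputed data) with variant coordinates as \code{rowRanges}.  The row
#' metadata carries \code{ref}, \code{alt} and \code{maf} columns.
#'
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

#' Per-site per-donor edited/total read counts
#'
#' A \linkS4class{RangedSummarizedExperiment} with assays \code{"edited"} and
#' \code{"total"} (sites x donors, non-negative integers, edited <= total).
#' \code{rowRanges} hold the edit-site coordinates with metadata columns
#' \code{ref}, \code{alt}, \code{gene_id}, \code{gene_start}, \code{gene_end},
#' \code{region} and \code{alu}.
#'
#' @export
setClass("EditingExperiment", contains = "RangedSummarizedExperiment")

#' Per-isoform per-donor 3'UTR expression counts
#'
#' A \linkS4class{RangedSummarizedExperiment} with assay \code{"counts"}
#' (3'UTR isoforms x donors).  \code{rowRanges} span each isoform's 3'UTR;
#' row metadata carries \code{gene_id}, \code{utr_length} and optionally a
#' PAS-motif interval (\code{pas_start}, \code{pas_end}).  After
#' \code{\link{computePAU}} / \code{\link{normalizePAU}} the object gains
#' \code{"pau"} and \code{"npau"} assays.
#'
#' @export
setClass("APAExperiment", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  if (any(d < 0 | d > 2, na.rm = TRUE))
    return("dosages must lie in [0, 2]")
  need <- c("ref", "alt", "maf")
  if (!all(need %in% colnames(SummarizedExperiment::rowData(object))))
    return("rowData must contain ref, alt, maf")
  if (anyDuplicated(rownames(object)))
    return("variant ids must be unique")
  TRUE
})

setValidity("EditingExperiment", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("edited", "total") %in% an))
    return("assays 'edited' and 'total' are required")
  ed <- SummarizedExperiment::assay(object, "edited")
  tt <- SummarizedExperiment::assay(object, "total")
  if (any(ed < 0, na.rm = TRUE) || any(tt < 0, na.rm = TRUE))
    return("counts must be non-negative")
  if (any(ed > tt, na.rm = TRUE))
    return("edited counts cannot exceed total counts")
  if (anyDuplicated(rownames(object)))
    return("site ids must be unique")
  TRUE
})

setValidity("APAExperiment", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  if (any(SummarizedExperiment::assay(object, "counts") < 0, na.rm = TRUE))
    return("counts must be non-negative")
  if (!"gene_id" %in% colnames(SummarizedExperiment::rowData(object)))
    return("rowData must contain gene_id")
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix, variants x donors, values in [0, 2].
#' @param variants \code{GRanges} of variant positions (1-based), one per row
#'   of \code{dosage}, with metadata columns \code{ref} and \code{alt}.
#' @param metadata optional list stored in the object metadata.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(dosage, variants, metadata = list()) {
  stopifnot(nrow(dosage) == length(variants))
  if (is.null(rownames(dosage))) rownames(dosage) <- names(variants)
  if (is.null(names(variants))) names(variants) <- rownames(dosage)
  f <- rowMeans(dosage, na.rm = TRUE) / 2
  S4Vectors::mcols(variants)$maf <- pmin(f, 1 - f)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowRanges = variants,
    metadata = metadata)
  new("GenotypeMatrix", se)
}

#' Construct an EditingExperiment
#'
#' @param edited,total integer matrices, sites x donors.
#' @param sites \code{GRanges} of edit-site positions with metadata columns
#'   \code{ref}, \code{alt}, \code{gene_id}, \code{gene_start},
#'   \code{gene_end}; optionally \code{region} and \code{alu}.
#' @param metadata optional list.
#' @return An \linkS4class{EditingExperiment}.
#' @export
EditingExperiment <- function(edited, total, sites, metadata = list()) {
  stopifnot(all(dim(edited) == dim(total)), nrow(edited) == length(sites))
  if (is.null(rownames(edited))) rownames(edited) <- names(sites)
  dimnames(total) <- dimnames(edited)
  if (is.null(names(sites))) names(sites) <- rownames(edited)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(edited = edited, total = total), rowRanges = sites,
    metadata = metadata)
  new("EditingExperiment", se)
}

#' Construct an APAExperiment
#'
#' @param counts numeric matrix, isoforms x donors.
#' @param isoforms \code{GRanges} spanning each isoform's 3'UTR with metadata
#'   columns \code{gene_id} and \code{utr_length}.
#' @param metadata optional list.
#' @return An \linkS4class{APAExperiment}.
#' @export
APAExperiment <- function(counts, isoforms, metadata = list()) {
  stopifnot(nrow(counts) == length(isoforms))
  if (is.null(rownames(counts))) rownames(counts) <- names(isoforms)
  if (is.null(names(isoforms))) names(isoforms) <- rownames(counts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowRanges = isoforms,
    metadata = metadata)
  new("APAExperiment", se)
}

# ---- accessors --------------------------------------------------------------

#' @describeIn GenotypeMatrix variants x donors dosage matrix.
#' @param x a GenotypeMatrix.
#' @export
dosageMatrix <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn GenotypeMatrix per-variant minor allele frequency.
#' @export
variantMAF <- function(x) SummarizedExperiment::rowData(x)$maf

#' Variant table of a GenotypeMatrix
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return data.frame with variant_id, chrom, pos, ref, alt, maf.
#' @export
variantInfo <- function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(variant_id = names(rr),
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = S4Vectors::mcols(rr)$ref,
             alt = S4Vectors::mcols(rr)$alt,
             maf = S4Vectors::mcols(rr)$maf,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @describeIn EditingExperiment edited-read count matrix.
#' @param x an EditingExperiment.
#' @export
editedCounts <- function(x) SummarizedExperiment::assay(x, "edited")

#' @describeIn EditingExperiment total-read count matrix.
#' @export
totalCounts <- function(x) SummarizedExperiment::assay(x, "total")

#' Site table of an EditingExperiment
#'
#' @param x an \linkS4class{EditingExperiment}.
#' @return data.frame keyed by site_id with coordinates and annotations.
#' @export
siteInfo <- function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  out <- data.frame(site_id = names(rr),
                    chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = GenomicRanges::start(rr),
                    strand = as.character(BiocGenerics::strand(rr)),
                    row.names = NULL, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(S4Vectors::mcols(rr)))
}

#' @describeIn APAExperiment isoform count matrix.
#' @param x an APAExperiment.
#' @export
isoformCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' Isoform table of an APAExperiment
#'
#' @param x an \linkS4class{APAExperiment}.
#' @return data.frame keyed by isoform_id with 3'UTR coordinates and gene ids.
#' @export
isoformInfo <- function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  out <- data.frame(isoform_id = names(rr),
                    chrom = as.character(GenomicRanges::seqnames(rr)),
                    utr_start = GenomicRanges::start(rr),
                    utr_end = GenomicRanges::end(rr),
                    strand = as.character(BiocGenerics::strand(rr)),
                    row.names = NULL, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(S4Vectors::mcols(rr)))
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object), "variants x", ncol(object), "donors\n")
  maf <- variantMAF(object)
  cat(sprintf("  MAF range: %.3f - %.3f\n", min(maf), max(maf)))
  callNextMethod()
})

setMethod("show", "EditingExperiment", function(object) {
  cat("EditingExperiment:", nrow(object), "edit sites x", ncol(object),
      "donors\n")
  callNextMethod()
})

setMethod("show", "APAExperiment", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat("APAExperiment:", nrow(object), "3'UTR isoforms in",
      length(unique(rd$gene_id)), "genes x", ncol(object), "donors\n")
  callNextMethod()
})
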