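# I/O layer.  Conventions centralized here: variants and edit sites are
# 1-based (VCF convention); interval files are written 0-based half-open
# (BED convention) via rtracklayer.

#' Write/read donor dosages as TSV
#'
#' Wide layout: variant_id, chrom, pos, ref, alt, then one column per donor.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param path output file.
#' @export
writeDosageTSV <- function(geno, path) {
  vi <- variantInfo(geno)
  out <- cbind(vi[, c("variant_id", "chrom", "pos", "ref", "alt")],
               as.data.frame(dosageMatrix(geno)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDosageTSV
#' @return \code{readDosageTSV}: a \linkS4class{GenotypeMatrix}.
#' @export
readDosageTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  meta <- c("variant_id", "chrom", "pos", "ref", "alt")
  dos <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(dos) <- df$variant_id
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1L),
                               ref = df$ref, alt = df$alt)
  names(gr) <- df$variant_id
  GenotypeMatrix(dos, gr)
}

#' Write/read edit counts as long TSV
#'
#' One row per site x donor: site_id, chrom, pos, ref, alt, strand, gene_id,
#' gene_start, gene_end, region, alu, donor, edited, total.
#'
#' @param edex an \linkS4class{EditingExperiment}.
#' @param path output file.
#' @export
writeEditCountsTSV <- function(edex, path) {
  si <- siteInfo(edex)
  ed <- editedCounts(edex); tt <- totalCounts(edex)
  long <- do.call(rbind, lapply(colnames(edex), function(d)
    cbind(si, donor = d, edited = ed[, d], total = tt[, d])))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEditCountsTSV
#' @return \code{readEditCountsTSV}: an \linkS4class{EditingExperiment}.
#' @export
readEditCountsTSV <- function(path) {
  df <- read.delim(path)
  sites <- unique(df[, setdiff(names(df), c("donor", "edited", "total"))])
  donors <- unique(df$donor)
  ed <- matrix(NA_integer_, nrow(sites), length(donors),
               dimnames = list(sites$site_id, donors))
  tt <- ed
  idx <- cbind(match(df$site_id, sites$site_id), match(df$donor, donors))
  ed[idx] <- df$edited
  tt[idx] <- df$total
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, width = 1L),
                               strand = sites$strand,
                               ref = sites$ref, alt = sites$alt,
                               gene_id = sites$gene_id,
                               gene_start = sites$gene_start,
                               gene_end = sites$gene_end,
                               region = sites$region, alu = sites$alu)
  names(gr) <- sites$site_id
  EditingExperiment(ed, tt, gr)
}

#' Write/read 3'UTR isoform counts as TSV
#'
#' Long layout: isoform_id, gene_id, chrom, utr_start, utr_end, strand,
#' utr_length, pas_start, pas_end, donor, count.
#'
#' @param apex an \linkS4class{APAExperiment}.
#' @param path output file.
#' @export
writeIsoformCountsTSV <- function(apex, path) {
  ii <- isoformInfo(apex)
  cts <- isoformCounts(apex)
  long <- do.call(rbind, lapply(colnames(apex), function(d)
    cbind(ii, donor = d, count = cts[, d])))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeIsoformCountsTSV
#' @return \code{readIsoformCountsTSV}: an \linkS4class{APAExperiment}.
#' @export
readIsoformCountsTSV <- function(path) {
  df <- read.delim(path)
  iso <- unique(df[, setdiff(names(df), c("donor", "count"))])
  donors <- unique(df$donor)
  cts <- matrix(NA_real_, nrow(iso), length(donors),
                dimnames = list(iso$isoform_id, donors))
  cts[cbind(match(df$isoform_id, iso$isoform_id),
            match(df$donor, donors))] <- df$count
  gr <- GenomicRanges::GRanges(iso$chrom,
                               IRanges::IRanges(iso$utr_start, iso$utr_end),
                               strand = iso$strand, gene_id = iso$gene_id,
                               utr_length = iso$utr_length,
                               pas_start = iso$pas_start,
                               pas_end = iso$pas_end)
  names(gr) <- iso$isoform_id
  APAExperiment(cts, gr)
}

#' Write edit sites as BED (0-based half-open)
#'
#' @param edex an \linkS4class{EditingExperiment}.
#' @param path output .bed file.
#' @export
writeSitesBED <- function(edex, path) {
  gr <- SummarizedExperiment::rowRanges(edex)
  export_gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                      IRanges::ranges(gr),
                                      strand = BiocGenerics::strand(gr))
  names(export_gr) <- names(gr)
  rtracklayer::export(export_gr, path, format = "BED")
  invisible(path)
}

#' Write/read GWAS summary statistics as TSV
#'
#' Columns: variant_id, chrom, pos, a1 (effect allele), a2, beta, se, p.
#'
#' @param gwas data.frame in the stated layout.
#' @param path file path.
#' @export
writeGWASTSV <- function(gwas, path) {
  write.table(gwas[, c("variant_id", "chrom", "pos", "a1", "a2",
                       "beta", "se", "p")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGWASTSV
#' @export
readGWASTSV <- function(path) read.delim(path)

#' Write genotypes as VCF (GT field)
#'
#' Hardened dosages are written as diploid genotypes (0/0, 0/1, 1/1).
#' Requires the VariantAnnotation package.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param path output .vcf file.
#' @export
writeGenotypeVCF <- function(geno, path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required to write VCF")
  vi <- variantInfo(geno)
  d <- round(dosageMatrix(geno))
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow(d), ncol(d),
               dimnames = dimnames(d))
  rr <- GenomicRanges::GRanges(vi$chrom, IRanges::IRanges(vi$pos, width = 1L))
  names(rr) <- vi$variant_id
  hdr <- VariantAnnotation::VCFHeader(
    samples = colnames(d),
    header = IRanges::DataFrameList(
      fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                        row.names = "fileformat"),
      FORMAT = S4Vectors::DataFrame(Number = "1", Type = "String",
                                    Description = "Genotype",
                                    row.names = "GT")))
  vcf <- VariantAnnotation::VCF(
    rowRanges = rr,
    colData = S4Vectors::DataFrame(Samples = seq_len(ncol(d)),
                                   row.names = colnames(d)),
    exptData = list(header = hdr),
    fixed = S4Vectors::DataFrame(
      REF = Biostrings::DNAStringSet(vi$ref),
      ALT = Biostrings::DNAStringSetList(as.list(vi$alt)),
      QUAL = rep(NA_real_, nrow(d)),
      FILTER = rep("PASS", nrow(d))),
    geno = S4Vectors::SimpleList(GT = gt))
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Read genotypes from a VCF into a GenotypeMatrix
#'
#' Multi-allelic records are skipped (with a message) or split into
#' biallelic records depending on \code{multiallelic}.
#'
#' @param path .vcf file.
#' @param multiallelic "skip" (default) or "split".
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypeVCF <- function(path, multiallelic = c("skip", "split")) {
  multiallelic <- match.arg(multiallelic)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required to read VCF")
  vcf <- VariantAnnotation::readVcf(path)
  nalt <- lengths(VariantAnnotation::alt(vcf))
  if (any(nalt > 1)) {
    if (multiallelic == "skip") {
      message("skipping ", sum(nalt > 1), " multi-allelic record(s)")
      vcf <- vcf[nalt == 1]
    } else {
      vcf <- VariantAnnotation::expand(vcf)
    }
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  count1 <- function(s) lengths(regmatches(s, gregexpr("1", s)))
  dos <- matrix(count1(gt), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  rr <- SummarizedExperiment::rowRanges(vcf)
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(rr),
                               IRanges::ranges(rr),
                               ref = as.character(VariantAnnotation::ref(vcf)),
                               alt = as.character(unlist(
                                 VariantAnnotation::alt(vcf))))
  names(gr) <- rownames(vcf)
  GenotypeMatrix(dos, gr)
}

#' Write simulation ground truth as JSON
#'
#' @param truth ground-truth list from the simulators.
#' @param path output .json file.
#' @export
writeGroundTruthJSON <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
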