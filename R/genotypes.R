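#' Genotype matrix
#'
#' Container for diploid biallelic SNP genotypes: an n x m matrix of
#' minor-allele dosages (0, 1, 2 or \code{NA} for missing) together with the
#' sample minor-allele frequencies.  Construction enforces minor-allele
#' orientation: markers whose coded allele has frequency above 0.5 are
#' flipped (dosage 2 - g), and markers with zero minor-allele count are
#' dropped, since the emission model requires frequencies strictly inside
#' (0, 1).
#'
#' @param geno Integer matrix, individuals in rows, markers in columns;
#'   dimnames supply individual and marker ids (generated when absent).
#' @param bp Optional per-marker base-pair positions (kept aligned through
#'   marker drops).
#' @param chrom Optional chromosome label.
#' @return An object of class \code{"genotype_matrix"}: list with elements
#'   \code{geno}, \code{f} (minor-allele frequencies), \code{bp},
#'   \code{chrom}, \code{flipped} (markers whose orientation was reversed),
#'   \code{kept} (column indices of the input that survived filtering).
#' @export
genotype_matrix <- function(geno, bp = NULL, chrom = "1") {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (!all(geno %in% c(0L, 1L, 2L, NA)))
    stop("genotypes must be dosages 0, 1, 2 or NA")
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("ind%04d", seq_len(nrow(geno)))
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("m%05d", seq_len(ncol(geno)))
  nonmiss <- colSums(!is.na(geno))
  if (any(nonmiss == 0)) {
    drop <- nonmiss == 0
    message(sum(drop), " all-missing markers dropped")
    geno <- geno[, !drop, drop = FALSE]
    if (!is.null(bp)) bp <- bp[!drop]
    nonmiss <- nonmiss[!drop]
  }
  f <- colSums(geno, na.rm = TRUE) / (2 * nonmiss)
  flipped <- f > 0.5
  if (any(flipped)) {
    geno[, flipped] <- 2L - geno[, flipped]
    f[flipped] <- 1 - f[flipped]
  }
  mono <- f == 0
  kept <- unname(which(!mono))
  if (any(mono)) {
    message(sum(mono), " monomorphic markers dropped")
    geno <- geno[, !mono, drop = FALSE]
    f <- f[!mono]
    flipped <- flipped[!mono]
    if (!is.null(bp)) bp <- bp[!mono]
  }
  if (ncol(geno) == 0) stop("zero usable markers after filtering")
  structure(list(geno = geno, f = unname(f), bp = bp, chrom = chrom,
                 flipped = unname(flipped), kept = kept),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers\n",
              nrow(x$geno), ncol(x$geno)))
  cat(sprintf("  missing: %.2f%%; mean minor-allele frequency: %.3f\n",
              100 * mean(is.na(x$geno)), mean(x$f)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Read genotypes from VCF or PLINK-style transposed text
#'
#' VCF input keeps biallelic SNP records only; multi-allelic and non-SNP
#' records are skipped with a logged count.  The transposed-text format has
#' one marker per row: columns \code{chrom}, \code{id}, \code{bp}, then one
#' dosage per individual (\code{NA} for missing), with a header row naming
#' the individuals.
#'
#' @param path Input file.
#' @param format "vcf" or "tped" (guessed from the file extension when
#'   missing).
#' @return A \code{\link{genotype_matrix}}.
#' @export
load_genotypes <- function(path, format = c("auto", "vcf", "tped")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tped"
  if (format == "vcf") .load_vcf(path) else .load_tped(path)
}

.load_vcf <- function(path) {
  if (requireNamespace("VariantAnnotation", quietly = TRUE))
    return(.load_vcf_va(path))
  .load_vcf_text(path)
}

.load_vcf_va <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  snp <- lengths(altl) == 1
  alt <- rep(NA_character_, length(ref))
  alt[snp] <- as.character(unlist(altl[snp]))
  keep <- snp & nchar(ref) == 1 & !is.na(alt) & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!keep))
    message(sum(!keep), " non-SNP or multi-allelic records skipped")
  if (!any(keep)) stop("zero usable markers in ", path)
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  dose <- function(a) ifelse(a == ".", NA_integer_, as.integer(a != "0"))
  g <- dose(substr(gt, 1, 1)) + dose(substr(gt, 3, 3))
  geno <- t(matrix(g, nrow = nrow(gt),
                   dimnames = list(names(rr)[keep], colnames(gt))))
  genotype_matrix(geno, bp = BiocGenerics::start(rr)[keep],
                  chrom = as.character(GenomeInfoDb::seqnames(rr))[keep][1])
}

.load_vcf_text <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  if (!length(body) || !startsWith(body[1], "#CHROM"))
    stop("not a VCF file (no #CHROM header line): ", path)
  hdr <- strsplit(sub("^#", "", body[1]), "\t")[[1]]
  ids <- hdr[-(1:9)]
  if (length(body) < 2) stop("zero usable markers in ", path)
  rows <- strsplit(body[-1], "\t")
  nfield <- lengths(rows)
  bad <- which(nfield != length(hdr))
  if (length(bad))
    stop("unparseable VCF record at line ",
         which(lines == body[bad[1] + 1L]), " of ", path)
  rec <- do.call(rbind, rows)
  ref <- rec[, 4]; alt <- rec[, 5]
  snp <- nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!snp))
    message(sum(!snp), " non-SNP or multi-allelic records skipped")
  rec <- rec[snp, , drop = FALSE]
  if (nrow(rec) == 0) stop("zero usable markers in ", path)
  gt <- rec[, -(1:9), drop = FALSE]
  gt <- sub(":.*", "", gt)
  allele1 <- substr(gt, 1, 1)
  allele2 <- substr(gt, 3, 3)
  dose <- function(a) ifelse(a == ".", NA_integer_,
                             as.integer(a != "0"))
  g <- dose(allele1) + dose(allele2)
  geno <- t(matrix(g, nrow = nrow(rec),
                   dimnames = list(rec[, 3], ids)))
  genotype_matrix(geno, bp = as.integer(rec[, 2]), chrom = rec[1, 1])
}

.load_tped <- function(path) {
  tab <- data.table::fread(path, header = TRUE, na.strings = "NA")
  if (ncol(tab) < 4) stop("transposed genotype file needs >= 4 columns")
  ids <- names(tab)[-(1:3)]
  geno <- t(as.matrix(tab[, -(1:3)]))
  rownames(geno) <- ids
  colnames(geno) <- as.character(tab[[2]])
  genotype_matrix(geno, bp = as.integer(tab[[3]]),
                  chrom = as.character(tab[[1]][1]))
}

#' Write genotypes as PLINK-style transposed text
#'
#' @param genotypes A \code{\link{genotype_matrix}}.
#' @param path Output file.
#' @export
write_genotypes_tped <- function(genotypes, path) {
  g <- genotypes$geno
  bp <- genotypes$bp
  if (is.null(bp)) bp <- seq_len(ncol(g))
  out <- data.table::data.table(chrom = genotypes$chrom,
                                id = colnames(g), bp = bp)
  out <- cbind(out, data.table::as.data.table(t(g)))
  data.table::setnames(out, c("chrom", "id", "bp", rownames(g)))
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Write genotypes (optionally phased) as VCF
#'
#' Minor alleles are written as ALT.  Unphased genotypes use \code{/};
#' phased calls use \code{|}; uncalled alleles use \code{.}.
#'
#' @param genotypes A \code{\link{genotype_matrix}}.
#' @param path Output file.
#' @param h1,h2 Optional n x m haplotype allele matrices (1 = minor,
#'   0 = major, NA = uncalled); when given, cells where both alleles are
#'   called are written phased.
#' @param phased Optional n x m logical matrix marking cells to emit with
#'   the phased separator (defaults to cells with both haplotype alleles
#'   called).
#' @export
write_phased_vcf <- function(genotypes, path, h1 = NULL, h2 = NULL,
                             phased = NULL) {
  g <- genotypes$geno
  n <- nrow(g); m <- ncol(g)
  bp <- genotypes$bp
  if (is.null(bp)) bp <- seq_len(m)
  if (is.null(h1)) {
    h1 <- matrix(NA_integer_, n, m); h2 <- h1
    hom <- !is.na(g) & g != 1L
    h1[hom] <- g[hom] %/% 2L; h2[hom] <- h1[hom]
  }
  if (is.null(phased)) phased <- !is.na(h1) & !is.na(h2)
  ch <- function(a) ifelse(is.na(a), ".", as.character(a))
  gt <- matrix("", n, m)
  both <- !is.na(h1) & !is.na(h2)
  gt[phased & both] <- paste0(h1[phased & both], "|", h2[phased & both])
  rest <- !(phased & both)
  # unphased: emit the genotype (or partial haplotype knowledge) with '/'
  a1 <- h1; a2 <- h2
  hom <- rest & !is.na(g) & g != 1L
  a1[hom] <- g[hom] %/% 2L; a2[hom] <- a1[hom]
  het <- rest & !is.na(g) & g == 1L
  a1[het] <- 0L; a2[het] <- 1L
  gt[rest] <- paste0(ch(a1[rest]), "/", ch(a2[rest]))
  lines <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", genotypes$chrom, ">"),
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  body <- vapply(seq_len(m), function(j) {
    paste(c(genotypes$chrom, bp[j], colnames(g)[j], "A", "G", ".", ".",
            ".", "GT", gt[, j]), collapse = "\t")
  }, "")
  writeLines(c(lines, body), path)
  invisible(path)
}
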