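#' Genetic map
#'
#' Per-marker chromosome, base-pair position and cumulative genetic position.
#' Genetic positions are stored both in centimorgans (as in HapMap-format
#' map files) and in Morgans (used by all model code).
#'
#' @param chrom Chromosome label (recycled scalar or vector).
#' @param id Marker identifiers (unique).
#' @param bp Base-pair positions, strictly increasing.
#' @param cm Cumulative genetic positions in centimorgans, nondecreasing.
#' @return A data frame of class \code{"genetic_map"} with columns
#'   \code{chrom}, \code{id}, \code{bp}, \code{cm}, \code{morgans}.
#' @export
genetic_map <- function(chrom, id, bp, cm) {
  m <- length(bp)
  chrom <- rep_len(chrom, m)
  if (length(id) != m || length(cm) != m)
    stop("map columns must have equal length")
  if (anyDuplicated(id)) stop("marker ids must be unique")
  for (ch in unique(chrom)) {
    i <- chrom == ch
    if (any(diff(bp[i]) <= 0))
      stop("bp positions must be strictly increasing within a chromosome")
    if (any(diff(cm[i]) < 0))
      stop("genetic positions must be nondecreasing within a chromosome")
  }
  structure(
    data.frame(chrom = chrom, id = as.character(id), bp = as.integer(bp),
               cm = cm, morgans = cm / 100, stringsAsFactors = FALSE),
    class = c("genetic_map", "data.frame"))
}

#' Read a HapMap-format genetic map file
#'
#' Expects the four whitespace- or tab-separated columns chromosome,
#' position (bp), recombination rate (cM/Mb, ignored) and cumulative map
#' position (cM), with one header line.  Markers of a genotype matrix that
#' are absent from the map get genetic positions linearly interpolated on
#' the bp scale from the flanking mapped markers.
#'
#' @param path Map file path.
#' @param genotypes Optional \code{\link{genotype_matrix}} to align to; the
#'   returned map then has one row per genotype marker, matched by bp
#'   position (and chromosome).
#' @return A \code{\link{genetic_map}}.
#' @export
load_map <- function(path, genotypes = NULL) {
  tab <- data.table::fread(path, header = TRUE)
  if (ncol(tab) < 4) stop("map file must have >= 4 columns")
  chrom <- as.character(tab[[1]])
  bp <- as.integer(tab[[2]])
  cm <- as.numeric(tab[[4]])
  ord <- order(bp)
  if (is.unsorted(bp)) stop("map bp positions out of order in ", path)
  if (any(diff(cm) < 0)) {
    bad <- which(diff(cm) < 0)[1] + 1L
    stop("nonmonotonic genetic map at line ", bad + 1L, " of ", path)
  }
  if (is.null(genotypes))
    return(genetic_map(chrom, paste0("m", seq_along(bp)), bp, cm))
  want_bp <- genotypes$bp
  want_id <- colnames(genotypes$geno)
  if (is.null(want_bp))
    stop("genotype matrix carries no bp positions to align the map by")
  hit <- match(want_bp, bp)
  cm_out <- cm[hit]
  miss <- is.na(hit)
  if (any(miss)) {
    cm_out[miss] <- stats::approx(bp, cm, xout = want_bp[miss],
                                  rule = 2)$y
    message(sum(miss), " markers absent from map; ",
            "positions interpolated on the bp scale")
  }
  cm_out <- cummax(cm_out)  # guard interpolation round-off
  genetic_map(chrom[1], want_id, want_bp, cm_out)
}

#' Write a genetic map in HapMap format
#'
#' @param map A \code{\link{genetic_map}}.
#' @param path Output path.
#' @export
write_map <- function(map, path) {
  mb <- diff(map$bp) / 1e6
  rate <- c(ifelse(mb > 0, diff(map$cm) / mb, 0), 0)
  utils::write.table(
    data.frame(Chromosome = map$chrom, `Position(bp)` = map$bp,
               `Rate(cM/Mb)` = rate, `Map(cM)` = map$cm,
               check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Synthetic single-chromosome genetic map
#'
#' Builds a marker map mimicking a dense genotyping array on a human
#' chromosome: markers placed uniformly at random on the physical scale,
#' with piecewise-variable recombination density (log-normal block rates)
#' on the genetic scale.  Defaults correspond to chromosome 20: 7,505
#' markers over 1.09 Morgans and 62 Mbp, i.e. about 6,885 markers per
#' Morgan.
#'
#' @param n_markers Number of markers.
#' @param length_morgans Total genetic length (Morgans).
#' @param length_bp Total physical length (bp).
#' @param n_blocks Number of constant-rate recombination blocks.
#' @param rate_sdlog Log-sd of the block rates (0 gives a uniform map).
#' @param chrom Chromosome label.
#' @param seed Optional seed (uses the current RNG stream when NULL).
#' @return A \code{\link{genetic_map}}.
#' @export
synthetic_map <- function(n_markers = 7505, length_morgans = 1.09,
                          length_bp = 62e6, n_blocks = 25,
                          rate_sdlog = 0.7, chrom = "20", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_markers >= 2, length_morgans > 0)
  bp <- sort(sample.int(length_bp - 2L, n_markers)) + 1L
  rates <- stats::rlnorm(n_blocks, 0, rate_sdlog)
  block <- pmin(n_blocks, 1L + as.integer(n_blocks * (bp / length_bp)))
  # cumulative genetic position: integrate the block rate over bp gaps
  gaps <- diff(bp) * rates[block[-1]]
  cm <- c(0, cumsum(gaps))
  cm <- cm / cm[n_markers] * length_morgans * 100
  genetic_map(chrom, sprintf("snp%05d", seq_len(n_markers)), bp, cm)
}

#' Per-marker genetic length weights
#'
#' Assigns each marker half of its two adjacent inter-marker intervals (end
#' markers get the half-interval on their single side), so that weights sum
#' to the chromosome's genetic length.  Used by the length-weighted IBD
#' metrics.
#'
#' @param map A \code{\link{genetic_map}}.
#' @return Numeric vector of Morgan weights, one per marker.
#' @export
marker_weights <- function(map) {
  pos <- map$morgans
  m <- length(pos)
  if (m == 1) return(0)
  d <- diff(pos)
  c(d[1] / 2, (d[-1] + d[-(m - 1)]) / 2, d[m - 1] / 2)
}
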