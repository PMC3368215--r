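# Founder-population simulator with full truth tracking.
#
# Sampled haplotypes are ancestry mosaics: ordered breakpoints on the genetic
# scale (Morgans) with a founder-haplotype label per piece.  Truth IBD between
# two sampled haplotypes is the set of intervals where both carry the same
# founder label.

#' Demographic configuration for the founder-population simulation
#'
#' A panmictic population founded by \code{n_founders} individuals grows
#' exponentially to \code{final_size} over \code{generations} generations
#' (census at generation k is \code{round(n_founders * growth^k)}), after
#' which \code{sample_size} individuals are drawn without replacement.
#'
#' @param n_founders Founding individuals (default 100).
#' @param final_size Final census size (default 18,000).
#' @param generations Number of generations (default 12).
#' @param sample_size Individuals sampled from the final generation
#'   (default 190).
#' @return A list of class \code{"demography_config"} including the derived
#'   per-generation \code{growth} multiplier.
#' @export
#' @examples
#' d <- demography_config()
#' round(d$n_founders * d$growth^d$generations)  # 18000
demography_config <- function(n_founders = 100, final_size = 18000,
                              generations = 12, sample_size = 190) {
  stopifnot(n_founders >= 2, final_size >= n_founders, generations >= 0)
  growth <- (final_size / n_founders)^(1 / max(generations, 1))
  if (sample_size > final_size)
    stop("sample_size exceeds the final census size")
  structure(list(n_founders = as.integer(n_founders),
                 final_size = as.integer(final_size),
                 generations = as.integer(generations),
                 sample_size = as.integer(sample_size),
                 growth = growth),
            class = "demography_config")
}

#' Census trajectory of the exponential growth model
#'
#' @param demography A \code{\link{demography_config}}.
#' @return Integer vector of census sizes at generations 0..generations.
#' @export
census_trajectory <- function(demography) {
  k <- 0:demography$generations
  sizes <- as.integer(round(demography$n_founders * demography$growth^k))
  sizes[length(sizes)] <- demography$final_size
  sizes
}

#' Draw founder haplotypes
#'
#' Founder alleles are synthetic: minor-allele frequencies are drawn from
#' \code{freq_spec} and alleles sampled independently per haplotype and
#' marker (no founder-generation linkage disequilibrium; the long-range IBD
#' structure that drives the method is created by the simulated
#' generations, not by founder LD).
#'
#' @param n_founders Number of founding individuals (2 haplotypes each).
#' @param m Number of markers.
#' @param freq_spec Function \code{(m) -> f} drawing target minor-allele
#'   frequencies; default uniform on [0.05, 0.5].
#' @return List with \code{haps} (2*n_founders x m 0/1 matrix, 1 = minor
#'   allele) and \code{f} (the target frequencies used).
#' @export
make_founder_haplotypes <- function(n_founders, m,
                                    freq_spec = function(m)
                                      stats::runif(m, 0.05, 0.5)) {
  stopifnot(m >= 2)
  f <- freq_spec(m)
  if (any(f <= 0) || any(f >= 1))
    stop("freq_spec must yield frequencies strictly inside (0, 1)")
  nh <- 2L * as.integer(n_founders)
  haps <- matrix(stats::rbinom(nh * m, 1L, rep(f, each = nh)), nh, m)
  list(haps = haps, f = f)
}

# One transmitted gamete: recombine the parent's two mosaics.
# Crossover count ~ Poisson(L) with breakpoints uniform on the genetic scale
# (Haldane, no interference), starting from a random haplotype.
.gamete <- function(h1, h2, L) {
  k <- stats::rpois(1, L)
  cuts <- if (k > 0) sort(stats::runif(k, 0, L)) else numeric(0)
  start <- sample.int(2L, 1L)
  cpp_recombine(h1$br, h1$lab, h2$br, h2$lab, cuts, start)
}

#' Evolve the population and return sampled ancestry mosaics
#'
#' Each generation every offspring draws two distinct uniform-random parents
#' from the previous generation; each parent transmits one recombined
#' gamete.  Alleles are transmitted perfectly (no mutation).
#'
#' @param demography A \code{\link{demography_config}}.
#' @param length_morgans Chromosome genetic length in Morgans.
#' @return List of \code{2 * sample_size} haplotype mosaics (ordered as
#'   individual 1 hap 1, hap 2, individual 2 hap 1, ...), each a list with
#'   piece end positions \code{br} (last equals the chromosome length) and
#'   founder-haplotype labels \code{lab} (1-based, in
#'   [1, 2 * n_founders]).
#' @export
evolve_population <- function(demography, length_morgans) {
  sizes <- census_trajectory(demography)
  L <- length_morgans
  nf <- demography$n_founders
  # founders: single-piece mosaics labeled by founder haplotype
  pop <- lapply(seq_len(2L * nf), function(h) list(br = L, lab = h))
  for (gen in seq_len(demography$generations)) {
    nprev <- sizes[gen]
    nnext <- sizes[gen + 1L]
    p1 <- sample.int(nprev, nnext, replace = TRUE)
    p2r <- sample.int(nprev - 1L, nnext, replace = TRUE)
    p2 <- p2r + (p2r >= p1)
    nxt <- vector("list", 2L * nnext)
    for (i in seq_len(nnext)) {
      nxt[[2L * i - 1L]] <- .gamete(pop[[2L * p1[i] - 1L]],
                                    pop[[2L * p1[i]]], L)
      nxt[[2L * i]] <- .gamete(pop[[2L * p2[i] - 1L]],
                               pop[[2L * p2[i]]], L)
    }
    pop <- nxt
  }
  n_now <- length(pop) %/% 2L
  take <- sort(sample.int(n_now, demography$sample_size))
  idx <- as.vector(rbind(2L * take - 1L, 2L * take))
  pop[idx]
}

#' Founder labels of sampled haplotypes at each marker
#'
#' @param mosaics Output of \code{\link{evolve_population}}.
#' @param map A \code{\link{genetic_map}}.
#' @return Integer matrix, one row per sampled haplotype, one column per
#'   marker: the founder-haplotype label covering that marker's genetic
#'   position.
#' @export
mosaic_labels <- function(mosaics, map) {
  pos <- map$morgans
  t(vapply(mosaics, function(h) {
    piece <- findInterval(pos, h$br, left.open = TRUE) + 1L
    piece[piece > length(h$lab)] <- length(h$lab)  # guard position == L
    h$lab[piece]
  }, integer(length(pos))))
}

#' Realize genotypes from ancestry mosaics and founder haplotypes
#'
#' Copies each marker's allele from the founder haplotype whose mosaic
#' piece covers the marker, and sums the two haplotypes into unordered
#' dosages.
#'
#' @param labels Label matrix from \code{\link{mosaic_labels}}.
#' @param founder_haps Founder haplotype matrix from
#'   \code{\link{make_founder_haplotypes}}.
#' @return List with \code{h1}, \code{h2} (n x m truth haplotype matrices,
#'   1 = minor allele) and \code{geno} (n x m dosage matrix).
#' @export
realize_genotypes <- function(labels, founder_haps) {
  nh <- nrow(labels); m <- ncol(labels)
  if (max(labels) > nrow(founder_haps))
    stop("mosaic label outside the founder haplotype set")
  haps <- matrix(0L, nh, m)
  for (h in seq_len(nh))
    haps[h, ] <- founder_haps[cbind(labels[h, ], seq_len(m))]
  odd <- seq(1L, nh, by = 2L)
  list(h1 = haps[odd, , drop = FALSE],
       h2 = haps[odd + 1L, , drop = FALSE],
       geno = haps[odd, , drop = FALSE] + haps[odd + 1L, , drop = FALSE])
}

#' Truth IBD intervals for one pair of individuals
#'
#' For each of the four haplotype pairings, reports the maximal marker runs
#' where both haplotypes carry the same founder-haplotype label, i.e.
#' descend from a common ancestor in one piece without internal
#' recombination.
#'
#' @param labels Label matrix from \code{\link{mosaic_labels}}.
#' @param a,b Individual indices (1-based).
#' @param map A \code{\link{genetic_map}}.
#' @return \code{data.frame} with columns \code{a}, \code{b}, \code{hap_a},
#'   \code{hap_b}, \code{start}, \code{end} (0-based half-open marker
#'   interval), \code{n_markers}, \code{length_cm}.
#' @export
true_ibd <- function(labels, a, b, map) {
  out <- vector("list", 4)
  k <- 0
  for (ha in 1:2) for (hb in 1:2) {
    eq <- labels[2L * (a - 1L) + ha, ] == labels[2L * (b - 1L) + hb, ]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    k <- k + 1
    if (!any(keep)) { out[[k]] <- NULL; next }
    s <- starts[keep]; e <- ends[keep]
    out[[k]] <- data.frame(
      a = a, b = b, hap_a = ha, hap_b = hb,
      start = s - 1L, end = e,
      n_markers = e - s + 1L,
      length_cm = (map$morgans[e] - map$morgans[s]) * 100)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(a = integer(0), b = integer(0), hap_a = integer(0),
                      hap_b = integer(0), start = integer(0),
                      end = integer(0), n_markers = integer(0),
                      length_cm = numeric(0))
  res
}

#' Truth IBD intervals for all pairs
#'
#' @inheritParams true_ibd
#' @param min_cm Drop truth intervals shorter than this (cM); 0 keeps all.
#' @return Row-bound \code{\link{true_ibd}} tables over all unordered
#'   pairs.
#' @export
true_ibd_all_pairs <- function(labels, map, min_cm = 0) {
  n <- nrow(labels) %/% 2L
  out <- vector("list", n * (n - 1L) %/% 2L)
  k <- 0
  for (a in seq_len(n - 1L)) for (b in seq(a + 1L, n)) {
    k <- k + 1
    out[[k]] <- true_ibd(labels, a, b, map)
  }
  res <- do.call(rbind, out)
  res[res$length_cm >= min_cm, , drop = FALSE]
}

#' Degrade genotypes with missingness and genotyping errors
#'
#' Cells are set missing independently; errors replace a genotype with one
#' of the two other dosages uniformly at a per-marker rate.  A two-tier
#' marker mixture (a fraction of markers with a high error rate, the rest
#' low) is supported by passing a per-marker rate vector.
#'
#' @param geno n x m dosage matrix.
#' @param missing_rate Per-cell missingness probability.
#' @param error_rate Scalar or per-marker vector of error probabilities.
#' @return List with \code{geno} (degraded matrix), \code{missing_mask} and
#'   \code{error_mask} (logical n x m matrices of perturbed cells).
#' @export
#' @examples
#' g <- matrix(rbinom(200, 2, 0.3), 10, 20)
#' # two-tier errors: 20% of markers at 10%, the rest at 0.1%
#' rates <- ifelse(runif(20) < 0.2, 0.10, 0.001)
#' noisy <- add_noise(g, missing_rate = 0.05, error_rate = rates)
add_noise <- function(geno, missing_rate = 0, error_rate = 0) {
  n <- nrow(geno); m <- ncol(geno)
  stopifnot(all(missing_rate >= 0), all(missing_rate <= 1),
            all(error_rate >= 0), all(error_rate <= 1))
  err_rate <- rep_len(error_rate, m)
  err <- matrix(stats::runif(n * m) < rep(err_rate, each = n), n, m)
  err[is.na(geno)] <- FALSE
  out <- geno
  if (any(err)) {
    shift <- 1L + (stats::runif(sum(err)) < 0.5)  # +1 or +2 mod 3
    out[err] <- (geno[err] + shift) %% 3L
  }
  miss <- matrix(stats::runif(n * m) < missing_rate, n, m)
  out[miss] <- NA_integer_
  list(geno = out, missing_mask = miss, error_mask = err)
}

#' Simulate a genotyped founder population with truth
#'
#' Runs the full simulation: synthetic founder haplotypes, exponential
#' population growth with genetic-map recombination and perfect allele
#' transmission, sampling, and genotype realization.  Markers that drifted
#' to monomorphic are dropped (the emission model needs frequencies inside
#' (0, 1)) and marker orientation is flipped to the realized minor allele,
#' with the truth haplotypes kept aligned.
#'
#' @param map A \code{\link{genetic_map}} (see \code{\link{synthetic_map}}).
#' @param demography A \code{\link{demography_config}}.
#' @param freq_spec Founder frequency spectrum, see
#'   \code{\link{make_founder_haplotypes}}.
#' @param seed Optional seed.
#' @return List: \code{genotypes} (\code{\link{genotype_matrix}}),
#'   \code{map} (subset to surviving markers), \code{h1}, \code{h2} (truth
#'   haplotypes, minor-allele coded), \code{labels} (founder labels of the
#'   sampled haplotypes), \code{demography}.
#' @export
simulate_founder_population <- function(map,
                                        demography = demography_config(),
                                        freq_spec = function(m)
                                          stats::runif(m, 0.05, 0.5),
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(map)
  L <- map$morgans[m]
  fh <- make_founder_haplotypes(demography$n_founders, m, freq_spec)
  mosaics <- evolve_population(demography, L)
  labels <- mosaic_labels(mosaics, map)
  real <- realize_genotypes(labels, fh$haps)
  # orient to realized minor allele and drop drifted-monomorphic markers
  p1 <- colMeans(real$geno) / 2
  flip <- p1 > 0.5
  geno <- real$geno
  h1 <- real$h1; h2 <- real$h2
  if (any(flip)) {
    geno[, flip] <- 2L - geno[, flip]
    h1[, flip] <- 1L - h1[, flip]
    h2[, flip] <- 1L - h2[, flip]
  }
  mono <- colSums(geno) == 0L
  keep <- which(!mono)
  map_out <- map[keep, , drop = FALSE]
  class(map_out) <- class(map)
  gm <- genotype_matrix(geno[, keep, drop = FALSE],
                        bp = map$bp[keep], chrom = map$chrom[1])
  stopifnot(ncol(gm$geno) == length(keep))  # constructor must not re-drop
  list(genotypes = gm, map = map_out,
       h1 = h1[, keep, drop = FALSE], h2 = h2[, keep, drop = FALSE],
       labels = labels[, keep, drop = FALSE],
       demography = demography)
}
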