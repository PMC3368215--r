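# Forward-Backward prescan over all pairs: find plausible IBD segments that
# scope the expensive Min-Sum phase.

# Per-marker emission array E[j, s, c]: state s, ordered diplotype pair
# c = 4*da + db + 1, vectorized over markers.
.emission_array <- function(f) {
  m <- length(f)
  w <- cbind(1 - f, f)  # column allele+1
  E <- array(0, c(m, 5, 16))
  for (da in 0:3) for (db in 0:3) {
    a <- c(da %/% 2L, da %% 2L)
    b <- c(db %/% 2L, db %% 2L)
    full <- w[, a[1] + 1] * w[, a[2] + 1] * w[, b[1] + 1] * w[, b[2] + 1]
    c1 <- 4 * da + db + 1
    E[, 1, c1] <- full
    for (s in 2:5) {
      ij <- .state_haps[s - 1, ]
      if (a[ij[1]] == b[ij[2]])
        E[, s, c1] <- full / w[, a[ij[1]] + 1]
    }
  }
  E
}

# Observation table for the pair HMM: obs[j, c*5 + s] = P(genotype pair
# combo | state), marginalized over diplotypes weighted by the genotype
# likelihood.  Genotype codes 0,1,2 dosage, 3 missing; c = 4*ga + gb.
.obs_table <- function(f, epsilon) {
  m <- length(f)
  E <- .emission_array(f)
  dose <- c(0L, 1L, 1L, 2L)  # dosage of diplotype code 0..3
  L <- matrix(1, 4, 4)       # rows genotype code 0..3 (3 = missing)
  for (g in 0:2) for (d in 0:3)
    L[g + 1, d + 1] <- if (dose[d + 1] == g) 1 - epsilon else epsilon / 2
  obs <- matrix(0, m, 80)
  for (ga in 0:3) for (gb in 0:3) {
    cg <- 4 * ga + gb
    for (s in 1:5) {
      acc <- numeric(m)
      for (da in 0:3) for (db in 0:3) {
        lw <- L[ga + 1, da + 1] * L[gb + 1, db + 1]
        if (lw > 0)
          acc <- acc + E[, s, 4 * da + db + 1] * lw
      }
      obs[, cg * 5 + s] <- acc
    }
  }
  obs
}

.gcode <- function(g) {
  g <- as.integer(g)
  g[is.na(g)] <- 3L
  g
}

#' Per-marker IBD posteriors for one pair of individuals
#'
#' Runs the scaled Forward-Backward algorithm over the five-state pair HMM:
#' transition matrices from the genetic map (kinship-capped), emissions
#' marginalized over the diplotypes compatible with the unordered observed
#' genotypes, chain initialized at the unconditional IBD prior.
#'
#' @param geno_a,geno_b Genotype dosage vectors (0, 1, 2, \code{NA}) on the
#'   same marker set.
#' @param map A \code{\link{genetic_map}} aligned to the genotypes.
#' @param params Model parameters.
#' @param freqs Minor-allele frequency vector.
#' @return 5 x m matrix of posterior state probabilities (columns sum to 1),
#'   rows named by \code{\link{ibd_states}}.
#' @export
pair_posteriors <- function(geno_a, geno_b, map, params = model_params(),
                            freqs) {
  m <- length(geno_a)
  if (length(geno_b) != m || nrow(map) != m || length(freqs) != m)
    stop("genotypes, map and frequencies must cover the same markers")
  obs <- .obs_table(freqs, params$epsilon)
  trans <- transition_kernels(map, params)
  post <- cpp_pair_posteriors(.gcode(geno_a), .gcode(geno_b), obs, trans,
                              stationary_ibd_prior(params))
  rownames(post) <- ibd_states()
  post
}

#' Call plausible IBD segments from pair posteriors
#'
#' Maximal runs of markers whose combined IBD posterior (sum of the four
#' one-haplotype-shared states) exceeds \code{posterior_threshold}.
#' Adjacent runs separated by fewer than \code{gap_merge} markers are
#' merged and runs shorter than \code{min_markers} markers are dropped
#' (smoothing against single discordant markers; configurable).
#'
#' @param posteriors Matrix from \code{\link{pair_posteriors}}.
#' @param map A \code{\link{genetic_map}}.
#' @param params Model parameters.
#' @return Data frame with columns \code{start}, \code{end} (0-based
#'   half-open marker interval), \code{peak_posterior},
#'   \code{genetic_length} (Morgans).
#' @export
call_segments <- function(posteriors, map, params = model_params()) {
  runs <- cpp_call_runs(posteriors, params$posterior_threshold,
                        params$gap_merge, params$min_markers)
  s <- runs[, "start"] + 1L
  e <- runs[, "end"]
  data.frame(start = as.integer(runs[, "start"]), end = as.integer(e),
             peak_posterior = runs[, "peak"],
             genetic_length = if (nrow(runs)) map$morgans[e] -
               map$morgans[s] else numeric(0))
}

#' Scan all pairs of individuals for plausible IBD segments
#'
#' Runs the Forward-Backward prescan over all n(n-1)/2 unordered pairs and
#' concatenates the called segments.  These segments scope the Min-Sum
#' message passing: phase can only be called at markers covered by at least
#' one plausible segment.
#'
#' @param genotypes A \code{\link{genotype_matrix}}.
#' @param map A \code{\link{genetic_map}} aligned to the genotypes.
#' @param params Model parameters.
#' @param progress Emit progress messages.
#' @return Data frame with columns \code{a}, \code{b} (1-based individual
#'   indices, a < b), \code{start}, \code{end} (0-based half-open marker
#'   interval), \code{peak_posterior}, \code{genetic_length} (Morgans).
#' @export
scan_all_pairs <- function(genotypes, map, params = model_params(),
                           progress = FALSE) {
  g <- genotypes$geno
  n <- nrow(g); m <- ncol(g)
  if (n < 2) stop("need at least two individuals")
  if (nrow(map) != m) stop("map does not align with the genotype markers")
  gc <- g
  gc[is.na(gc)] <- 3L
  obs <- .obs_table(genotypes$f, params$epsilon)
  trans <- transition_kernels(map, params)
  segs <- cpp_scan_pairs(gc, obs, trans, stationary_ibd_prior(params),
                         params$posterior_threshold, params$gap_merge,
                         params$min_markers, progress)
  out <- data.frame(a = as.integer(segs[, "a"]),
                    b = as.integer(segs[, "b"]),
                    start = as.integer(segs[, "start"]),
                    end = as.integer(segs[, "end"]),
                    peak_posterior = segs[, "peak"])
  out$genetic_length <- if (nrow(out))
    map$morgans[out$end] - map$morgans[out$start + 1L] else numeric(0)
  if (is.finite(params$max_depth) && nrow(out) > 1)
    out <- .cap_depth(out, n, m, params$max_depth)
  out
}

# Cap the number of segments covering any (individual, marker) cell,
# keeping highest peak posterior first.
.cap_depth <- function(segs, n, m, max_depth) {
  ord <- order(-segs$peak_posterior)
  cov <- matrix(0L, n, m)
  keep <- logical(nrow(segs))
  for (k in ord) {
    span <- (segs$start[k] + 1L):segs$end[k]
    if (max(cov[segs$a[k], span]) < max_depth &&
        max(cov[segs$b[k], span]) < max_depth) {
      keep[k] <- TRUE
      cov[segs$a[k], span] <- cov[segs$a[k], span] + 1L
      cov[segs$b[k], span] <- cov[segs$b[k], span] + 1L
    }
  }
  segs[keep, , drop = FALSE]
}

#' Write plausible segments as tab-separated text
#'
#' @param segments Data frame from \code{\link{scan_all_pairs}}.
#' @param genotypes The \code{\link{genotype_matrix}} scanned.
#' @param map The \code{\link{genetic_map}} used.
#' @param path Output path.
#' @export
write_segments <- function(segments, genotypes, map, path) {
  ids <- rownames(genotypes$geno)
  bp <- if (is.null(genotypes$bp)) map$bp else genotypes$bp
  out <- data.frame(
    a_id = ids[segments$a], b_id = ids[segments$b],
    chrom = map$chrom[1],
    start_bp = bp[segments$start + 1L], end_bp = bp[segments$end],
    start_marker = segments$start, end_marker = segments$end,
    genetic_length_cM = segments$genetic_length * 100,
    peak_posterior = segments$peak_posterior)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
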