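# Min-Sum phasing over the Bayesian network restricted to plausible IBD
# segments.  The network couples, for every plausible-segment pair, a chain
# of 5-valued IBD indicators with the 4-valued diplotype variables of both
# individuals; genotype observations attach as unary factors.

#' Conditional distribution of an IBD indicator
#'
#' The conditional probability table of the IBD indicator at a marker given
#' the two diplotypes at that marker and the IBD state at the previous
#' marker: Bayes inversion of the pair HMM,
#' P(p = s | d_a, d_b, prev) proportional to T(prev -> s) E(s; d_a, d_b),
#' normalized over the five states.  When the emission is zero for all four
#' IBD states (identity-by-state violated) the distribution concentrates on
#' NONIBD.
#'
#' @param d_a,d_b Diplotype codes 0..3.
#' @param prev Previous IBD state (1..5 or label); \code{NULL} for the
#'   first marker of a chain, which conditions on the unconditional IBD
#'   prior instead.
#' @param t Genetic distance to the previous marker (Morgans).
#' @param f Minor-allele frequency.
#' @param params Model parameters.
#' @return Probability 5-vector over \code{\link{ibd_states}}.
#' @export
#' @examples
#' ibd_cpt(3, 0, prev = 1, t = 1e-4, f = 0.3)  # opposite homozygotes
ibd_cpt <- function(d_a, d_b, prev = NULL, t, f, params = model_params()) {
  if (is.character(prev)) prev <- match(prev, ibd_states())
  trow <- if (is.null(prev)) {
    stationary_ibd_prior(params)
  } else {
    Q <- build_rate_matrix(params)
    transition_matrix(Q, t, params$kappa)[prev, ]
  }
  e <- vapply(1:5, function(s) emission_prob(s, d_a, d_b, f), 0)
  u <- trow * e
  u / sum(u)
}

#' Phase genotypes by damped Min-Sum over plausible IBD segments
#'
#' The full pipeline: a Forward-Backward prescan finds plausible IBD
#' segments for every pair of individuals (unless \code{segments} is
#' given); the Bayesian network restricted to those segments is then solved
#' approximately by damped Min-Sum message passing in the negative-log
#' domain, sweeping each segment chain forward and backward and updating
#' the diplotype beliefs after each chain.  From the converged max-marginals
#' the function calls ordered diplotypes (refusing when the margin between
#' the two orientations of a heterozygote is below \code{phase_margin}),
#' imputes missing alleles through MAP IBD links, and extracts IBD segment
#' calls.
#'
#' Each individual's global haplotype-flip symmetry is anchored by fixing
#' its first covered heterozygous site to minor-allele-on-haplotype-1, so
#' output is deterministic; switch-error metrics are invariant to the
#' anchor choice.
#'
#' @param genotypes A \code{\link{genotype_matrix}}.
#' @param map A \code{\link{genetic_map}} aligned to the genotypes.
#' @param params Model parameters.
#' @param segments Optional precomputed segments from
#'   \code{\link{scan_all_pairs}}.
#' @param progress Emit progress messages.
#' @return Object of class \code{"phase_result"}: list with n x m matrices
#'   \code{h1}, \code{h2} (called haplotype alleles, 1 = minor, \code{NA} =
#'   no call), \code{phased} (ordered diplotype called), \code{margin}
#'   (max-marginal margin at covered cells), \code{imputed} (missing cells
#'   with at least one imputed allele), plus \code{ibd_calls} (data frame,
#'   see \code{\link{extract_ibd_calls}}), \code{segments},
#'   \code{corrections} (suspected genotype errors when \code{epsilon} >
#'   0), \code{converged}, \code{iters}, \code{delta}, \code{params}.
#' @export
phase_genotypes <- function(genotypes, map, params = model_params(),
                            segments = NULL, progress = FALSE) {
  g <- genotypes$geno
  n <- nrow(g); m <- ncol(g)
  if (nrow(map) != m) stop("map does not align with the genotype markers")
  if (is.null(segments))
    segments <- scan_all_pairs(genotypes, map, params, progress)
  if (nrow(segments) == 0) {
    warning("no plausible IBD segments found; everything left unphased")
    return(.empty_phase_result(genotypes, segments, params))
  }
  covered <- matrix(FALSE, n, m)
  homp <- matrix(FALSE, n, m)  # partner of a covering segment is hom here
  hom <- !is.na(g) & g != 1L
  for (k in seq_len(nrow(segments))) {
    span <- (segments$start[k] + 1L):segments$end[k]
    a <- segments$a[k]; b <- segments$b[k]
    covered[a, span] <- TRUE
    covered[b, span] <- TRUE
    homp[a, span[hom[b, span]]] <- TRUE
    homp[b, span[hom[a, span]]] <- TRUE
  }
  # Per-individual anchor fixing the global haplotype-flip gauge.  Prefer
  # a heterozygous site whose segment partner is homozygous there: such a
  # site pins the chain's haplotype labeling, so the anchor breaks the
  # residual label symmetry.  Take the candidate nearest the midpoint of
  # the individual's covered span — boundary sites can be excluded from
  # the MAP IBD run by the entry/exit tradeoff, which would unpin the
  # anchor.  Fall back to the covered heterozygote nearest the midpoint.
  anchors <- rep(-1L, n)
  for (i in seq_len(n)) {
    het <- which(covered[i, ] & !is.na(g[i, ]) & g[i, ] == 1L)
    if (!length(het)) next
    cov_idx <- which(covered[i, ])
    mid <- (cov_idx[1] + cov_idx[length(cov_idx)]) / 2
    informative <- het[homp[i, het]]
    pool <- if (length(informative)) informative else het
    anchors[i] <- pool[which.min(abs(pool - mid))] - 1L
  }
  gc <- g
  gc[is.na(gc)] <- 3L
  segdef <- cbind(segments$a - 1L, segments$b - 1L,
                  segments$start, segments$end)
  storage.mode(segdef) <- "integer"
  fit <- cpp_min_sum(gc, genotypes$f, params$epsilon,
                     transition_kernels(map, params),
                     stationary_ibd_prior(params), segdef, anchors,
                     params$damping, params$max_iters, params$tol,
                     .NEGLOG_ZERO)
  if (!fit$converged && progress)
    message(sprintf("Min-Sum not converged after %d sweeps (delta %.2g)",
                    fit$iters, fit$delta))
  res <- .call_phase(fit, genotypes, segments, params)
  res$ibd_calls <- extract_ibd_calls(res, map)
  res
}

.NEGLOG_ZERO <- 700  # -log of the smallest representable probability used

.empty_phase_result <- function(genotypes, segments, params) {
  g <- genotypes$geno
  n <- nrow(g); m <- ncol(g)
  h1 <- matrix(NA_integer_, n, m, dimnames = dimnames(g))
  h2 <- h1
  hom <- !is.na(g) & g != 1L
  h1[hom] <- g[hom] %/% 2L
  h2[hom] <- h1[hom]
  structure(list(h1 = h1, h2 = h2, phased = hom,
                 margin = matrix(NA_real_, n, m),
                 imputed = matrix(FALSE, n, m),
                 ibd_calls = .empty_ibd_calls(),
                 segments = segments, seg_states = list(),
                 corrections = NULL, converged = TRUE, iters = 0L,
                 delta = 0, params = params),
            class = "phase_result")
}

# Turn min-sum beliefs into diplotype calls, refusals and imputations.
.call_phase <- function(fit, genotypes, segments, params) {
  g <- genotypes$geno
  n <- nrow(g); m <- ncol(g)
  B <- fit$belief           # 4 x nH, rows = diplotype codes 0..3
  hidx <- fit$hidx          # n x m, -1 or 0-based belief column
  h1 <- matrix(NA_integer_, n, m, dimnames = dimnames(g))
  h2 <- h1
  margin <- matrix(NA_real_, n, m)
  phased <- matrix(FALSE, n, m)
  imputed <- matrix(FALSE, n, m)

  # trivial phase of observed homozygotes
  hom <- !is.na(g) & g != 1L
  h1[hom] <- g[hom] %/% 2L
  h2[hom] <- h1[hom]
  phased[hom] <- TRUE

  cov <- hidx >= 0
  # heterozygous covered sites: compare the two orderings
  het <- which(!is.na(g) & g == 1L & cov)
  if (length(het)) {
    cols <- hidx[het] + 1L
    d1 <- B[2, cols]  # (major, minor)
    d2 <- B[3, cols]  # (minor, major)
    mg <- abs(d1 - d2)
    margin[het] <- mg
    call <- mg >= params$phase_margin
    minor_first <- d2 < d1
    h1[het[call]] <- as.integer(minor_first[call])
    h2[het[call]] <- 1L - as.integer(minor_first[call])
    phased[het[call]] <- TRUE
  }

  # MAP-linked haplotypes per cell (for imputation)
  linked <- .linked_haplotypes(fit, segments, n, m)
  miss <- which(is.na(g) & cov)
  if (length(miss)) {
    cols <- hidx[miss] + 1L
    # haplotype 1 allele: compare best diplotype with a1 = 0 vs a1 = 1
    best10 <- pmin(B[1, cols], B[2, cols])
    best11 <- pmin(B[3, cols], B[4, cols])
    mg1 <- abs(best10 - best11)
    ok1 <- linked$h1[miss] & mg1 >= params$phase_margin
    h1[miss[ok1]] <- as.integer(best11 < best10)[ok1]
    best20 <- pmin(B[1, cols], B[3, cols])
    best21 <- pmin(B[2, cols], B[4, cols])
    mg2 <- abs(best20 - best21)
    ok2 <- linked$h2[miss] & mg2 >= params$phase_margin
    h2[miss[ok2]] <- as.integer(best21 < best20)[ok2]
    margin[miss] <- pmin(mg1, mg2)
    imputed[miss] <- ok1 | ok2
    phased[miss[ok1 & ok2]] <- TRUE
  }

  # suspected genotype errors (reported, never applied)
  corrections <- NULL
  if (params$epsilon > 0) {
    obs <- which(!is.na(g) & cov)
    cols <- hidx[obs] + 1L
    bestd <- max.col(-t(B[, cols, drop = FALSE])) - 1L
    dose <- bestd %/% 2L + bestd %% 2L
    consi <- vapply(seq_along(obs), function(k) {
      dd <- which(c(0L, 1L, 1L, 2L) == g[obs[k]]) - 1L
      min(B[dd + 1L, cols[k]])
    }, 0)
    over <- dose != g[obs] &
      (consi - B[cbind(bestd + 1L, cols)]) >= params$phase_margin
    if (any(over)) {
      ij <- arrayInd(obs[over], dim(g))
      corrections <- data.frame(individual = ij[, 1], marker = ij[, 2],
                                observed = g[obs[over]],
                                suggested = dose[over])
    }
  }

  structure(list(h1 = h1, h2 = h2, phased = phased, margin = margin,
                 imputed = imputed, segments = segments,
                 seg_states = fit$seg_states,
                 seg_margin = fit$seg_margin,
                 seg_maxmarg = fit$seg_maxmarg,
                 corrections = corrections, converged = fit$converged,
                 iters = fit$iters, delta = fit$delta, params = params),
            class = "phase_result")
}

# Which haplotype of each individual is linked by a MAP IBD chain at each
# marker.
.linked_haplotypes <- function(fit, segments, n, m) {
  l1 <- matrix(FALSE, n, m)
  l2 <- matrix(FALSE, n, m)
  for (k in seq_len(nrow(segments))) {
    st <- fit$seg_states[[k]]
    jj <- segments$start[k] + seq_along(st)  # 1-based marker indices
    a <- segments$a[k]; b <- segments$b[k]
    ia <- .state_haps[pmax(st - 1L, 1L), 1]  # hap of a for states 2..5
    ib <- .state_haps[pmax(st - 1L, 1L), 2]
    on <- st > 1L
    l1[a, jj[on & ia == 1L]] <- TRUE
    l2[a, jj[on & ia == 2L]] <- TRUE
    l1[b, jj[on & ib == 1L]] <- TRUE
    l2[b, jj[on & ib == 2L]] <- TRUE
  }
  list(h1 = l1, h2 = l2)
}

.empty_ibd_calls <- function() {
  data.frame(a = integer(0), b = integer(0), hap_a = integer(0),
             hap_b = integer(0), start = integer(0), end = integer(0),
             n_markers = integer(0), length_cm = numeric(0))
}

#' Extract IBD segment calls from a phase result
#'
#' Maximal runs of constant MAP IBD state within each plausible segment's
#' chain, split at flips between states and at non-IBD stretches.
#'
#' @param phase A \code{\link{phase_genotypes}} result.
#' @param map A \code{\link{genetic_map}}.
#' @return Data frame with columns \code{a}, \code{b} (individual indices),
#'   \code{hap_a}, \code{hap_b} (haplotype configuration), \code{start},
#'   \code{end} (0-based half-open marker interval), \code{n_markers},
#'   \code{length_cm}.
#' @export
extract_ibd_calls <- function(phase, map) {
  segs <- phase$segments
  out <- vector("list", length(phase$seg_states))
  for (k in seq_along(phase$seg_states)) {
    st <- phase$seg_states[[k]]
    r <- rle(st)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values > 1L
    if (!any(keep)) next
    s0 <- segs$start[k] + starts[keep]      # 1-based global marker index
    e0 <- segs$start[k] + ends[keep]
    hp <- .state_haps[r$values[keep] - 1L, , drop = FALSE]
    out[[k]] <- data.frame(
      a = segs$a[k], b = segs$b[k],
      hap_a = hp[, 1], hap_b = hp[, 2],
      start = s0 - 1L, end = e0,
      n_markers = e0 - s0 + 1L,
      length_cm = (map$morgans[e0] - map$morgans[s0]) * 100)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- .empty_ibd_calls()
  res
}

#' Write IBD calls as tab-separated text
#'
#' Columns: individual ids, haplotype indices, chromosome, bp span, marker
#' span (0-based half-open) and genetic length in cM.
#'
#' @param calls Data frame from \code{\link{extract_ibd_calls}} (or the
#'   simulator's truth IBD, which uses the same schema).
#' @param genotypes The phased \code{\link{genotype_matrix}}.
#' @param map The \code{\link{genetic_map}} used.
#' @param path Output path.
#' @export
write_ibd_calls <- function(calls, genotypes, map, path) {
  ids <- rownames(genotypes$geno)
  bp <- if (is.null(genotypes$bp)) map$bp else genotypes$bp
  out <- data.frame(
    a_id = ids[calls$a], a_hap = calls$hap_a,
    b_id = ids[calls$b], b_hap = calls$hap_b,
    chrom = map$chrom[1],
    start_bp = bp[calls$start + 1L], end_bp = bp[calls$end],
    start_marker = calls$start, end_marker = calls$end,
    n_markers = calls$n_markers, genetic_length_cM = calls$length_cm)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.phase_result <- function(x, ...) {
  g <- !is.na(x$h1) & !is.na(x$h2)
  cat(sprintf("phase_result: %d x %d; %s after %d sweeps (delta %.2g)\n",
              nrow(x$h1), ncol(x$h1),
              if (x$converged) "converged" else "NOT converged",
              x$iters, x$delta))
  cat(sprintf("  %d plausible segments, %d IBD calls\n",
              nrow(x$segments), nrow(x$ibd_calls)))
  invisible(x)
}
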