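# Five-state continuous-time IBD process for one pair of diploid individuals.
#
# State order used everywhere: 1 = NONIBD, 2 = S11, 3 = S12, 4 = S21, 5 = S22,
# where Sij means haplotype i of individual a is IBD with haplotype j of b.
#
# Diplotypes are ordered allele pairs coded 0..3 as code = 2*a1 + a2 with
# allele 1 = minor, 0 = major; a1 sits on haplotype 1.  A pair of diplotypes
# (da, db) is coded 0..15 as 4*da + db.

#' IBD state labels
#'
#' @return Character vector of the five pairwise IBD states, in the order
#'   used by all matrices in the package.
#' @export
ibd_states <- function() c("NONIBD", "S11", "S12", "S21", "S22")

# haplotype indices (i, j) for states 2..5; row s-1 gives c(i, j) of Sij
.state_haps <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))

#' Ordered diplotype codes
#'
#' @return Data frame with the four ordered diplotypes per biallelic marker:
#'   integer \code{code} 0..3, alleles \code{a1}, \code{a2} (1 = minor,
#'   0 = major) on haplotypes 1 and 2, and the minor-allele \code{dosage}.
#' @export
diplotype_table <- function() {
  code <- 0:3
  a1 <- code %/% 2L
  a2 <- code %% 2L
  data.frame(code = code, a1 = a1, a2 = a2, dosage = a1 + a2)
}

#' Rate matrix of the five-state IBD process
#'
#' The non-IBD state is left at rate \code{g}, split equally over the four
#' IBD states; each IBD state is left at rate \code{l} towards non-IBD.
#' There are no direct IBD-to-IBD rates: over an interval, "flips" between
#' IBD states arise through paths via non-IBD inside \code{expm(t Q)}.
#'
#' @param params An \code{\link{model_params}} object (only \code{g} and
#'   \code{l} are used).
#' @return A 5x5 rate matrix with rows summing to zero.
#' @export
#' @examples
#' Q <- build_rate_matrix(model_params())
#' rowSums(Q)  # all zero
build_rate_matrix <- function(params) {
  g <- params$g; l <- params$l
  if (g <= 0 || l <= 0) stop("rates g and l must be positive")
  Q <- matrix(0, 5, 5, dimnames = list(ibd_states(), ibd_states()))
  Q[1, 2:5] <- g / 4
  Q[1, 1] <- -g
  Q[2:5, 1] <- l
  diag(Q)[2:5] <- -l
  Q
}

# Closed-form exp(tQ) entries for the symmetric 5-state rate structure.
# Lumping the four IBD states gives a two-state chain with rates g (enter)
# and l (leave); conditional on having left the starting IBD state at least
# once, the IBD label is uniform over the four states by symmetry.
# Returns the five distinct entries for each t (vectorized over t).
.trans_entries <- function(g, l, t) {
  s <- g + l
  est <- exp(-s * t)
  elt <- exp(-l * t)
  nn <- (l + g * est) / s         # NONIBD -> NONIBD
  ns <- (1 - nn) / 4              # NONIBD -> each Sij
  inI <- (g + l * est) / s        # Sii... P(in some IBD | start IBD)
  sn <- 1 - inI                   # Sij -> NONIBD
  soth <- (inI - elt) / 4         # Sij -> Skl, (k,l) != (i,j)
  sstay <- elt + soth             # Sij -> Sij
  list(nn = nn, ns = ns, sn = sn, sstay = sstay, soth = soth)
}

#' Per-interval transition matrix with kinship capping
#'
#' Computes \code{expm(t Q)} for one inter-marker interval and caps each
#' NONIBD-to-IBD entry at \code{kappa / 4} (total \code{kappa}, the kinship
#' coefficient: the unconditional probability of IBD), returning the clipped
#' mass to the NONIBD-to-NONIBD entry so the matrix stays row-stochastic.
#'
#' @param Q Rate matrix from \code{\link{build_rate_matrix}}.
#' @param t Genetic distance of the interval in Morgans (nonnegative).
#' @param kappa Kinship cap in [0, 1]; 1 disables the cap.
#' @return A 5x5 row-stochastic matrix with attribute \code{t}.
#' @export
#' @examples
#' Q <- build_rate_matrix(model_params())
#' P <- transition_matrix(Q, 0.001, kappa = 0.01)
#' rowSums(P)
transition_matrix <- function(Q, t, kappa = 1) {
  if (t < 0) stop("genetic distance t must be nonnegative (map out of order?)")
  g <- -Q[1, 1]; l <- Q[2, 1]
  if (t == 0) {
    P <- diag(5)
    dimnames(P) <- dimnames(Q)
    attr(P, "t") <- 0
    return(P)
  }
  e <- .trans_entries(g, l, t)
  ns <- min(e$ns, kappa / 4)
  P <- matrix(e$soth, 5, 5, dimnames = dimnames(Q))
  P[1, 1] <- 1 - 4 * ns
  P[1, 2:5] <- ns
  P[2:5, 1] <- e$sn
  diag(P)[2:5] <- e$sstay
  attr(P, "t") <- t
  P
}

#' Transition matrices for all intervals of a genetic map
#'
#' @param map A \code{\link{genetic_map}}.
#' @param params Model parameters.
#' @return A (m-1) x 25 matrix: row j holds \code{transition_matrix} for the
#'   interval between markers j and j+1, stored column-major.
#' @export
transition_kernels <- function(map, params) {
  pos <- map$morgans
  t <- diff(pos)
  if (any(t < 0)) stop("genetic map positions must be nondecreasing")
  m1 <- length(t)
  e <- .trans_entries(params$g, params$l, t)
  ns <- pmin(e$ns, params$kappa / 4)
  P <- matrix(0, m1, 25)
  # column-major index of entry (r, c) in a 5x5 matrix is (c-1)*5 + r
  idx <- function(r, c) (c - 1L) * 5L + r
  P[, idx(1L, 1L)] <- 1 - 4 * ns
  for (c in 2:5) P[, idx(1L, c)] <- ns
  for (r in 2:5) P[, idx(r, 1L)] <- e$sn
  for (r in 2:5) for (c in 2:5)
    P[, idx(r, c)] <- if (r == c) e$sstay else e$soth
  zero <- t == 0
  if (any(zero)) {
    P[zero, ] <- 0
    for (r in 1:5) P[zero, idx(r, r)] <- 1
  }
  P
}

#' Stationary / unconditional prior over IBD states
#'
#' The chain prior used at segment boundaries: the unconditional probability
#' of IBD is the kinship coefficient \code{kappa}, split equally over the
#' four IBD states.
#'
#' @param params Model parameters (only \code{kappa} is used).
#' @return Probability 5-vector.
#' @export
stationary_ibd_prior <- function(params) {
  k <- params$kappa
  c(NONIBD = 1 - k, S11 = k / 4, S12 = k / 4, S21 = k / 4, S22 = k / 4)
}

#' Emission probability of an ordered diplotype pair given the IBD state
#'
#' Under Hardy-Weinberg equilibrium with minor-allele frequency \code{f},
#' a non-IBD pair emits the product of the four per-haplotype allele
#' frequencies.  Under Sij the emission is zero unless allele i of
#' individual a equals allele j of individual b; otherwise the shared
#' allele's frequency is counted once and the three free alleles contribute
#' their own frequencies.
#'
#' @param state IBD state: integer 1..5 or a label from
#'   \code{\link{ibd_states}}.
#' @param d_a,d_b Diplotype codes 0..3 (see \code{\link{diplotype_table}}).
#' @param f Minor-allele frequency, strictly inside (0, 1).
#' @return Emission probability.
#' @export
#' @examples
#' # one individual hom-minor, the other het with the minor allele first:
#' emission_prob("S11", 3, 2, 0.2)     # f^2 (1 - f)
#' emission_prob("NONIBD", 3, 2, 0.2)  # f^3 (1 - f)
emission_prob <- function(state, d_a, d_b, f) {
  if (any(f <= 0) || any(f >= 1))
    stop("allele frequency must lie strictly in (0, 1); ",
         "monomorphic markers must be excluded upstream")
  if (is.character(state)) state <- match(state, ibd_states())
  stopifnot(state %in% 1:5, d_a %in% 0:3, d_b %in% 0:3)
  a <- c(d_a %/% 2L, d_a %% 2L)   # alleles of a on haplotypes 1, 2
  b <- c(d_b %/% 2L, d_b %% 2L)
  w <- function(al) ifelse(al == 1L, f, 1 - f)
  full <- prod(w(c(a, b)))
  if (state == 1L) return(full)
  ij <- .state_haps[state - 1L, ]
  if (a[ij[1]] != b[ij[2]]) return(0)
  full / w(a[ij[1]])
}

#' Emission table for one marker
#'
#' @param f Minor-allele frequency (scalar).
#' @return 5 x 16 matrix: rows are IBD states, columns ordered diplotype
#'   pairs coded \code{4 * d_a + d_b} (0-based), value the emission
#'   probability.  Every row sums to 1.
#' @export
emission_table <- function(f) {
  E <- matrix(0, 5, 16, dimnames = list(ibd_states(), NULL))
  for (da in 0:3) for (db in 0:3)
    for (s in 1:5)
      E[s, 4 * da + db + 1] <- emission_prob(s, da, db, f)
  E
}

#' Genotype observation likelihood given a diplotype
#'
#' The observed genotype depends essentially deterministically on the
#' underlying diplotype, allowing for symmetric assay noise: probability
#' \code{1 - epsilon} for the dosage of the diplotype and \code{epsilon / 2}
#' for each of the two other dosages.  A missing observation is
#' uninformative (likelihood 1).
#'
#' @param observed Genotype dosage 0, 1, 2 or \code{NA} (missing).
#' @param d Diplotype code 0..3.
#' @param epsilon Genotyping error probability in [0, 0.5).
#' @return Likelihood value.
#' @export
genotype_likelihood <- function(observed, d, epsilon = 0) {
  stopifnot(d %in% 0:3, epsilon >= 0, epsilon < 0.5)
  if (is.na(observed)) return(1)
  if (!observed %in% 0:2) stop("invalid genotype code: ", observed)
  dose <- d %/% 2L + d %% 2L
  if (observed == dose) 1 - epsilon else epsilon / 2
}

#' Enumerate IBD configurations of four haplotypes
#'
#' Exhaustively partitions the four labeled haplotypes of a pair of diploid
#' individuals (a1, a2, b1, b2) into IBD-equivalence classes.  There are 15
#' such set partitions; the five-state pairwise model keeps those in which
#' either no haplotypes are IBD or exactly one cross-individual pair is IBD.
#' The remaining ten involve within-individual IBD (homozygosity by descent)
#' or multiple sharing and are deliberately outside the model.
#'
#' @return Data frame with one row per partition: a \code{partition} string,
#'   and \code{modeled} indicating whether the five-state model keeps it.
#' @export
ibd_configurations <- function() {
  items <- c("a1", "a2", "b1", "b2")
  # enumerate set partitions by restricted-growth strings
  parts <- list()
  rec <- function(assign, k) {
    i <- length(assign) + 1L
    if (i > 4L) {
      parts[[length(parts) + 1L]] <<- assign
      return()
    }
    for (b in seq_len(k + 1L)) rec(c(assign, b), max(k, b))
  }
  rec(integer(0), 0L)
  desc <- vapply(parts, function(p) {
    paste(vapply(split(items, p), paste, "", collapse = "="),
          collapse = " | ")
  }, "")
  modeled <- vapply(parts, function(p) {
    sizes <- table(p)
    if (all(sizes == 1)) return(TRUE)        # NONIBD
    if (sum(sizes == 2) == 1 && all(sizes <= 2)) {
      pair <- names(sizes)[sizes == 2]
      merged <- items[p == as.integer(pair)]
      # exactly one doubleton, and it spans the two individuals
      return(length(unique(substr(merged, 1, 1))) == 2)
    }
    FALSE
  }, TRUE)
  data.frame(partition = desc, modeled = modeled)
}
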