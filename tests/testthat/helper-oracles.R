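# Independent oracles used across the suite.  All are brute-force or
# closed-form computations kept deliberately separate from the package's
# dynamic-programming / message-passing code paths.

# Matrix exponential by truncated Taylor series (k terms).
taylor_expm <- function(A, k = 30) {
  out <- diag(nrow(A))
  term <- diag(nrow(A))
  for (i in seq_len(k)) {
    term <- term %*% A / i
    out <- out + term
  }
  out
}

# Per-state observation likelihoods for a genotype pair at one marker,
# from the scalar emission and genotype-likelihood primitives.
obs_vector <- function(ga, gb, f, epsilon = 0) {
  ga <- ifelse(is.na(ga), NA, ga)
  vapply(1:5, function(s) {
    acc <- 0
    for (da in 0:3) for (db in 0:3)
      acc <- acc + emission_prob(s, da, db, f) *
        genotype_likelihood(ga, da, epsilon) *
        genotype_likelihood(gb, db, epsilon)
    acc
  }, 0)
}

# Exhaustive-path Forward-Backward oracle: per-marker posteriors of the
# 5-state pair HMM by summing over all 5^m hidden paths.
fb_enum_oracle <- function(geno_a, geno_b, map, params, freqs) {
  m <- length(geno_a)
  obs <- sapply(seq_len(m), function(j)
    obs_vector(geno_a[j], geno_b[j], freqs[j], params$epsilon))  # 5 x m
  Q <- build_rate_matrix(params)
  Tm <- lapply(seq_len(m - 1), function(j)
    transition_matrix(Q, map$morgans[j + 1] - map$morgans[j],
                      params$kappa))
  pi0 <- stationary_ibd_prior(params)
  paths <- as.matrix(expand.grid(rep(list(1:5), m)))
  pr <- pi0[paths[, 1]] * obs[cbind(paths[, 1], 1)]
  for (j in 2:m)
    pr <- pr * Tm[[j - 1]][cbind(paths[, j - 1], paths[, j])] *
      obs[cbind(paths[, j], j)]
  post <- matrix(0, 5, m)
  for (j in seq_len(m))
    post[, j] <- vapply(1:5, function(s) sum(pr[paths[, j] == s]), 0)
  sweep(post, 2, colSums(post), "/")
}

# Negative-log joint score of a complete (h, p) assignment for a single
# pair over the full marker range, matching the phaser's model: uniform
# diplotype prior (constant, dropped), genotype likelihood factors,
# hard per-individual anchors, and the Bayes-inverted IBD-indicator CPT
# chain started from the unconditional IBD prior.
joint_neglog <- function(geno_a, geno_b, map, params, freqs, ha, hb, p,
                         anchors = c(NA, NA)) {
  m <- length(geno_a)
  nl <- function(x) if (x > 0) -log(x) else 700
  s <- 0
  for (j in seq_len(m)) {
    s <- s + nl(genotype_likelihood(geno_a[j], ha[j], params$epsilon)) +
      nl(genotype_likelihood(geno_b[j], hb[j], params$epsilon))
    if (!is.na(anchors[1]) && anchors[1] == j && ha[j] != 2) s <- s + 700
    if (!is.na(anchors[2]) && anchors[2] == j && hb[j] != 2) s <- s + 700
    cpt <- if (j == 1)
      ibd_cpt(ha[j], hb[j], prev = NULL, t = 0, f = freqs[j], params)
    else
      ibd_cpt(ha[j], hb[j], prev = p[j - 1],
              t = map$morgans[j] - map$morgans[j - 1], f = freqs[j],
              params)
    s <- s + nl(cpt[[p[j]]])
  }
  unname(s)
}

# Exact MAP score for a single pair by exhaustive enumeration over all
# genotype-consistent diplotype configurations with an inner Viterbi over
# the 5-state indicator chain.  Only feasible for a handful of markers.
map_enum_oracle <- function(geno_a, geno_b, map, params, freqs,
                            anchors = c(NA, NA)) {
  m <- length(geno_a)
  opts <- function(g, anchor_here) {
    o <- if (is.na(g)) 0:3 else switch(g + 1, 0L, c(1L, 2L), 3L)
    if (anchor_here) o <- intersect(o, 2L)
    o
  }
  best <- Inf
  oa <- lapply(seq_len(m), function(j)
    opts(geno_a[j], !is.na(anchors[1]) && anchors[1] == j))
  ob <- lapply(seq_len(m), function(j)
    opts(geno_b[j], !is.na(anchors[2]) && anchors[2] == j))
  ha_grid <- as.matrix(expand.grid(oa))
  hb_grid <- as.matrix(expand.grid(ob))
  nl <- function(x) ifelse(x > 0, -log(x), 700)
  for (ia in seq_len(nrow(ha_grid))) for (ib in seq_len(nrow(hb_grid))) {
    ha <- ha_grid[ia, ]; hb <- hb_grid[ib, ]
    # Viterbi over the p chain for this diplotype configuration
    v <- nl(ibd_cpt(ha[1], hb[1], NULL, 0, freqs[1], params))
    for (j in 2:m) {
      step <- sapply(1:5, function(prev)
        nl(ibd_cpt(ha[j], hb[j], prev,
                   map$morgans[j] - map$morgans[j - 1], freqs[j],
                   params)))  # 5 (p_j) x 5 (prev)... rows p_j
      v <- apply(t(step) + v, 2, min)  # min over prev for each p_j
    }
    sc <- min(v)  # genotype factors are zero for consistent h, eps = 0
    if (params$epsilon > 0)
      sc <- sc + sum(nl(mapply(genotype_likelihood, geno_a, ha,
                               MoreArgs = list(epsilon = params$epsilon))),
                     nl(mapply(genotype_likelihood, geno_b, hb,
                               MoreArgs = list(epsilon = params$epsilon))))
    if (sc < best) best <- sc
  }
  best
}

# Convenience: wrap a dosage matrix plus frequency vector for the phaser
# without the constructor's reorientation.  Columns are first nudged to be
# polymorphic and minor-oriented so that nothing is dropped or flipped and
# the marker map stays aligned.
as_gm <- function(geno, f, bp = NULL) {
  nonmiss <- colSums(!is.na(geno))
  p <- colSums(geno, na.rm = TRUE) / (2 * nonmiss)
  flip <- p > 0.5
  for (j in which(flip)) geno[, j] <- 2L - geno[, j]
  for (j in which(p %in% c(0, 1))) {
    i <- which(!is.na(geno[, j]))[1]
    geno[i, j] <- 1L
  }
  gm <- genotype_matrix(geno, bp = bp)
  stopifnot(ncol(gm$geno) == ncol(geno), !any(gm$flipped))
  # keep the handed-in frequencies aligned with the reoriented coding
  gm$f <- ifelse(flip, 1 - f, f)
  gm
}

# Wrap genotypes + known truth frequencies verbatim (no reorientation):
# with a handful of individuals the realized-frequency reorientation of the
# constructor conditions on the data and distorts the likelihood, which is
# exactly why production code estimates f from the whole sample.
raw_gm <- function(geno, f) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("ind%04d", seq_len(nrow(geno)))
  structure(list(geno = geno, f = f, bp = NULL, chrom = "1",
                 flipped = rep(FALSE, ncol(geno)),
                 kept = seq_len(ncol(geno))),
            class = "genotype_matrix")
}

flat_map <- function(m, length_morgans = 0.01 * (m - 1), chrom = "1") {
  genetic_map(chrom, sprintf("t%03d", 1:m), seq_len(m) * 1000,
              seq(0, length_morgans * 100, length.out = m))
}

full_segment <- function(m, a = 1L, b = 2L)
  data.frame(a = a, b = b, start = 0L, end = m,
             peak_posterior = 1, genetic_length = NA_real_)

# Anchors as phase_genotypes derives them for a fully covered pair: among
# heterozygous sites whose partner is homozygous there (else all hets),
# the one nearest the midpoint of the marker range; 1-based, NA when the
# individual has no het site.
first_het_anchor <- function(g, gpartner) {
  het <- which(!is.na(g) & g == 1L)
  if (!length(het)) return(NA_integer_)
  inf <- het[!is.na(gpartner[het]) & gpartner[het] != 1L]
  pool <- if (length(inf)) inf else het
  mid <- (1 + length(g)) / 2
  pool[which.min(abs(pool - mid))]
}
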