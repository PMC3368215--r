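# Min-Sum phaser: CPT inversion, tree exactness, calling behavior.

test_that("IBD-indicator CPT matches direct Bayes computation", {
  p <- model_params()
  # opposite homozygotes: all IBD emissions zero, mass on NONIBD
  cpt <- ibd_cpt(3, 0, prev = 1, t = 1e-4, f = 0.3, params = p)
  expect_equal(unname(cpt), c(1, 0, 0, 0, 0))
  # zero distance from an IBD state with compatible diplotypes stays put
  cpt <- ibd_cpt(3, 3, prev = "S11", t = 0, f = 0.3, params = p)
  expect_equal(unname(cpt), c(0, 1, 0, 0, 0))
  # random draws against a scalar 5-term normalization oracle
  set.seed(41)
  for (i in 1:25) {
    f <- runif(1, 0.05, 0.95)
    t <- runif(1, 0, 0.01)
    prev <- sample(1:5, 1)
    da <- sample(0:3, 1); db <- sample(0:3, 1)
    trow <- transition_matrix(build_rate_matrix(p), t, p$kappa)[prev, ]
    e <- vapply(1:5, function(s) emission_prob(s, da, db, f), 0)
    expect_equal(unname(ibd_cpt(da, db, prev, t, f, p)),
                 unname(trow * e / sum(trow * e)), tolerance = 1e-12)
  }
})

test_that("the restricted graph creates the expected variables", {
  # one segment over pair (1,2), markers [5,10): 2 x 5 diplotype variables
  set.seed(43)
  m <- 12
  map <- flat_map(m)
  f <- rep(0.4, m)
  repeat {
    g <- matrix(rbinom(3 * m, 2, 0.4), 3, m)
    if (all(colSums(g) > 0) && all(colSums(g) <= 3)) break
  }
  gm <- as_gm(g, f)
  segs <- data.frame(a = 1L, b = 2L, start = 5L, end = 10L,
                     peak_posterior = 1, genetic_length = NA)
  res <- phase_genotypes(gm, map, model_params(), segments = segs)
  expect_length(res$seg_states[[1]], 5)
  # the third individual has no diplotype variables at all
  expect_false(any(res$phased[3, ] & g[3, ] == 1))
  # heterozygous sites outside every segment stay unphased
  outside_het <- g == 1
  outside_het[, 6:10] <- FALSE
  expect_false(any(res$phased[outside_het]))
})

test_that("Min-Sum equals the exhaustive MAP oracle on trees", {
  # a single pair over one full-length segment is cycle-free, so the
  # damped Min-Sum fixed point must attain the exact MAP score
  set.seed(47)
  p0 <- model_params()
  for (i in 1:15) {
    m <- sample(3:4, 1)
    map <- flat_map(m, length_morgans = runif(1, 0.005, 0.05))
    f <- runif(m, 0.1, 0.5)
    repeat {
      g <- matrix(rbinom(2 * m, 2, rep(f, each = 2)), 2, m)
      if (all(colSums(g) > 0) && all(colMeans(g) / 2 <= 0.5)) break
    }
    gm <- as_gm(g, f)
    for (damping in c(0, 0.5)) {
      # phase_margin ~ 0: call whenever the max-marginals are not tied, so
      # the assembled configuration is the Min-Sum argmax itself
      p <- model_params(damping = damping, phase_margin = 1e-9)
      res <- phase_genotypes(gm, map, p, segments = full_segment(m))
      anchors <- c(first_het_anchor(g[1, ], g[2, ]), first_het_anchor(g[2, ], g[1, ]))
      # assemble the Min-Sum MAP configuration from beliefs + chain states
      dip <- function(i, j) {
        if (!is.na(g[i, j]) && g[i, j] != 1)
          return(c(0L, 3L)[g[i, j] / 2 + 1])
        if (isTRUE(res$phased[i, j]))
          return(2L * res$h1[i, j] + res$h2[i, j])
        # unphased heterozygote: either ordering attains the optimum
        2L
      }
      ha <- vapply(1:m, function(j) dip(1, j), 0L)
      hb <- vapply(1:m, function(j) dip(2, j), 0L)
      score <- joint_neglog(g[1, ], g[2, ], map, p, gm$f, ha, hb,
                            res$seg_states[[1]], anchors)
      oracle <- map_enum_oracle(g[1, ], g[2, ], map, p, gm$f, anchors)
      expect_equal(score, oracle, tolerance = 1e-4)
    }
  }
})

test_that("all genotypes missing leave everything unphased", {
  m <- 8
  map <- flat_map(m)
  gm <- structure(list(geno = matrix(NA_integer_, 2, m,
                                     dimnames = list(c("a", "b"), NULL)),
                       f = rep(0.3, m), bp = NULL, chrom = "1",
                       flipped = rep(FALSE, m), kept = 1:m),
                  class = "genotype_matrix")
  res <- phase_genotypes(gm, map, model_params(),
                         segments = full_segment(m))
  expect_false(any(res$phased))
  expect_true(all(is.na(res$h1)))
})

test_that("the core long-range deduction phases a duo heterozygote", {
  # individuals IBD on haplotype (1,1) across the chromosome; where one is
  # homozygous and the other het, the shared allele lands on haplotype 1
  set.seed(53)
  m <- 200
  map <- flat_map(m, length_morgans = 0.1)
  f <- runif(m, 0.2, 0.5)
  shared <- rbinom(m, 1, f)
  oa <- rbinom(m, 1, f); ob <- rbinom(m, 1, f)
  g <- rbind(shared + oa, shared + ob)
  gm <- as_gm(g, f)
  # keep the truth haplotype in the (possibly reoriented) minor coding
  shared_m <- ifelse(colSums(g) > 2, 1L - shared, shared)
  res <- phase_genotypes(gm, map, model_params(),
                         segments = full_segment(m))
  st <- res$seg_states[[1]]
  expect_gt(mean(st > 1), 0.9)
  # configuration must be constant where called (no spurious flips)
  expect_lte(length(rle(st[st > 1])$values), 2)
  cfg <- as.integer(names(which.max(table(st[st > 1]))))
  hap_a <- c(1, 1, 2, 2)[cfg - 1]  # which haplotype of a carries the share
  called_het <- which(gm$geno[1, ] == 1 & gm$geno[2, ] != 1 &
                        res$phased[1, ] & st == cfg)
  ha <- if (hap_a == 1) res$h1 else res$h2
  expect_gt(length(called_het), 20)
  expect_true(all(ha[1, called_het] == shared_m[called_het]))
})

test_that("phase calls always reproduce observed genotypes when eps = 0", {
  set.seed(59)
  m <- 300
  map <- flat_map(m, length_morgans = 0.15)
  f <- runif(m, 0.1, 0.5)
  h <- matrix(rbinom(8 * m, 1, rep(f, each = 8)), 8, m)
  h[3, 51:250] <- h[1, 51:250]  # share a long haplotype across two pairs
  h[5, 101:300] <- h[2, 101:300]
  g <- h[c(1, 3, 5, 7), ] + h[c(2, 4, 6, 8), ]
  gm <- as_gm(g, f)
  res <- phase_genotypes(gm, map, model_params())
  called <- res$phased & !is.na(gm$geno)
  expect_true(all((res$h1 + res$h2)[called] == gm$geno[called]))
  # margins are nonnegative wherever defined
  expect_true(all(res$margin[!is.na(res$margin)] >= 0))
})

test_that("IBD and phase calls cohere and runs split at flips", {
  # MAP chain NONIBD x3, S11 x5, NONIBD x2 -> a single 5-marker call
  fake <- structure(list(
    segments = data.frame(a = 1L, b = 2L, start = 0L, end = 10L),
    seg_states = list(c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 1L, 1L))),
    class = "phase_result")
  map <- flat_map(10)
  calls <- extract_ibd_calls(fake, map)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, 3L)
  expect_equal(calls$end, 8L)
  expect_equal(calls$n_markers, 5L)
  expect_equal(c(calls$hap_a, calls$hap_b), c(1L, 1L))
  # a flip S11 -> S12 mid-run gives two calls sharing a boundary
  fake$seg_states <- list(c(2L, 2L, 2L, 3L, 3L, 1L, 1L, 1L, 1L, 1L))
  calls <- extract_ibd_calls(fake, map)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$end[1], calls$start[2])
  expect_equal(calls$hap_b, c(1L, 2L))
})

test_that("imputation calls alleles only through MAP IBD links", {
  set.seed(61)
  m <- 200
  map <- flat_map(m, length_morgans = 0.1)
  f <- runif(m, 0.2, 0.5)
  shared <- rbinom(m, 1, f)
  g <- rbind(shared + rbinom(m, 1, f), shared + rbinom(m, 1, f),
             rbinom(m, 2L, f))  # third, unrelated individual
  # hide one of a's genotypes where the partner is homozygous; keep the
  # column polymorphic and minor-oriented through the third individual
  j0 <- which(g[2, ] != 1)
  j0 <- j0[which.min(abs(j0 - 100))]
  g[1, j0] <- NA
  g[3, j0] <- if (shared[j0] == 1L) 0L else 1L
  gm <- as_gm(g, f)
  res <- phase_genotypes(gm, map, model_params(),
                         segments = full_segment(m))
  # haplotype on the shared side recovers the shared allele
  st <- res$seg_states[[1]]
  expect_gt(st[j0], 1)
  hap_a <- c(1, 1, 2, 2)[st[j0] - 1]
  ha <- if (hap_a == 1) res$h1 else res$h2
  expect_false(is.na(ha[1, j0]))
  expect_equal(ha[1, j0], shared[j0])
  # the same missing site stays uncalled when no segment covers it
  seg_part <- data.frame(a = 1L, b = 2L, start = 150L, end = 200L,
                         peak_posterior = 1, genetic_length = NA)
  res2 <- phase_genotypes(gm, map, model_params(), segments = seg_part)
  expect_true(is.na(res2$h1[1, j0]) && is.na(res2$h2[1, j0]))
  expect_false(res2$imputed[1, j0])
})

test_that("phasing is deterministic for identical inputs", {
  set.seed(67)
  m <- 150
  map <- flat_map(m, length_morgans = 0.08)
  f <- runif(m, 0.2, 0.5)
  shared <- rbinom(m, 1, f)
  g <- rbind(shared + rbinom(m, 1, f), shared + rbinom(m, 1, f),
             rbinom(m, 2, f))
  gm <- as_gm(g, f)
  r1 <- phase_genotypes(gm, map, model_params())
  r2 <- phase_genotypes(gm, map, model_params())
  expect_identical(r1$h1, r2$h1)
  expect_identical(r1$h2, r2$h2)
  expect_identical(r1$margin, r2$margin)
  expect_identical(r1$ibd_calls, r2$ibd_calls)
})

test_that("an empty segment list yields an all-unphased result", {
  m <- 20
  map <- flat_map(m)
  g <- matrix(rep(c(1L, 0L), m), 2, m)
  gm <- as_gm(g, rep(0.25, m))
  expect_warning(res <- phase_genotypes(gm, map, model_params(),
                                        segments = scan_all_pairs(
                                          gm, map, model_params())[0, ]),
                 "unphased")
  expect_false(any(res$phased & gm$geno == 1))
})
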