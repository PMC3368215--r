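# Founder-population simulator: demography, recombination, truth tracking.

test_that("census trajectory follows rounded exponential growth", {
  d <- demography_config()
  sizes <- census_trajectory(d)
  r <- (18000 / 100)^(1 / 12)
  expect_equal(sizes, as.integer(round(100 * r^(0:12))))
  expect_equal(sizes[13], 18000L)
  expect_error(demography_config(sample_size = 20000), "exceeds")
})

test_that("founder haplotypes realize the frequency spectrum", {
  set.seed(71)
  fh <- make_founder_haplotypes(100, 1000)
  expect_equal(dim(fh$haps), c(200, 1000))
  realized <- colMeans(fh$haps)
  expect_gt(mean(realized), 0.24)
  expect_lt(mean(realized), 0.31)
  # constant spectrum stays within 3 binomial standard deviations
  fh5 <- make_founder_haplotypes(100, 500,
                                 freq_spec = function(m) rep(0.5, m))
  sd3 <- 3 * sqrt(0.25 / 200)
  expect_gt(mean(abs(colMeans(fh5$haps) - 0.5) <= sd3), 0.99)
  # reproducibility under the seed
  set.seed(72); a <- make_founder_haplotypes(10, 50)
  set.seed(72); b <- make_founder_haplotypes(10, 50)
  set.seed(73); c3 <- make_founder_haplotypes(10, 50)
  expect_identical(a, b)
  expect_false(identical(a$haps, c3$haps))
  expect_error(make_founder_haplotypes(10, 50,
                                       freq_spec = function(m) rep(1, m)),
               "strictly inside")
})

test_that("crossover counts follow the genetic length", {
  set.seed(79)
  L <- 1.09
  h1 <- list(br = L, lab = 1L)
  h2 <- list(br = L, lab = 2L)
  # with distinct labels on the two parental haplotypes, gamete pieces - 1
  # equals the realized crossover count of the transmission
  nxo <- replicate(10000, length(ibdphase:::.gamete(h1, h2, L)$lab) - 1L)
  expect_gt(mean(nxo), 1.05)
  expect_lt(mean(nxo), 1.13)
  # gamete pieces tile the chromosome for random cut sets
  for (i in 1:50) {
    cuts <- sort(runif(rpois(1, 3), 0, L))
    gam <- ibdphase:::cpp_recombine(h1$br, h1$lab, h2$br, h2$lab, cuts,
                                    sample(2, 1))
    expect_equal(gam$br[length(gam$br)], L)
    expect_true(all(diff(gam$br) > 0))
    expect_length(gam$lab, length(gam$br))
    expect_true(all(gam$lab %in% 1:2))
    expect_true(all(diff(gam$lab) != 0))  # adjacent pieces merged
  }
})

test_that("zero generations returns the founders themselves", {
  set.seed(83)
  d <- demography_config(n_founders = 20, final_size = 20,
                         generations = 0, sample_size = 20)
  mos <- evolve_population(d, 0.5)
  expect_length(mos, 40)
  expect_true(all(vapply(mos, function(h) length(h$lab) == 1, TRUE)))
  expect_setequal(vapply(mos, function(h) h$lab, 1L), 1:40)
})

test_that("mosaics always tile the chromosome exactly", {
  set.seed(89)
  d <- demography_config(n_founders = 10, final_size = 80,
                         generations = 4, sample_size = 30)
  mos <- evolve_population(d, 1.2)
  for (h in mos) {
    expect_equal(h$br[length(h$br)], 1.2)
    expect_true(all(diff(c(0, h$br)) > 0))
    expect_true(all(h$lab >= 1 & h$lab <= 20))
  }
})

test_that("genotype realization copies founder alleles by position", {
  set.seed(97)
  map <- flat_map(50, length_morgans = 1)
  fh <- make_founder_haplotypes(5, 50)
  # hand-built mosaic: founder hap 3 up to 0.4 M, then founder hap 7
  mos <- list(list(br = c(0.4, 1), lab = c(3L, 7L)),
              list(br = 1, lab = 10L))
  labs <- mosaic_labels(mos, map)
  # independent interval-lookup oracle
  expected <- ifelse(map$morgans <= 0.4, 3L, 7L)
  expect_equal(labs[1, ], expected)
  expect_equal(labs[2, ], rep(10L, 50))
  real <- realize_genotypes(labs, fh$haps)
  expect_equal(real$h1[1, ], fh$haps[cbind(expected, 1:50)])
  expect_equal(real$geno, real$h1 + real$h2)
})

test_that("truth IBD equals the per-marker label-run oracle", {
  map <- flat_map(20, length_morgans = 0.2)
  labs <- rbind(c(rep(1L, 8), rep(2L, 12)),   # a hap 1
                rep(3L, 20),                  # a hap 2
                c(rep(1L, 12), rep(4L, 8)),   # b hap 1
                rep(5L, 20))                  # b hap 2
  tr <- true_ibd(labs, 1, 2, map)
  expect_equal(nrow(tr), 1)
  expect_equal(c(tr$hap_a, tr$hap_b), c(1L, 1L))
  expect_equal(c(tr$start, tr$end), c(0L, 8L))
  expect_equal(tr$length_cm, (map$morgans[8] - map$morgans[1]) * 100)
  # disjoint founder labels share nothing
  expect_equal(nrow(true_ibd(labs[c(2, 2, 4, 4), ], 1, 2, map)), 0)
  # random small mosaics against brute-force per-marker comparison
  set.seed(101)
  for (i in 1:20) {
    labs <- matrix(sample(1:4, 4 * 15, replace = TRUE), 4, 15)
    tr <- true_ibd(labs, 1, 2, map[1:15, ])
    per_marker <- matrix(FALSE, 4, 15)
    k <- 0
    for (ha in 1:2) for (hb in 1:2) {
      k <- k + 1
      per_marker[k, ] <- labs[ha, ] == labs[2 + hb, ]
    }
    covered <- matrix(FALSE, 4, 15)
    for (r in seq_len(nrow(tr))) {
      cfg <- 2 * (tr$hap_a[r] - 1) + tr$hap_b[r]
      covered[cfg, (tr$start[r] + 1):tr$end[r]] <- TRUE
    }
    expect_identical(covered, per_marker)
  }
})

test_that("truth IBD is symmetric and allele-consistent", {
  set.seed(103)
  map <- synthetic_map(300, length_morgans = 0.4, seed = 7)
  d <- demography_config(n_founders = 30, final_size = 300,
                         generations = 6, sample_size = 25)
  sim <- simulate_founder_population(map, d)
  tr12 <- true_ibd(sim$labels, 1, 2, sim$map)
  tr21 <- true_ibd(sim$labels, 2, 1, sim$map)
  expect_equal(tr12$start, tr21$start[order(tr21$hap_b, tr21$hap_a)])
  haps <- list(sim$h1, sim$h2)
  for (r in seq_len(nrow(tr12))) {
    span <- (tr12$start[r] + 1):tr12$end[r]
    expect_equal(haps[[tr12$hap_a[r]]][1, span],
                 haps[[tr12$hap_b[r]]][2, span])
  }
})

test_that("noise injection realizes the requested rates", {
  set.seed(107)
  g <- matrix(rbinom(1e6, 2, 0.3), 1000, 1000)
  out <- add_noise(g, missing_rate = 0.05)
  expect_gt(mean(is.na(out$geno)), 0.0493)
  expect_lt(mean(is.na(out$geno)), 0.0507)
  expect_identical(add_noise(g, 0, 0)$geno, g)
  # errors always change the genotype, at the per-marker rate
  rates <- ifelse(runif(1000) < 0.2, 0.10, 0.001)
  out2 <- add_noise(g, error_rate = rates)
  changed <- out2$geno != g
  expect_identical(unname(changed), unname(out2$error_mask))
  # two-tier mixture: overall rate ~ 0.2*0.10 + 0.8*0.001 = 2.08%
  expect_equal(mean(changed), 0.2 * 0.10 + 0.8 * 0.001, tolerance = 0.15)
})

test_that("simulated genotypes are minor-oriented with aligned truth", {
  set.seed(109)
  map <- synthetic_map(250, length_morgans = 0.3, seed = 9)
  d <- demography_config(n_founders = 20, final_size = 200,
                         generations = 5, sample_size = 30)
  sim <- simulate_founder_population(map, d)
  expect_true(all(sim$genotypes$f > 0 & sim$genotypes$f <= 0.5))
  # dosage equals the sum of the two truth haplotypes at every site
  expect_equal(sim$genotypes$geno, sim$h1 + sim$h2, ignore_attr = TRUE)
  expect_equal(nrow(sim$map), ncol(sim$genotypes$geno))
})
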