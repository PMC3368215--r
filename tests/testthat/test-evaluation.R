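# Metrics: switch error, yield, IBD sensitivity/FDR, imputation, trios.

# A minimal phase_result-like object for metric tests.
fake_phase <- function(h1, h2, phased = !is.na(h1) & !is.na(h2)) {
  structure(list(h1 = h1, h2 = h2, phased = phased,
                 imputed = matrix(FALSE, nrow(h1), ncol(h1))),
            class = "phase_result")
}

test_that("switch errors count orientation flips per Morgan", {
  m <- 11
  map <- flat_map(m, length_morgans = 1)  # 1-Morgan chromosome
  t1 <- matrix(1L, 1, m); t2 <- matrix(0L, 1, m)  # all het
  # perfect call: zero switches
  expect_equal(switch_error(t1, t2, fake_phase(t1, t2), map)$per_morgan, 0)
  # one flip halfway: 1 switch / (1 ind x 1 Morgan)
  h1 <- t1; h2 <- t2
  h1[1, 6:11] <- 0L; h2[1, 6:11] <- 1L
  sw <- switch_error(t1, t2, fake_phase(h1, h2), map)
  expect_equal(sw$per_morgan, 1)
  expect_equal(sw$switches, 1L)
  # invariant under flipping the whole individual
  sw_flip <- switch_error(t1, t2, fake_phase(h2, h1), map)
  expect_equal(sw_flip$per_morgan, 1)
  # random orientations: brute-force pairwise comparison agrees, and the
  # expected switch count approaches (k - 1) / 2
  set.seed(113)
  counts <- vapply(1:200, function(i) {
    o <- sample(0:1, m, replace = TRUE)
    h1 <- matrix(o, 1); h2 <- 1L - h1
    sw <- switch_error(t1, t2, fake_phase(h1, h2), map)$switches
    brute <- 0L
    for (j in 2:m) brute <- brute + as.integer(o[j] != o[j - 1])
    expect_equal(sw, brute)
    sw
  }, 0L)
  expect_equal(mean(counts), (m - 1) / 2, tolerance = 0.15)
})

test_that("within-segment switch errors reset at unphased sites", {
  m <- 7
  map <- flat_map(m, length_morgans = 1)
  t1 <- matrix(1L, 1, m); t2 <- matrix(0L, 1, m)
  h1 <- matrix(c(1L, 1L, NA, 0L, 0L, 1L, 1L), 1)
  h2 <- 1L - h1
  ph <- !is.na(h1)
  sw <- switch_error(t1, t2, fake_phase(h1, h2, ph), map)
  # plain walk: flips at 2->4 and 5->6
  expect_equal(sw$switches, 2L)
  # the unphased marker 3 breaks the first comparison: only 5->6 remains
  expect_equal(sw$within_per_morgan, 1)
})

test_that("IBD metrics match a hand-computed worked fixture", {
  # 5 individuals, 20 markers, uniform map of 0.2 Morgans
  map <- flat_map(20, length_morgans = 0.19)
  w <- marker_weights(map)
  expect_equal(sum(w), 0.19)
  truth <- data.frame(a = c(1L, 1L, 2L), b = c(2L, 3L, 4L),
                      hap_a = c(1L, 2L, 1L), hap_b = c(1L, 1L, 2L),
                      start = c(0L, 5L, 10L), end = c(10L, 15L, 20L),
                      n_markers = c(10L, 10L, 10L),
                      length_cm = c(9, 9, 9))
  # calls: half of the first truth interval; one fully false call
  calls <- data.frame(a = c(1L, 4L), b = c(2L, 5L),
                      hap_a = 1L, hap_b = 1L,
                      start = c(0L, 2L), end = c(5L, 8L),
                      n_markers = c(5L, 6L),
                      length_cm = c(4, 5))
  im <- ibd_metrics(calls, truth, map, min_truth_cm = 1)
  # hand computation: marker weights are 0.01 except 0.005 at the two ends
  sens_den <- sum(w[1:10]) + sum(w[6:15]) + sum(w[11:20])
  expect_equal(im$sensitivity, sum(w[1:5]) / sens_den)
  expect_equal(im$fdr, sum(w[3:8]) / (sum(w[1:5]) + sum(w[3:8])))
  # calls == truth gives sensitivity 1, FDR 0
  im2 <- ibd_metrics(truth, truth, map)
  expect_equal(im2$sensitivity, 1)
  expect_equal(im2$fdr, 0)
  expect_equal(im2$sensitivity_config, 1)
  # empty calls: sensitivity 0, FDR undefined
  im3 <- ibd_metrics(calls[0, ], truth, map)
  expect_equal(im3$sensitivity, 0)
  expect_true(is.nan(im3$fdr))
})

.mask_of_test <- function(tab, m) {
  mask <- logical(m)
  for (r in seq_len(nrow(tab)))
    mask[(tab$start[r] + 1L):tab$end[r]] <- TRUE
  mask
}

test_that("raising the truth-length floor shrinks the truth denominator", {
  # Sensitivity itself is NOT monotone in the floor: excluding short truth
  # segments removes them from numerator and denominator alike, and short
  # segments are the hardest to detect, so sensitivity typically rises
  # with the floor.  The monotone quantity is the truth length retained.
  set.seed(127)
  map <- flat_map(100, length_morgans = 0.5)
  mk <- function(n) {
    s <- sort(sample(0:98, n))
    e <- pmin(s + sample(2:30, n, replace = TRUE), 100L)
    data.frame(a = 1L, b = 2L, hap_a = 1L, hap_b = 1L, start = s, end = e,
               n_markers = e - s,
               length_cm = (map$morgans[e] - map$morgans[s + 1]) * 100)
  }
  truth <- mk(6); calls <- mk(4)
  floors <- c(0, 1, 3, 6, 10)
  res <- lapply(floors, function(fl) ibd_metrics(calls, truth, map, fl))
  dens <- vapply(res, `[[`, 0, "truth_morgans")
  expect_true(all(diff(dens) <= 1e-12))
  # the FDR does not depend on the sensitivity floor
  fdrs <- vapply(res, `[[`, 0, "fdr")
  expect_true(all(abs(fdrs - fdrs[1]) < 1e-12))
  # with no floor, sensitivity is plain covered/total truth weight
  w <- marker_weights(map)
  tm <- .mask_of_test(truth, 100); cm <- .mask_of_test(calls, 100)
  expect_equal(res[[1]]$sensitivity, sum(w[tm & cm]) / sum(w[tm]))
})

test_that("imputation metrics count fully imputed discordances", {
  truth <- matrix(c(2L, 1L, 0L, 2L), 2, 2)
  h1 <- matrix(c(1L, NA, 0L, NA), 2, 2)
  h2 <- matrix(c(1L, 1L, 1L, NA), 2, 2)
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  im <- imputation_metrics(truth, fake_phase(h1, h2), mask)
  # cells (1,1): 1+1=2 correct; (1,2): 0+1=1 vs truth 0 -> wrong;
  # (2,1): one allele only -> excluded from error, counts 1 allele
  expect_equal(im$n_full, 2L)
  expect_equal(im$imputation_error, 0.5)
  expect_equal(im$allele_yield, 5 / 6)
  # nothing imputed: error undefined, yield zero
  im0 <- imputation_metrics(truth, fake_phase(matrix(NA_integer_, 2, 2),
                                              matrix(NA_integer_, 2, 2)),
                            mask)
  expect_true(is.nan(im0$imputation_error))
  expect_equal(im0$allele_yield, 0)
})

test_that("trio logic phases offspring from homozygous parents", {
  off <- c(1L, 1L, 1L, 0L, 1L, NA)
  fat <- c(2L, 1L, 0L, 2L, 1L, 1L)
  mot <- c(1L, 0L, 1L, 1L, 1L, 1L)
  tr <- trio_truth_phase(off, fat, mot)
  expect_equal(tr$h_pat[1], 1L)            # father hom-minor
  expect_equal(tr$h_mat[1], 0L)
  expect_equal(tr$h_mat[2], 0L)            # mother hom-major
  expect_equal(tr$h_pat[2], 1L)
  expect_equal(tr$h_pat[3], 0L)            # father hom-major
  expect_true(is.na(tr$h_pat[5]))          # both parents het
  expect_equal(tr$mendel_errors, 1L)       # site 4: off hom-major, father 2
  expect_true(is.na(tr$h_pat[4]))
})
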