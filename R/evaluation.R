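# Accuracy metrics: switch errors per Morgan, phasing yield, length-weighted
# IBD sensitivity/FDR, imputation error, and trio-based truth phasing.

#' Switch errors against truth haplotypes
#'
#' Walks each individual's phased heterozygous sites in map order and counts
#' transitions where the relative orientation versus the truth flips.  The
#' rate normalizes total switches by (number of individuals x chromosome
#' genetic length in Morgans) and is invariant to flipping any individual's
#' entire haplotype pair.  The within-segment variant restricts comparisons
#' to consecutive heterozygous sites with no intervening unphased
#' heterozygote, so that refusals break the comparison chain.
#'
#' Only sites where both truth and call are heterozygous (correctly
#' genotyped heterozygotes) enter the comparison.
#'
#' @param truth_h1,truth_h2 n x m truth haplotype matrices (minor-allele
#'   coded, as from \code{\link{simulate_founder_population}}).
#' @param phase A \code{\link{phase_genotypes}} result.
#' @param map A \code{\link{genetic_map}}.
#' @return List: \code{switches} (per-individual counts),
#'   \code{per_morgan} (mean switch errors per Morgan),
#'   \code{within_per_morgan} (within-phased-segments variant),
#'   \code{n_compared} (orientation comparisons made).
#' @export
switch_error <- function(truth_h1, truth_h2, phase, map) {
  n <- nrow(truth_h1); m <- ncol(truth_h1)
  L <- map$morgans[m] - map$morgans[1]
  switches <- integer(n)
  within <- integer(n)
  ncomp <- 0L
  for (i in seq_len(n)) {
    t_het <- truth_h1[i, ] != truth_h2[i, ]
    c_het <- !is.na(phase$h1[i, ]) & !is.na(phase$h2[i, ]) &
      phase$h1[i, ] != phase$h2[i, ]
    use <- which(t_het & c_het & phase$phased[i, ])
    if (length(use) >= 2) {
      o <- phase$h1[i, use] == truth_h1[i, use]
      flip <- diff(o) != 0
      switches[i] <- sum(flip)
      ncomp <- ncomp + length(use) - 1L
      # within-segment: reset at unphased heterozygotes between the sites
      unph <- t_het & !phase$phased[i, ]
      cum_unph <- cumsum(unph)
      contiguous <- diff(cum_unph[use]) == 0
      within[i] <- sum(flip & contiguous)
    }
  }
  list(switches = switches,
       per_morgan = sum(switches) / (n * L),
       within_per_morgan = sum(within) / (n * L),
       n_compared = ncomp)
}

#' Phasing yield
#'
#' Fraction of observed heterozygous sites for which a phase call was made.
#'
#' @param phase A \code{\link{phase_genotypes}} result.
#' @param genotypes The phased \code{\link{genotype_matrix}}.
#' @return Yield fraction in [0, 1].
#' @export
phasing_yield <- function(phase, genotypes) {
  het <- !is.na(genotypes$geno) & genotypes$geno == 1L
  sum(phase$phased & het) / sum(het)
}

# Pair-keyed marker mask union of half-open intervals.
.mask_of <- function(tab, m) {
  mask <- logical(m)
  for (r in seq_len(nrow(tab)))
    mask[(tab$start[r] + 1L):tab$end[r]] <- TRUE
  mask
}

#' Length-weighted IBD detection metrics
#'
#' Compares called IBD segments to truth IBD intervals in units of
#' (pair, marker) cells weighted by local genetic length.  Sensitivity is
#' the covered fraction of truth length, with truth intervals shorter than
#' \code{min_truth_cm} excluded from the denominator; the false discovery
#' rate is the called length not overlapping any truth interval (no length
#' floor) over total called length.  The headline metrics ignore the
#' haplotype configuration (pair-level overlap); configuration-resolved
#' variants are also reported.
#'
#' @param calls Data frame from \code{\link{extract_ibd_calls}}.
#' @param truth Data frame from \code{\link{true_ibd_all_pairs}} (same
#'   schema).
#' @param map A \code{\link{genetic_map}}.
#' @param min_truth_cm Truth-length floor for the sensitivity denominator
#'   (cM).
#' @return List: \code{sensitivity}, \code{fdr} (NaN when nothing called),
#'   \code{sensitivity_config}, \code{fdr_config}, and the weighted truth /
#'   called totals in Morgans.
#' @export
ibd_metrics <- function(calls, truth, map, min_truth_cm = 1) {
  m <- nrow(map)
  w <- marker_weights(map)
  key <- function(tab) paste(tab$a, tab$b, sep = ":")
  ck <- key(calls); tk <- key(truth)
  truth_f <- truth[truth$length_cm >= min_truth_cm, , drop = FALSE]
  tfk <- key(truth_f)
  sens_num <- sens_den <- fdr_num <- fdr_den <- 0
  sens_num_c <- sens_den_c <- fdr_num_c <- fdr_den_c <- 0
  for (pk in unique(c(ck, tk))) {
    cs <- calls[ck == pk, , drop = FALSE]
    ts <- truth[tk == pk, , drop = FALSE]
    tf <- truth_f[tfk == pk, , drop = FALSE]
    cmask <- if (nrow(cs)) .mask_of(cs, m) else logical(m)
    tmask <- if (nrow(ts)) .mask_of(ts, m) else logical(m)
    fmask <- if (nrow(tf)) .mask_of(tf, m) else logical(m)
    sens_num <- sens_num + sum(w[fmask & cmask])
    sens_den <- sens_den + sum(w[fmask])
    fdr_num <- fdr_num + sum(w[cmask & !tmask])
    fdr_den <- fdr_den + sum(w[cmask])
    # configuration-resolved: match (hap_a, hap_b) too
    for (ha in 1:2) for (hb in 1:2) {
      csc <- cs[cs$hap_a == ha & cs$hap_b == hb, , drop = FALSE]
      tsc <- ts[ts$hap_a == ha & ts$hap_b == hb, , drop = FALSE]
      tfc <- tf[tf$hap_a == ha & tf$hap_b == hb, , drop = FALSE]
      cm2 <- if (nrow(csc)) .mask_of(csc, m) else logical(m)
      tm2 <- if (nrow(tsc)) .mask_of(tsc, m) else logical(m)
      fm2 <- if (nrow(tfc)) .mask_of(tfc, m) else logical(m)
      sens_num_c <- sens_num_c + sum(w[fm2 & cm2])
      sens_den_c <- sens_den_c + sum(w[fm2])
      fdr_num_c <- fdr_num_c + sum(w[cm2 & !tm2])
      fdr_den_c <- fdr_den_c + sum(w[cm2])
    }
  }
  list(sensitivity = if (sens_den > 0) sens_num / sens_den else 0,
       fdr = if (fdr_den > 0) fdr_num / fdr_den else NaN,
       sensitivity_config = if (sens_den_c > 0)
         sens_num_c / sens_den_c else 0,
       fdr_config = if (fdr_den_c > 0) fdr_num_c / fdr_den_c else NaN,
       truth_morgans = sens_den, called_morgans = fdr_den)
}

#' Imputation accuracy at masked genotypes
#'
#' Error is counted as discordance with the held-out genotype at cells the
#' phaser imputed fully (both alleles); the allele yield counts imputed
#' alleles over all masked alleles.
#'
#' @param truth_geno n x m dosage matrix before masking.
#' @param phase A \code{\link{phase_genotypes}} result on the masked data.
#' @param mask Logical n x m matrix marking the masked cells.
#' @return List: \code{imputation_error} (NaN when nothing fully imputed),
#'   \code{allele_yield}, \code{n_full} (fully imputed cells),
#'   \code{n_masked}.
#' @export
imputation_metrics <- function(truth_geno, phase, mask) {
  idx <- which(mask)
  a1 <- phase$h1[idx]; a2 <- phase$h2[idx]
  full <- !is.na(a1) & !is.na(a2)
  err <- if (any(full))
    mean((a1[full] + a2[full]) != truth_geno[idx][full]) else NaN
  yield <- (sum(!is.na(a1)) + sum(!is.na(a2))) / (2 * length(idx))
  list(imputation_error = err, allele_yield = yield,
       n_full = sum(full), n_masked = length(idx))
}

#' Trio-based truth phasing
#'
#' Phases an offspring at sites where it is heterozygous and at least one
#' parent is homozygous: the offspring allele matching the homozygous
#' parent is assigned to that parent's haplotype.  Mendelian-inconsistent
#' sites are excluded and counted.
#'
#' @param offspring,father,mother Genotype dosage vectors (0, 1, 2,
#'   \code{NA}).
#' @return List: \code{h_pat}, \code{h_mat} (partial haplotypes, \code{NA}
#'   where trio logic cannot phase), \code{mendel_errors} (count of
#'   excluded inconsistent sites).
#' @export
trio_truth_phase <- function(offspring, father, mother) {
  m <- length(offspring)
  h_pat <- rep(NA_integer_, m)
  h_mat <- rep(NA_integer_, m)
  mend <- (!is.na(offspring) & !is.na(father) &
             ((offspring == 0 & father == 2) |
                (offspring == 2 & father == 0))) |
    (!is.na(offspring) & !is.na(mother) &
       ((offspring == 0 & mother == 2) | (offspring == 2 & mother == 0)))
  het <- !is.na(offspring) & offspring == 1L & !mend
  fhom <- het & !is.na(father) & father != 1L
  h_pat[fhom] <- father[fhom] %/% 2L
  h_mat[fhom] <- 1L - h_pat[fhom]
  mhom <- het & !is.na(mother) & mother != 1L & is.na(h_pat)
  h_mat[mhom] <- mother[mhom] %/% 2L
  h_pat[mhom] <- 1L - h_mat[mhom]
  list(h_pat = h_pat, h_mat = h_mat, mendel_errors = sum(mend))
}

#' Write a flat key-value metrics report
#'
#' @param metrics Named list of scalar metrics.
#' @param path Output path (tab-separated \code{key value} lines).
#' @export
write_metrics_report <- function(metrics, path) {
  keys <- names(metrics)
  vals <- vapply(metrics, function(v) format(v, digits = 10), "")
  writeLines(paste(keys, vals, sep = "\t"), path)
  invisible(path)
}

#' Write metrics as machine-readable JSON
#'
#' @param metrics Named list of scalar metrics.
#' @param path Output path.
#' @export
write_metrics_json <- function(metrics, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("write_metrics_json needs the jsonlite package")
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
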