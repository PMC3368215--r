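#' Founder-population phasing benchmark
#'
#' Runs the full validation experiment on simulated founder-population
#' replicates: simulate genotypes with truth, phase the error-free data and
#' score switch errors, yield and length-weighted IBD detection against the
#' simulator truth, then mask a fraction of genotypes at random, re-phase
#' and score imputation.  The defaults are the desk-scale configuration
#' (about 2,000 markers over 0.3 Morgans at the density of a dense array,
#' 100 sampled individuals, full 100-founder to 18,000 exponential
#' demography); the full-scale configuration is
#' \code{n_markers = 7505, length_morgans = 1.09, sample_size = 190}.
#'
#' @param seed Base seed; replicate r uses \code{seed * 1000 + r}.
#' @param n_reps Number of simulation replicates.
#' @param n_markers,length_morgans Synthetic map size.
#' @param demography A \code{\link{demography_config}}.
#' @param params Model parameters used for phasing.
#' @param mask_rate Fraction of genotype cells masked for the imputation
#'   arm; 0 skips that arm.
#' @param min_truth_cm Truth-segment floor for IBD sensitivity (cM).
#' @param progress Print one line per replicate.
#' @return Data frame with one row per replicate: \code{switch_per_morgan},
#'   \code{within_per_morgan}, \code{yield}, \code{ibd_fdr},
#'   \code{ibd_sensitivity}, \code{imputation_error}, \code{allele_yield},
#'   \code{n_ind}, \code{n_markers}, \code{converged}.
#' @export
founder_benchmark <- function(seed = 1, n_reps = 5, n_markers = 2000,
                              length_morgans = 0.3,
                              demography = demography_config(sample_size = 100),
                              params = model_params(),
                              mask_rate = 0.01, min_truth_cm = 1,
                              progress = FALSE) {
  stopifnot(seed * 1000 + n_reps < .Machine$integer.max)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed * 1000 + r)
    map <- synthetic_map(n_markers = n_markers,
                         length_morgans = length_morgans)
    sim <- simulate_founder_population(map, demography)
    truth <- true_ibd_all_pairs(sim$labels, sim$map)
    res <- phase_genotypes(sim$genotypes, sim$map, params)
    sw <- switch_error(sim$h1, sim$h2, res, sim$map)
    im <- ibd_metrics(res$ibd_calls, truth, sim$map, min_truth_cm)
    imp_err <- NA_real_
    allele_yield <- NA_real_
    if (mask_rate > 0) {
      noisy <- add_noise(sim$genotypes$geno, missing_rate = mask_rate)
      gm <- sim$genotypes
      gm$geno <- noisy$geno  # frequencies change negligibly at 1% masking
      resm <- phase_genotypes(gm, sim$map, params)
      impm <- imputation_metrics(sim$genotypes$geno, resm,
                                 noisy$missing_mask)
      imp_err <- impm$imputation_error
      allele_yield <- impm$allele_yield
    }
    out[[r]] <- data.frame(
      rep = r,
      switch_per_morgan = sw$per_morgan,
      within_per_morgan = sw$within_per_morgan,
      yield = phasing_yield(res, sim$genotypes),
      ibd_fdr = im$fdr,
      ibd_sensitivity = im$sensitivity,
      imputation_error = imp_err,
      allele_yield = allele_yield,
      n_ind = nrow(sim$genotypes$geno),
      n_markers = ncol(sim$genotypes$geno),
      converged = res$converged)
    if (progress)
      message(sprintf(
        "rep %d: sw/M %.2f yield %.3f fdr %.4f sens %.3f imp.err %.5f",
        r, sw$per_morgan, out[[r]]$yield, im$fdr, im$sensitivity, imp_err))
  }
  do.call(rbind, out)
}
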