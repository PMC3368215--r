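#' Model parameters for IBD-based long-range phasing
#'
#' Collects the parameters of the five-state pairwise IBD process, the
#' message-passing schedule and the calling thresholds.  The IBD process is
#' parameterized by the rate \code{g} of entering an IBD state and the rate
#' \code{l} of leaving it, both per Morgan.  The reciprocals are the expected
#' non-IBD and IBD identical-by-state segment lengths; the defaults (1 cM and
#' 10 cM) are the standard operating point of the method.
#'
#' @param expected_nonibd_cm Expected non-IBD segment length in centimorgans;
#'   sets \code{g = 100 / expected_nonibd_cm} per Morgan.  Halving this value
#'   trades phasing accuracy for yield.
#' @param expected_ibd_cm Expected IBD segment length in centimorgans; sets
#'   \code{l = 100 / expected_ibd_cm} per Morgan.
#' @param g,l Entry/exit rates per Morgan.  Override the two expected-length
#'   arguments when given directly.
#' @param kappa Kinship cap: the unconditional probability that a pair of
#'   individuals shares some haplotype IBD at a locus, used to cap the
#'   per-interval probability of moving into an IBD state.  The default
#'   0.05 matches the IBD prevalence of a densely sampled isolate (for the
#'   bundled founder-population simulation the realized value is about
#'   0.057) and is large enough that at typical array densities the cap
#'   binds only across unusually long map gaps, not between ordinary
#'   adjacent markers.  Tune to the cohort.
#' @param epsilon Genotyping error probability per genotype, in [0, 0.5).
#' @param damping Message damping weight in [0, 1); the update is
#'   \code{damping * old + (1 - damping) * new} in the negative-log domain.
#' @param max_iters Cap on Min-Sum sweeps.
#' @param tol Convergence tolerance on the maximum absolute message change.
#' @param posterior_threshold Prescan cutoff: markers whose combined IBD
#'   posterior exceeds this value are part of a plausible IBD segment.
#' @param phase_margin Minimum max-marginal margin, in negative-log units,
#'   required to call a phase (or impute an allele).  2.0 corresponds to
#'   posterior odds of about e^2.
#' @param gap_merge Plausible-segment runs separated by fewer than this many
#'   markers are merged (prescan smoothing; not part of the core model).
#' @param min_markers Plausible-segment runs shorter than this many markers
#'   are dropped.
#' @param max_depth Optional cap on the number of plausible segments covering
#'   any (individual, marker) cell; \code{Inf} disables the cap.
#' @param seed Optional random seed recorded with the parameters.
#'
#' @return An object of class \code{"ibd_params"}: a named list.
#' @export
#' @examples
#' p <- model_params()
#' p$g  # 100 per Morgan: expected non-IBD segment of 1 cM
#' p$l  # 10 per Morgan: expected IBD segment of 10 cM
model_params <- function(expected_nonibd_cm = 1,
                         expected_ibd_cm = 10,
                         g = NULL, l = NULL,
                         kappa = 0.05,
                         epsilon = 0,
                         damping = 0.5,
                         max_iters = 30L,
                         tol = 1e-4,
                         posterior_threshold = 0.5,
                         phase_margin = 2.0,
                         gap_merge = 2L,
                         min_markers = 16L,
                         max_depth = Inf,
                         seed = NULL) {
  if (is.null(g)) {
    stopifnot(expected_nonibd_cm > 0)
    g <- 100 / expected_nonibd_cm
  }
  if (is.null(l)) {
    stopifnot(expected_ibd_cm > 0)
    l <- 100 / expected_ibd_cm
  }
  if (!is.numeric(g) || g <= 0 || !is.numeric(l) || l <= 0)
    stop("rates g and l must be positive")
  if (kappa < 0 || kappa > 1) stop("kappa must lie in [0, 1]")
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must lie in [0, 0.5)")
  if (damping < 0 || damping >= 1) stop("damping must lie in [0, 1)")
  if (posterior_threshold <= 0 || posterior_threshold >= 1)
    stop("posterior_threshold must lie in (0, 1)")
  if (phase_margin < 0) stop("phase_margin must be nonnegative")
  structure(list(
    g = g, l = l, kappa = kappa, epsilon = epsilon,
    damping = damping, max_iters = as.integer(max_iters), tol = tol,
    posterior_threshold = posterior_threshold, phase_margin = phase_margin,
    gap_merge = as.integer(gap_merge), min_markers = as.integer(min_markers),
    max_depth = max_depth, seed = seed
  ), class = "ibd_params")
}

#' @export
print.ibd_params <- function(x, ...) {
  cat("IBD phasing parameters\n")
  cat(sprintf("  g = %.4g /Morgan (expected non-IBD segment %.3g cM)\n",
              x$g, 100 / x$g))
  cat(sprintf("  l = %.4g /Morgan (expected IBD segment %.3g cM)\n",
              x$l, 100 / x$l))
  cat(sprintf("  kappa = %g, epsilon = %g\n", x$kappa, x$epsilon))
  cat(sprintf("  damping = %g, max_iters = %d, tol = %g\n",
              x$damping, x$max_iters, x$tol))
  cat(sprintf("  posterior_threshold = %g, phase_margin = %g\n",
              x$posterior_threshold, x$phase_margin))
  cat(sprintf("  gap_merge = %d, min_markers = %d, max_depth = %s\n",
              x$gap_merge, x$min_markers, format(x$max_depth)))
  invisible(x)
}
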