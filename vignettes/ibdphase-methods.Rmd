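---
title: "Long-range phasing through pairwise IBD: model and methods"
author: "ibdphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Long-range phasing through pairwise IBD: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdphase)
```

# The problem

In an isolated founder population that has been densely genotyped, most
individuals share long chromosomal segments identical by descent (IBD) with
other sampled individuals: segments inherited in one piece from a recent
common ancestor.  Where individual $a$ is heterozygous and an IBD partner
$b$ is homozygous, the allele on $a$'s shared haplotype is determined — so
systematically comparing all pairs phases most heterozygous sites without
pedigrees, locates the IBD segments themselves, and imputes missing alleles
through the shared haplotypes.  `ibdphase` implements this long-range
phasing approach as a probabilistic graphical model.

# The pairwise IBD process

For each ordered pair of diploid individuals the IBD relationship along the
chromosome is modeled as a five-state continuous-time Markov process on the
genetic scale: one non-IBD state and four states $S_{ij}$, "haplotype $i$ of
$a$ is IBD with haplotype $j$ of $b$".  Configurations with two or more
shared haplotype pairs, or within-individual sharing (homozygosity by
descent), are deliberately excluded: of the 15 ways four labeled haplotypes
can be partitioned into IBD classes (`ibd_configurations()`), the model
keeps the five that carry all the phase information of the common cases.

The process enters IBD at rate $g$ (split equally over the four states) and
leaves at rate $l$, both per Morgan, so $1/g$ is the expected non-IBD
segment length and $1/l$ the expected IBD segment length given
identity-by-state.  Defaults are 1 cM and 10 cM.  Per-interval transition
probabilities are $\exp(tQ)$ with $t$ the inter-marker distance in Morgans;
for this rate structure the exponential has a closed form (a lumped
two-state chain plus uniform relabeling among the four IBD states), which
`transition_matrix()` uses directly.

**Kinship cap.**  Because $g/(g+l)$ would put most of the stationary mass
on IBD, the probability of moving into IBD between adjacent markers is
capped at the kinship coefficient $\kappa$ — the unconditional probability
that the pair shares a haplotype at a locus — with the clipped mass
returned to the non-IBD self-transition, and the chain is initialized at
$(1-\kappa, \kappa/4, \ldots)$.  The default is $\kappa = 0.05$: in the
founder-population demography simulated here the realized sharing
probability is about 0.057, and at dense-array marker spacing
(0.015 cM between markers) a cap of this size binds only across unusually
long map gaps, not between ordinary adjacent markers — which is how the cap
is meant to behave.  Substantially smaller values make the cap bind at
every interval and starve the model of IBD entry probability.  $\kappa$ is
a tuning knob and should reflect the cohort's relatedness.

**Emissions.**  Given the state, the pair emits two ordered diplotypes
under Hardy-Weinberg equilibrium with the sample allele frequencies,
subject to the IBS constraint: under $S_{ij}$ the shared allele's frequency
is counted once.  A homozygous-minor / heterozygous pair sharing the minor
allele has probability $f^2(1-f)$ under sharing and $f^3(1-f)$ apart.
Observed genotypes attach to the diplotypes with symmetric assay noise
$\varepsilon$ (default 0; set it to the platform's error rate to let the
model tolerate discordances).  Monomorphic markers are excluded — the
emission model requires $0 < f < 1$ — and markers are reoriented so the
minor allele is the coded allele.

# Prescan: plausible IBD segments

Running full inference over all pairs and markers is wasteful because IBD
is sparse.  A scaled Forward–Backward pass over the five-state pair HMM
(`scan_all_pairs()`) computes per-marker posteriors for every pair, and
maximal runs with combined IBD posterior above 50% become *plausible IBD
segments*.  Runs separated by fewer than `gap_merge` (2) markers are
merged, and runs shorter than `min_markers` (16) are dropped; both are
smoothing choices against single discordant markers, not part of the core
model.  Phase can only be called at markers covered by at least one
plausible segment — the price of the restriction is that sites without a
recent common ancestor in the sample stay unphased.

# The Bayesian network and Min-Sum

All pairs are coupled into one Bayesian network: per individual and marker
a 4-valued ordered-diplotype variable $h$ with a uniform prior (an
allele-frequency prior was rejected by the original method's authors
because it overcalls major alleles at missing sites); per pair and marker a
5-valued IBD indicator $p$ whose conditional probability table inverts the
HMM by Bayes' rule,
$P(p_j \mid d_a, d_b, p_{j-1}) \propto T(p_{j-1} \to p_j)\,E(p_j; d_a, d_b)$,
normalized over the five states; the first indicator of each segment chain
conditions on the $(1-\kappa, \kappa/4,\ldots)$ prior.  Genotype
observations attach to $h$ as unary factors.

Approximate MAP inference uses Min-Sum (max-product) message passing in the
negative-log domain, restricted to the plausible segments.  The schedule
sweeps each segment chain forward and backward exactly (the chain messages
are recomputed each sweep), while the factor-to-diplotype messages — the
loopy part of the graph — are damped,
$m' = \lambda\, m_{\text{old}} + (1-\lambda)\, m_{\text{new}}$ with
$\lambda = 0.5$, and segments are processed sequentially so updated beliefs
propagate within a sweep.  Iteration stops when the largest message change
falls below $10^{-4}$ or after `max_iters` (30) sweeps; non-convergence is
flagged in the result but calls are still made from the current
max-marginals.  On a cycle-free instance (one pair, one segment) this
reduces to exact MAP, which the test suite verifies against exhaustive
enumeration.

## Symmetry anchoring

Flipping an individual's two haplotypes everywhere (relabeling the IBD
states accordingly) leaves the joint probability unchanged, so max-marginals
at heterozygous sites would be exactly tied.  The gauge is fixed with one
hard anchor per individual: a single heterozygous site is forced to
minor-allele-on-haplotype-1.  Two details matter and were found the hard
way:

* the anchor site should have a *homozygous* segment partner — at a
  het–het site the chain can absorb the anchor by relabeling its state, and
  the label symmetry survives;
* the anchor should sit in the *interior* of the individual's covered
  region — the MAP solution may place a boundary marker just outside the
  IBD run (the entry/exit tradeoff is of order one negative-log unit),
  which silently unpins an edge anchor.

`phase_genotypes()` therefore anchors the informative heterozygote nearest
the midpoint of each individual's covered span.  Switch-error metrics are
invariant to the anchor choice; it only makes output deterministic.

## Calls, refusals, imputation

A heterozygous site is phased when the max-marginal margin between its two
orientations reaches `phase_margin` (2.0 negative-log units, posterior odds
about $e^2$); otherwise the method refuses.  Margins behave like min-cuts,
not sums: a site's margin is roughly proportional to the number of
committed IBD chains covering it (about 1.7 units per chain in the bundled
simulations), so yield grows with sample size and sharing depth.  Missing
alleles are imputed per haplotype: an allele is called only when a MAP IBD
chain links that haplotype at that marker and the same margin test passes;
a genotype counts as fully imputed when both alleles are called.  When
$\varepsilon > 0$, sites where the MAP diplotype contradicts the observed
genotype by at least the margin are reported as suspected genotype errors
but never silently corrected.  IBD segment calls are maximal runs of a
constant MAP state, split at flips; ties between states break toward the
lower-numbered state.

# The simulator

`simulate_founder_population()` emulates a genotyped isolate: 100 founders
grow exponentially to 18,000 in 12 generations (census
$\mathrm{round}(100\,r^k)$), each offspring drawing two distinct random
parents, each gamete recombining with Poisson($L$) crossovers placed
uniformly on the genetic scale (Haldane, no interference), alleles
transmitted without mutation, and 190 individuals sampled at the end
(`sample_size` is configurable).  Founder haplotypes are synthetic:
independent sites with frequencies uniform on [0.05, 0.5].  This removes
any external-data dependency at the cost of founder-generation linkage
disequilibrium; the long-range IBD structure that drives the method is
created by the simulated generations, not by founder LD, but short-range
"background" IBS runs of real human data are underrepresented, so prescan
false positives are likely optimistic here.  Ancestry mosaics track the
founder haplotype of every sampled chromosome piece, giving exact truth
haplotypes and truth IBD (equal founder labels).  Markers that drift to
monomorphic are dropped and orientation is re-minored, with truth kept
aligned.  `add_noise()` injects missingness and genotyping errors
(uniformly wrong dosages; optionally a two-tier per-marker error mixture).

The default validation map is `synthetic_map()`'s chromosome-20-like map:
7,505 markers over 1.09 Morgans and 62 Mbp (about 6,885 markers per
Morgan) with log-normal block recombination rates.  Desk-scale runs keep
the per-Morgan density and shrink the chromosome (2,000 markers over 0.3
Morgans) and the sample (100 individuals).

# Evaluation

`switch_error()` counts flips of relative orientation versus truth along
each individual's phased heterozygous sites, normalized by individuals
times chromosome length in Morgans (invariant to whole-individual flips);
the within-segment variant resets the comparison at every unphased
heterozygote, isolating errors inside contiguously phased stretches.
`phasing_yield()` is the phased fraction of heterozygous sites.
`ibd_metrics()` compares called and truth IBD in genetic-length-weighted
(pair, marker) cells: sensitivity over truth segments of at least 1 cM
(configurable floor), FDR over all called length, both pair-level
(haplotype configuration ignored) with configuration-resolved variants
reported too.  `imputation_metrics()` counts discordances at fully imputed
masked genotypes and the imputed-allele yield.  `trio_truth_phase()`
builds partial truth haplotypes for real-data style evaluation from
parent-offspring genotypes, excluding and counting Mendelian
inconsistencies.

# What the desk-scale benchmark does and does not establish

`founder_benchmark()` (also driven by `scripts/acceptance.R`) runs five
desk-scale replicates: error-free phasing scored against truth, plus a 1%
masking arm for imputation.  At this scale the IBD detection operating
point (length-weighted FDR well under 1.5%, sensitivity around 75%)
matches the published full-scale behavior of the approach, and switch
errors inside phased segments are rare (< 1 per Morgan).  Total switch
errors and yield, however, are depth-limited: with 100 samples each site is
covered by about half as many IBD partners as with 190, margins shrink
accordingly, more sites fall below the refusal threshold (yield ~76%
rather than ~93%), and the refusal boundaries contribute extra orientation
flips.  These quantities recover with sample size, not with more
iterations; the full-scale configuration for offline verification is
`founder_benchmark(n_markers = 7505, length_morgans = 1.09,
demography = demography_config(sample_size = 190), n_reps = 10)` (hours,
not minutes).  A green property suite (oracle equivalence, tree exactness,
coherence invariants) plus the desk-scale operating points is therefore the
meaningful correctness claim; the headline full-scale numbers are expected
to be approached only at full scale.

# Numerical choices

* All probability work in the Min-Sum engine is in the negative-log
  domain; $-\log 0$ is represented as 700 (below the smallest positive
  double's negative log), so hard IBS violations dominate without
  overflow.
* Forward–Backward uses per-marker rescaling, safe for chromosomes of
  $10^5$ markers and more.
* Zero-length map intervals (co-located markers) use the identity
  transition.
* Messages are normalized to minimum zero; convergence is measured on the
  damped factor-to-diplotype messages.
* Chain-state ties break toward the lower-numbered state; tied
  orientation max-marginals are refusals.

# Known limitations

* Quadratic cost in the number of individuals (all pairs are scanned);
  the optional `max_depth` coverage cap trades sensitivity for time.
* The five-state model ignores homozygosity by descent and multi-way
  sharing; dense consanguinity is better served by richer state spaces.
* Yield and margins degrade gracefully but noticeably below ~100 sampled
  individuals or outside founder populations, where long-range IBD is
  rare.
* Genotyping error above about 1% degrades both yield and accuracy;
  stringent upstream QC is assumed.
* Single-chromosome runs; loop over chromosomes externally.
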