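---
title: "Cross-fluid correlation networks and connectedness ranking: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-fluid correlation networks and connectedness ranking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabridge)
```

# The problem

Paired blood and cerebrospinal-fluid (CSF) NMR metabolomics of transgenic
mouse models asks a question that single-fluid profiling cannot: which
metabolites move *together* across the blood–brain barrier, and does that
coupling change when amyloid pathology is present?  The practical setting
is hostile to standard large-sample statistics: samples are pooled (one
measurement may represent several animals), per-group sample sizes are in
the single digits, and NMR yields only relative concentrations.  Every
method in this package is chosen with those constraints in mind.

# Preprocessing model

A spectrum is a strictly monotone ppm axis with one intensity per point.
The chain applied by `preprocess_spectrum()` is, in the default order:

1. **Baseline**: the mean intensity over the pooled signal-free edges
   (below −3 ppm and above 12.5 ppm) is subtracted as a single constant.
   A one-constant baseline is deliberately minimal: curvature corrections
   belong upstream in vendor processing.  The pooled mean over the union
   of the two edge regions is used (one constant, not two).
2. **Reference normalization**: division by the trapezoidal *area* of the
   reference (DSS) window, 0 ± 0.05 ppm.  Area rather than peak height:
   the integral averages over noise, and is invariant to the small line
   shape changes that pH shifts cause.  After this step the reference
   integral is exactly 1, so spectra from different receiver gains are
   comparable.
3. **Alignment**: a single global shift, estimated as the maximizer of
   the circular cross-correlation (computed by FFT) within ±`max_shift`
   ppm.  Interval-wise (segment) alignment is out of scope.
4. **Masking**: keep 0.5–9.5 ppm, drop the 4.5–5.2 ppm water region
   (inclusive bounds on both).
5. **Binning**: averages over half-open bins `[left, left + w)` of width
   w = 0.0008 ppm anchored at the lowest retained ppm; output axis is the
   bin centers; a partial trailing bin is kept when it contains a point.
   The 0.5–9.5 ppm window therefore yields exactly
   (9.5 − 0.5)/0.0008 = 11,250 bins before water removal.

Baseline subtraction and normalization are each idempotent (a second
pass is a no-op), and normalization is scale-invariant; the test suite
checks both on random spectra.  Whether normalization precedes or follows
baseline correction is configurable through `steps`; the default order is
baseline first, so the reference area is measured above a zeroed
baseline.

## Alignment reference

When samples carry a synthetic reference peak *at* 0 ppm (as the
simulator produces — the reference is by definition already on-scale),
whole-spectrum cross-correlation against another sample is pinned at lag
0 by the two reference peaks and cannot see metabolite drift.  The
pipeline therefore aligns each spectrum against the **library consensus**
(the sum of the standard spectra, which has no reference peak), so the
metabolite peaks drive the estimate and samples land on the standards'
grid positions — which is exactly what the subsequent regression needs.
On simulated data this recovers grid-level shifts exactly.

# Quantification

With a library S of standards (rows unit-normalized to total intensity
1, matching the sample's grid) the relative concentrations solve

$$\min_{c \ge 0} \; \lVert y - S^\top c \rVert_2 .$$

Because the model is linear, this is a convex problem with a unique
optimum when S has full row rank; `fit_concentrations()` solves it
directly with the Lawson–Hanson active-set algorithm (`pracma`),
which is deterministic and has no initialization sensitivity.  The
classical two-stage route — an unconstrained linear least-squares start
refined by Levenberg–Marquardt under box constraints
(`minpack.lm`) — is retained as `method = "two-stage"` and converges to
the same optimum (tested); we use plain least squares rather than a PLS
fit for the starting point because the destination of a convex descent
does not depend on where it starts.

Fitting is *joint* over all standards by default: overlapping standards
compete for the same intensity, which is the point of full-spectrum
deconvolution.  A per-standard `method = "independent"` mode (each
standard projected alone, clipped at zero) is provided for comparison;
the two agree only when standards do not overlap.  Ill-conditioning from
near-duplicate standards is flagged when the library condition number
exceeds 1e6.

Guarantees validated by the tests: exact recovery of noiseless mixtures
(≤ 1e−6), exact positive homogeneity (scaling the sample scales the
coefficients), and optimality against random nonnegative candidates.
At 1% additive Gaussian noise (relative to the spectrum maximum) with 20
standards, coefficients with true share ≥ 0.05 are recovered within 5%
relative error in ≥ 95 of 100 replicates.

# Cross-fluid Spearman networks

For n matched samples and the metabolites shared between fluids, the
matrix M has M[i, j] = Spearman ρ between metabolite i in blood and
metabolite j in CSF (average ranks for ties); the CSF→blood direction is
its transpose.  Within-fluid correlations are deliberately excluded from
the object: the scientific target is co-variation *across* the barrier.

**p-values.**  At the sample sizes this design produces (often n ≤ 9),
asymptotic approximations are the wrong tool.  For n ≤ 9 the permutation
null distribution of ρ is enumerated exactly over all n! orderings,
conditioning on the observed rank multisets (so ties are handled
consistently); the distribution is cached per rank-multiset pair, so a
full 51×51 matrix costs one enumeration when the data are tie-free.
Above n = 9 the usual t approximation t = r√((n−2)/(1−r²)) on n−2
degrees of freedom is used.  This deviates intentionally from the
Edgeworth-corrected AS89 approximation: at tiny n exactness is available
and preferable, and AS89 is itself an approximation.  The tests verify
exact agreement with an independent brute-force enumerator for all
n ∈ {4,…,7}.

**Significance mask and harmonization.**  A = ρ where p ≤ α (α = 0.05,
uncorrected — matching the exploratory per-pair convention of the study
design this package emulates; a Benjamini–Hochberg mode is available but
off by default).  For genotype comparisons, the pair list is the union
of pairs significant in *either* group, each list carrying its own
group's raw ρ, so both groups always report the same pairs.

**Differential correlation.**  For each harmonized pair,
z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3)), two-sided normal
p-value.  Correlations at ±1 are clamped to ±(1 − 1e−10) with a warning
(atanh diverges); n < 4 is refused because the z variance 1/(n−3) does
not exist.  Calibration is checked under the transform's own exactness
regime: Pearson correlations of two independent bivariate-normal groups
(n = 20 each, equal true ρ, 10,000 replicates) reject at a rate inside
[0.04, 0.06] at α = 0.05.  Fed Spearman ρ instead, the same statistic is
mildly anticonservative (the Fisher-z variance of Spearman's ρ is
≈ 1.06/(n−3)); users comparing rank correlations should read borderline
p-values accordingly.

# Connectedness ranking

From the significance-masked adjacency A the block matrix

$$M = \begin{bmatrix} 0 & |A| \\ |A|^\top & 0 \end{bmatrix}$$

encodes only cross-fluid edges; the absolute value is taken because the
ranking measures a metabolite's capacity to influence others, not the
sign of that influence.  Powers of M count walks: even powers connect
metabolites within a fluid *through* the other fluid, odd powers connect
across.  The total connection strength is the geometric series
Σₖ Mᵏ, which converges after scaling by any α with α‖M‖ < 1; the package
fixes α = (0.01 + ‖M‖_F)⁻¹ so the condition holds by construction, and
asserts the spectral radius ρ(αM) < 1 on every run.  The ranked score is
the column sum of

$$T' = M \sum_{k\ge 0} (\alpha M)^k = M (I - \alpha M)^{-1},$$

computed by LU solve, never by explicit inversion.  The first n columns
score blood metabolites, the last n CSF metabolites.  Only the *ordering*
of scores is meaningful — dropping the leading α factor rescales all
scores equally — so scores should be compared, not interpreted in
absolute units.

Numerical choices: a metabolite with no significant cross-fluid edge has
score exactly 0 in real arithmetic (its zero column propagates through
every power of M), so the implementation forces the exact zero rather
than leaving ~1e−16 LU round-off; an all-zero adjacency returns zero
scores with a warning (α = 1/0.01 = 100) rather than aborting batch
runs; rank ties are broken lexicographically by metabolite name for
deterministic output.  The resolvent is validated against a truncated
500-term series (independent matrix-power implementation) to 1e−8 over
random networks up to n = 20, and against the closed form of the
single-edge network, whose score is 1/(1 − α) = 3.3573 exactly.

# Group summaries

- **Log ratios**: per metabolite and sex×genotype group,
  log₁₀(mean late / mean early) of the group means — positive values
  mean the metabolite rises with age.  The direction (late over early)
  is fixed and stated in every output header, since "ratio between early
  and late" is ambiguous in common usage.
- **ANOVA ranking**: one-way ANOVA per metabolite across the grouping
  factor (genotype by default; whether sexes are pooled is the caller's
  choice).  With two groups F equals the squared pooled-t statistic
  (property-tested).
- **Consensus selection**: the intersection of the top-k metabolites by
  ANOVA F and by |coefficient| of an L2-regularized logistic regression
  (λ = 1 on standardized features; λ has no data-derived default because
  tiny cohorts make cross-validation unstable).  A caution the tests
  document: under pure noise the two rankings are strongly *concordant*
  (both score the same group-mean contrast), so the size of the
  intersection is far larger than the hypergeometric count independent
  rankings would give — consensus selection controls method
  idiosyncrasy, not false positives, and should not be read as a
  calibrated test.

# The synthetic cohort

The simulator stands in for an undeposited dataset and defines the
conditions under which the package is validated:

- **Design**: 2 sexes × 2 genotypes (WT / amyloid transgenic) × 2 age
  points, 3 pooled replicates per cell by default, matched blood and CSF
  measurements per replicate; 51 metabolites per fluid, all shared, by
  default.  Each pool is treated as one replicate (the within-pool
  animal structure is not modelled).  Because the source design's
  effective per-group n is not recoverable, `replicates_per_group` is a
  free parameter.
- **Copula**: cross-fluid rank correlation is imposed through a Gaussian
  copula; the latent Pearson entries are 2 sin(πρ_S/6), the exact
  relation for bivariate normals, so target Spearman values are achieved
  exactly in the large-n limit (empirically within ±0.05 at n = 10,000).
  The within-fluid latent blocks are identity — the assembled joint
  correlation matrix must be positive semi-definite, and infeasible
  targets are rejected with the offending eigenvalue.
- **Marginals and effects**: log-normal marginals (default sdlog 0.5,
  the ~50% coefficient of variation typical of metabolite panels);
  genotype and age effects are additive on the log scale (default 0.2 ≈
  a 22% concentration change, a moderate, realistic effect size),
  applied to the leading 30% of the metabolite list.  Additive log-scale
  effects keep the marginals log-normal and leave within-group rank
  correlations untouched.
- **Spectra**: standards are sums of Lorentzian lines (the natural NMR
  line shape), default half-width 0.002 ppm (~1.2 Hz at 600 MHz), unit
  total intensity; mixtures add a constant baseline, i.i.d. Gaussian
  noise, an optional circular peak-drift shift, and an isolated
  reference peak at 0 ppm of known area so that downstream
  normalization is exercised.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: broad lipoprotein envelopes under the sharp
peaks, multiplet structure and J-coupling, pH-dependent *differential*
shifts (all peaks drift together here), heteroscedastic noise, and
between-batch drift.  Conclusions about the statistical machinery
transfer; conclusions about spectral fitting difficulty on serum NOESY
data do not.

# Problem sizes used in the validation suite

The shipped tests run the full validation at these sizes (chosen to make
the checks decisive at interactive cost): 100 random networks up to
n = 20 for the resolvent/series comparison (1e−8); all n! permutations,
n ∈ {4,…,7}, 50 pairs each, for exact Spearman p-values; 10,000
Monte-Carlo replicates at n = 20/group for the Fisher-z null; 100
seeded replicates of 20-standard mixtures at 1% noise for quantification
recovery; 10,000 samples for copula fidelity; and 25 random sparse
networks for the exact-zero invariant.  The demo pipeline runs 12 shared
metabolites on a 0.002-ppm grid; the statistical machinery is identical
at the full 51-metabolite, 0.0008-ppm scale, only slower.

# Known limitations

- Alignment is a single global shift; metabolite-specific pH drift needs
  segment-wise methods and is out of scope.
- Quantification returns relative units tied to the reference area; no
  absolute (mM) calibration.
- Exact Spearman p-values are enumerated only to n = 9 (9! = 362,880
  permutations); beyond that the t approximation's accuracy is the
  limit.
- The connectedness score inherits the significance mask: edges just
  beyond α = 0.05 contribute nothing, so rankings can be sensitive to
  the threshold in small cohorts.
- With uncorrected per-pair α = 0.05 and hundreds of pairs, a fraction
  of network edges are expected false positives; the BH option exists
  where that matters.
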