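# metabridge

Cross-biofluid NMR metabolomics: how do metabolite levels in **blood** and
**cerebrospinal fluid (CSF)** co-vary across the blood–brain barrier, and
how does that co-variation change with genotype?

The package is written for metabolomics analysts working with paired
blood/CSF 1D ¹H NMR measurements of small cohorts — the typical setting in
transgenic-model neurodegeneration studies, where samples are pooled, per
group sample sizes are tiny, and only *relative* concentrations are
available. It covers the whole path from raw two-column spectra to a
ranked list of cross-fluid "connected" metabolites:

1. **Preprocessing** — constant baseline subtraction estimated from the
   signal-free spectrum edges, normalization to the area of the 0-ppm
   reference (DSS) peak, restriction to 0.5–9.5 ppm with the water region
   (4.5–5.2 ppm) removed, averaging into 0.0008-ppm bins, and global
   alignment by FFT cross-correlation.
2. **Quantification** — relative concentrations by fitting each spectrum
   as a nonnegative linear combination of unit-normalized standard
   spectra over the whole spectral range:
   min‖y − Sᵀc‖₂ s.t. c ≥ 0, solved with the Lawson–Hanson active-set
   algorithm (a Levenberg–Marquardt two-stage mode is available).
3. **Correlation networks** — for metabolites shared between fluids, the
   Spearman matrix M with M[i,j] = ρ(blood i, CSF j), exact permutation
   p-values for n ≤ 9 matched samples (t approximation above), and the
   significance-masked adjacency A (α = 0.05). Pairs significant in either
   genotype are harmonized across groups and genotype differences tested
   by Fisher z: z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3)).
4. **Connectedness ranking** — the path-counting score built from the
   bipartite block matrix M = [[0, |A|], [|A|ᵀ, 0]]: with
   α = (0.01 + ‖M‖_F)⁻¹ the geometric series of walk counts converges and
   T′ = M(I − αM)⁻¹ sums walks of every length; each metabolite is ranked
   by its column sum of T′ (first n columns = blood, last n = CSF).
5. **Group summaries** — log₁₀(late/early) concentration ratios, one-way
   ANOVA ranking, and ANOVA × ridge-logistic consensus feature selection.
6. **Synthetic data** — a Gaussian-copula simulator for group-structured
   concentration tables with prescribed cross-fluid Spearman correlations
   (via ρ_P = 2 sin(πρ_S/6)) and log-normal marginals, plus Lorentzian
   standard libraries and mixture spectra with full ground truth — so
   every stage can be validated against known answers.

## Worked example

Quantify a synthetic three-metabolite mixture and rank a small network:

```r
library(metabridge)

ax  <- seq(-0.2, 9.6, by = 0.002)
lib <- make_standard_library(list(
  standard_spec("lactate", data.frame(center = c(1.33, 4.11),
                                      height = c(3, 1), width = 0.002)),
  standard_spec("alanine", data.frame(center = 1.48, height = 1, width = 0.002)),
  standard_spec("glucose", data.frame(center = 3.40, height = 1, width = 0.002))),
  ax)

mx  <- synthesize_mixture_spectrum(lib, c(0.5, 0.2, 0.3), noise_sd = 0.001,
                                   seed = 42, reference_height = 0)
fit <- fit_concentrations(mx$spectrum, lib)
round(coef(fit), 4)
#> lactate alanine glucose
#>  0.5002  0.1993  0.2956
```

The fitted concentrations recover the generating values (0.5, 0.2, 0.3)
to a few parts per thousand at this noise level. Ranking a toy 2×2
adjacency (blood rows, CSF columns; entries are significant Spearman
correlations):

```r
A <- matrix(c(0.9, 0, -0.62, 0.8), 2,
            dimnames = list(c("acetate", "glucose"),
                            c("taurine", "lactate")))
connectedness_scores(build_block_matrix(A))
#> <connectedness> 2 blood / 2 CSF metabolites (alpha = 0.51937)
#> top blood:
#>  metabolite    score rank
#>     acetate 3.996947    1
#>     glucose 2.326389    2
#> top CSF:
#>  metabolite    score rank
#>     lactate 3.673658    1
#>     taurine 2.768303    2
```

Acetate outranks glucose in blood: its |0.9| edge, plus the walks it
inherits through taurine and lactate, accumulate more path weight than
glucose's single 0.8 edge. A genotype difference in correlation for one
pair (r = 0.89 in the transgenic group vs −0.43 in wild type, n = 10 per
group):

```r
differential_correlations(
  data.frame(blood = "acetate", csf = "taurine", rho = 0.89),
  data.frame(blood = "acetate", csf = "taurine", rho = -0.43),
  n1 = 10, n2 = 10)
#>     blood     csf   r1    r2   z_stat      p_value significant
#> 1 acetate taurine 0.89 -0.43 3.520568 0.0004306242        TRUE
```

The full simulate → preprocess → quantify → correlate → rank → summarize
chain is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "demo_run")
```

which writes true and recovered concentration tables, per-group ρ/p/A
matrices, differential-correlation tables, connectedness rankings and the
group summaries as CSV, plus a run log, under `demo_run/`.

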