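---
title: "Methods: trait-based macroecology of a fossil clade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-based macroecology of a fossil clade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleomacro)
```

`paleomacro` implements a complete analysis chain for asking how
ecomorphological traits relate to species "success" in the fossil record
— success in time (species duration) and in space (grid-cell occupancy)
— and which macroevolutionary model best describes trait change on a
clade's phylogeny. The motivating system is a densely sampled fossil
carnivoran clade with strong dietary disparity (hypo- to
hypercarnivores), but every stage is generic. This vignette documents
the models, their assumptions, the tunable parameters, and the numerical
choices; the README shows a worked end-to-end run.

## 1. Dietary ecomorphology and the carnivory index

Three dental/mandibular ratios summarize diet in carnivorans:

* **RBL**, relative blade length: trigonid (slicing) blade length over
  total lower first molar (m1) length, in (0, 1]; higher = more
  slicing-dominated, more carnivorous.
* **RUGA**, relative upper grinding area: square root of the upper
  molar grinding area over upper fourth premolar (P4) length; higher =
  more grinding surface, less carnivorous.
* **JD/DL**, jaw depth over dentary length; deep short jaws indicate
  powerful, often bone-cracking, bites.

`fit_carnivory_index()` standardizes the three ratios by their training
means and standard deviations and eigendecomposes their correlation
matrix — a correlation-matrix PCA, chosen because the ratios differ in
spread by an order of magnitude and a covariance PCA would be dominated
by RUGA. PC1 is the **carnivory index**; its sign is fixed so RBL loads
positively (carnivory increases to the right), and PC2 approximates
durophagy. The PCA is trained on extant species of known diet and the
fossil species are projected through the frozen training
standardization and loadings (`project_carnivory()`); projected fossil
PC1 is re-centred on the fossil median, so 0 means "median fossil
carnivory". Diet labels never enter the fit — they are carried only for
visualization, deliberately avoiding a discriminant analysis that would
force fossils into extant categories.

This is a *standard*, not phylogenetic, PCA. Reducing correlated traits
by standard PCA before fitting phylogenetic models can bias model
selection toward early-burst-like (ACDC) signatures; we keep the
standard PCA (the extant training set has no agreed evolutionary model
either) and flag the caveat here rather than "fixing" it.

Missing dentary lengths (common in fragmentary fossils) are imputed by
a per-subfamily log-log regression of dentary length on m1 length
(`fit_dentary_imputer()`), the usual allometric form. Imputed values
are flagged; ratios whose inputs are missing and cannot be imputed stay
`NA` and the species is excluded from projection with a report, never
silently filled. Body mass comes from the m1-length allometry
`log10(mass) = a + b log10(m1)`; the coefficients are configuration
with a documented, non-normative default (`a = -2.58`, `b = 2.97`,
in the range of published carnivoran m1 regressions).

## 2. Preservation-adjusted durations

Observed first and last appearances (FAD/LAD) understate true
durations. `estimate_durations()` implements the simplest
birth–death-with-preservation model: per species, occurrence ages are a
homogeneous Poisson process with rate `q` (occurrences/Myr) on the true
interval `(TE, TS)`, so the per-species likelihood given `k`
occurrences is `q^k exp(-q (TS - TE))` with `TS >= FAD`, `TE <= LAD`.
Across species, `(TS, TE)` carry a constant-rate birth–death prior
`lambda^S mu^E exp(-(lambda + mu) sum(TS_i - TE_i))`. Priors: `TS` and
`TE` uniform on a window extending the observed range by `pad` (default
15 Myr); `q`, `lambda`, `mu` vague Gamma(1, 0.1).

Under this factorization every full conditional is available in closed
form — truncated exponentials for each `TS_i` and `TE_i`, Gammas for
the three rates — so the sampler is a plain Gibbs scheme (the
exactly-conditional special case of Metropolis-within-Gibbs). It has no
proposal tuning, mixes essentially instantly, and is reproducible under
a fixed seed. Non-homogeneous preservation ("hat-shaped" rates,
rate-shift models) is deliberately out of scope; the homogeneous model
keeps the estimator fully auditable against a numeric grid posterior,
and the package's tests hold it to that oracle within 0.05 Myr.

Occurrence interval dates are resolved to midpoints by default;
`age_mode = "resample"` instead re-draws ages uniformly within their
intervals every iteration, propagating dating uncertainty. Duration is
`median(TS) - median(TE)` with medians taken marginally — always at
least the stratigraphic range. The default desk-scale chain is 5e5
iterations with 10% burn-in; production-scale settings (1e7 iterations,
2e5 burn-in) are plain arguments.

## 3. Occupancy and maximum locality coverage

Raw locality counts conflate range size with collection clustering.
`occupancy_by_slice()` therefore rasterizes occurrences onto half-degree
cells (`floor(coordinate / 0.5)`, half-open cells so boundary points
belong to the cell starting there) and, per time slice, scores each
species by the fraction of *clade-occupied* cells it occupies. An
occurrence joins a slice if its age-interval midpoint falls inside it.
`max_locality_coverage()` takes each species' maximum over slices, ties
broken toward the older slice. Occupancy is a relative measure within
the clade per slice; it is undefined (absent, not zero) in slices where
the clade has no record. The default slice table has 18 contiguous
slices over the last 40 Myr, emulating land-mammal-age subdivisions; it
is approximate and user-replaceable.

Species found at a single locality ("singletons") and extant species
are excluded up front by `filter_species()` — the former because one
locality cannot constrain duration or coverage, the latter because
modern ranges are anthropogenically constrained — with counts reported
per reason.

## 4. Phylogenetic signal, PGLS and the specialization analyses

`pagel_lambda_ml()` profiles the Gaussian likelihood over Pagel's
lambda in [0, 1] (lambda scales the off-diagonal of the shared-path
matrix `C`; mean and rate are concentrated out analytically) and tests
lambda = 0 with a likelihood-ratio chi-square on 1 df (no boundary
halving by default, mirroring common implementations; a 50:50 mixture
is available). `blomberg_k()` computes the classic mean-square-error
ratio statistic and a tip-permutation p-value with floor
`1/(1 + n_perm)` (default 999 permutations). One calibration caveat
discovered while validating: K's sampling distribution under Brownian
motion is right-skewed — its mean is 1 but its median sits below 1, and
markedly so on birth–death trees with many extinct tips (about 0.76 at
128 tips in our checks, with values identical to an independent
implementation). The calibration tests therefore use pure-birth
ultrametric trees, the setting in which the statistic was originally
characterized; on fossil trees K should be interpreted against that
skew, not against 1.

`pgls_fit()` is generalized least squares with residual covariance
proportional to the *phylogenetic correlation* matrix (C rescaled to
unit diagonal, as the standard `gls(corPagel)` route does). This choice
matters on non-ultrametric trees: with the raw covariance, lambda = 0
would still be a weighted regression by tip depth, whereas on the
correlation scale lambda = 0 reduces exactly to OLS — the behaviour
users of the standard tools expect, and the reduction our tests verify
to 1e-8. Lambda is estimated by profile ML on [0, 1] or fixed at 1
(Brownian) or 0 (null); `pgls_compare_lambda()` compares the three by
AICc.

The specialization analysis (`build_specialization_dataset()`,
`fit_side_regressions()`) splits species at the median carnivory value
(ties go deterministically to the less-carnivorous side), defines
specialization as distance from the median within each side, and
regresses duration on specialization per side — by OLS when the ML
lambda of the OLS residuals is below a configurable threshold (default
0.25), else by PGLS. Configured outlier species stay in the table but
never enter a fit. Because duration variance shrinks toward the
specialized extremes (a preservation-driven heteroscedasticity),
`quantile_regression()` fits the upper conditional quantiles
(tau = 0.6–0.9 by default): the check-loss objective is minimized
exactly — an asymmetric IRLS pass followed by enumeration of candidate
lines through the lowest-residual point pairs, exploiting the fact that
an optimal simple quantile regression passes through two data points —
and inference is by xy-pair bootstrap (SE = bootstrap standard
deviation; two-sided p from a normal reference; percentile intervals
reported). The production-scale bootstrap is 10,000 replicates;
reduced-replicate runs are for exploration.

`nested_duration_models()` compares five OLS models of duration —
each of log10 mass, carnivory and coverage alone, the mass-by-carnivory
full factorial, and the three-way full factorial — by AICc with
k = number of *mean* parameters (2, 2, 2, 4, 8). Counting only mean
parameters reproduces the printed AICc values of the reference analysis
from its printed log-likelihoods to within about 0.1, whereas counting
the variance misses by more than 2; the weights-from-AICc path is
treated as normative.

## 5. Six models of trait evolution

All six models are Gaussian on the tips, so each is fully specified by
a mean vector and covariance matrix (`model_mean_cov()`), with `C` the
shared-path-length matrix and `T_i` the root-to-tip times
(non-ultrametric trees handled exactly throughout):

| model | mean | covariance | shape parameter |
|---|---|---|---|
| BM    | `z0` | `s2 C` | — |
| OU    | `z0` | `s2/(2a) exp(-a(T_i+T_j-2C_ij)) (1-exp(-2a C_ij))` | attraction `a` |
| ACDC  | `z0` | `s2 (exp(r C_ij)-1)/r` | rate change `r` |
| Trend | `z0` | `s2 (C_ij + b C_ij^2/2)` | rate slope `b` |
| Drift | `z0 + m T_i` | `s2 C` | directional `m` |
| Div   | `z0` | `int_0^{C_ij} (s2 + psi n(t)) dt` | diversity `psi` |

OU uses the single-stationary-peak convention with the root at the
optimum (`z0` doubles as the optimum), and the exact exponential
covariance rather than a branch-stretch approximation. Div's lineage
count `n(t)` is the reconstructed diversity of the tree being fitted —
lineages increment at internal nodes and decrement at extinct tips'
ages (the only observable diversity) — and the piecewise-constant rate
is integrated exactly between change points. Trend and Div rates are
constrained nonnegative over the tree's time span.

**Fitting.** `fit_trait_model()` exploits the structure of the
likelihood instead of a generic multistart optimizer: for every model
the covariance is `s2 V(shape)` and the mean is linear in its
parameters, so `z0` (plus Drift's `m`) and `s2` are profiled
analytically by GLS, leaving at most a one-dimensional optimization
over the shape parameter. That profile is maximized by a coarse grid
over the feasible range (log-spaced for OU, where curvature
concentrates at weak attraction) followed by golden-section refinement.
This is deterministic, restart-free, and in our checks matches the
closed-form BM solution to 1e-6 and a dense matrix-inversion likelihood
oracle to 1e-9. Parameter counts for AICc: BM 2, all others 3. Shape
bounds: `a` in [0, 50/depth]; `r` in ±15/depth; `b` and `psi` bounded
below so the rate stays positive. Degenerate covariances (exchangeable
duplicate tips, e.g. zero-length cherries) are reported by name.

`fit_over_posterior()` repeats the comparison across a posterior sample
of trees — pruning each tree to the trait's species (with a warning,
skipping trees missing more than half of them), computing per-tree
Akaike weights, and summarizing each model by its **median weight
across trees** (per-tree weights sum to 1; medians need not). Subclade
(e.g. subfamily) analyses pass a species list.

## 6. The synthetic-data generator

Every stage is testable without downloads because the generator
produces all four inputs with known ground truth:

* **Trees** (`simulate_tree()`): forward constant-rate birth–death
  simulation conditioned on total tip count (extinct tips retained), so
  trees are non-ultrametric like fossil tip-dated trees. The clock
  stops strictly between the last and the next event so no
  zero-length cherries arise. The origination/extinction age of every
  tip is recorded. A posterior sample is emulated by multiplicative
  lognormal jitter of edge lengths (`simulate_posterior_trees()`).
* **Traits** (`simulate_trait()`): exact multivariate-normal draws from
  the same mean/covariance the likelihoods use, so simulator and
  fitter share one analytic law and moment tests close the loop.
* **Fossil records** (`simulate_fossil_record()`): homogeneous Poisson
  occurrences at rate `q` on each species' true interval; per-species
  2-D Gaussian geographic kernels inside the configured extent;
  localities formed by snapping to a 0.1-degree raster; dating
  intervals of true age ± half the enclosing slice width
  (land-mammal-age-style binning) or a fixed half-width.
* **Morphometrics** (`simulate_extant_morphoset()`,
  `simulate_fossil_morphoset()`): diet-category centroids with
  Gaussian noise for the extant training set (the bone-cracking
  "hyaenid-like" centroid has the highest RBL and JD/DL and lowest
  RUGA); fossil characters generated from latent carnivory and mass,
  with a configurable fraction of dentaries removed to exercise
  imputation.

Default study conditions: 60 tips, birth 0.25/Myr, death 0.2/Myr
(a mostly extinct clade, as in the motivating system), `q` = 2
occurrences/Myr, 18 time slices over 40 Myr, half-degree grid over a
mid-latitude extent. Pipeline trait models default to Drift with
positive directional term for log10 mass (a Cope's-Rule-like size
increase; rates chosen so the tip spread is about 0.4 on the log10
scale) and BM for carnivory (tip spread near 1, matching typical
carnivory-index dispersion). What the generator does **not** emulate:
spatially or environmentally varying preservation, dispersal
biogeography, correlated dating errors, taxonomic lumping/splitting.
Passing tests therefore certify the statistical machinery under the
stated model, not robustness to those real-data pathologies.

## 7. Numerical choices and limitations

* All Gaussian likelihoods are evaluated by Cholesky; simulation adds a
  relative 1e-12 diagonal jitter only for draws. Exact zero-residual
  fits are clamped (variance floor 1e-290) and flagged rather than
  fatal.
* Golden-section tolerances are 1e-10; lambda and shape grids have
  16–21 coarse points. Ties in `max_locality_coverage()` go to the
  older slice; species exactly at the carnivory median go to the
  "less" side; slice membership is `young <= mid < old` with the oldest
  slice closed above.
* The pipeline derives every stage seed deterministically from one
  master seed; rerunning a configuration yields byte-identical CSVs.
  Reference problem sizes used by the package's own acceptance checks:
  a 60-species fixture, 50 posterior trees, 2e5 MCMC iterations,
  500-replicate bootstraps.
* Known limitations: single-trait evolution models only (no
  multivariate models, no rate-shift-point detection); homogeneous
  preservation; one global `q` by default; occupancy is relative to
  clade-occupied cells and so not comparable across clades; the
  carnivory index inherits the standard-PCA caveat above.
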