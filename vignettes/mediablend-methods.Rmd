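---
title: "Media-blending design and analysis: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Media-blending design and analysis: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the models and procedures implemented in
`mediablend`, the assumptions behind them, the parameters a user may want
to change, and the limitations a careful reader should keep in mind.

## 1. The design problem

Media blending varies the concentrations of all `d` components of a
culture medium simultaneously by mixing `m` pre-made mother media in
integer volume units. Writing the mother-media composition as a
nonnegative matrix `A (m x d)` and the `k` possible unit allocations as
`D (k x m)`, the component profile of every candidate blend is `E = D A`.
Choosing `n` conditions to culture is a D-optimal design problem —
maximize `det(E'ᵀE')` — because that determinant is the squared volume of
the parallelepiped spanned by the design's column vectors: the larger the
volume, the more directionally diverse the information about individual
components.

**The rank constraint.** Practical blending uses far fewer mother media
than there are components (`m < d`, typically 10-ish media against 50+
components). Then `rank(E') <= m < d`, the `d x d` Gram matrix is
singular, and the plain determinant criterion is identically zero. This is
not a numerical nuisance but the defining constraint of the method: some
multicollinearity among components is unavoidable, and no selection of
conditions can remove it. The package therefore:

1. standardizes `A` per component (population SD; z-scores put all
   components, whatever their units, on one scale);
2. projects onto principal components retaining a fraction
   `var_threshold` (default 0.99) of the variance — the smallest number
   `p` of orthogonal directions carrying essentially all compositional
   variation, with `p <= m - 1` by construction;
3. maximizes `det(E'ᵀE')` for `E = D B` in the `p`-dimensional score
   space, where the Gram matrix is generically full rank.

Because `E' = D'A'V_p`, the PC-space determinant equals the determinant of
`V_pᵀ A'ᵀ D'ᵀ D' A' V_p`: optimizing in score space optimizes the
non-redundant part of the original component-space problem. A test
verifies this factorization numerically.

**Random search.** Selection uses uniform random sampling of `n`-row
subsets (default `iters = 10000`), keeping the first-encountered maximum
and the full determinant trace. Random search is simple, embarrassingly
reproducible, and sufficient here because the determinant distribution
over subsets is heavily right-skewed: the design goal is a clearly
above-typical subset, not a certified global optimum. On all small
instances where exhaustive enumeration is feasible the search does attain
the global maximum (tested); exchange-type optimizers are out of scope.
Ties are broken by first encounter, and all sampling is driven by R's RNG
so a seed fixes the result exactly.

**Determinant scale.** By default the determinant is computed on raw PC
scores. A `standardize_det_cols` switch z-scores the selected columns
first; both conventions appear in practice (the raw form weights
components by their variance share, the standardized form only by their
directions). The default was chosen to keep the criterion identical to
the Gram volume of the actual design matrix; the switch changes the
selected subset but not the workflow.

## 2. Diagnostics

`design_diagnostics()` reports pairwise `|r|` among the selected score
columns and variance inflation factors `VIF_j = 1/(1 - R²_j)` computed
via the inverse correlation matrix. For a well-spread design all VIFs are
close to 1. The contrast between the best and the worst subset in a
search is largest when `n` is of the same order as `p`; when `n >> p`
every random subset already estimates the score covariance well and the
diagnostics of good and bad selections converge — D-optimal selection
buys the most when conditions are scarce. Exactly collinear columns give an `Inf` sentinel with a
warning rather than an error, since diagnosing a degenerate design is
precisely when the function is useful. Hierarchical clustering of media
(`cluster_media`) uses Ward's method on Euclidean distances of the
standardized compositions — the standard choice for spotting
near-duplicate media before blending. Whether clustering should use raw
or standardized concentrations is genuinely open; standardized is the
default (it matches the design mathematics), raw is a flag away.

## 3. The modeling protocol

Culture datasets have replicate structure: each designed condition is
cultured in several biological replicates. Every random partition in the
package is **grouped by condition** — train/test split (default 6:4),
cross-validation folds, and the test subsets used for baseline
comparison — because replicates of one condition share identical
explanatory variables; splitting them across partitions would leak the
condition's response level and inflate apparent accuracy.

Eleven regression algorithms cover three modeling assumptions: drastic
responses (random forest, classical gradient-boosted trees, regularized
gradient boosting), smooth nonlinearity (RBF-kernel support-vector and
Gaussian-process regression), and linear structure (partial least
squares, ridge, lasso, elastic net, linear SVR, linear GPR). Defaults use
small documented grids (at most 8 points per algorithm) because the
protocol, not the grid, is the substance; grids are overridable per
model. The tuning criterion is the maximum of mean minus standard
deviation of validation R² across folds — a pessimistic criterion that
trades a little accuracy for stability. PLS components are additionally
capped at the numerical rank of `X` minus one, since blending data are
rank deficient by construction and components beyond the rank are
degenerate.

Models are compared with a baseline that predicts the training-mean
response: per grouped test subset (default 5), one-sided paired t-tests
ask whether the model's MSE is lower, with Holm correction across the
candidate models. A model is *superior* when it is significantly better
than baseline and generalizes: both the R² and the MSE train/test ratios
must lie within `band` (default 0.15) of 1. Two readings of the band were
possible (`|ratio - 1| <= band` versus `ratio` in `[1/(1+band), 1+band]`);
the implementation uses the first, which matches its worked examples.
Note a caveat measured during development and asserted in the test suite
only in its robust form: with ~48 test conditions the subset-level MSE
ratio itself carries roughly 20% sampling noise, so the 15% band is a
coin flip even for a well-specified linear model on clean linear data.
The band flags *candidate* superior models; it is not a stable property
of the data-generating process at this sample size.

## 4. Component importance under multicollinearity

Permutation feature importance (PFI) measures the drop in test R² when
one variable is shuffled (default `J = 10` repeats; `J` is a variance
knob, not a bias knob, and 10 is stable at test sizes around 150).
Under correlation, plain PFI underestimates: a correlated partner carries
the same information and compensates for the shuffle. The adjusted
variant therefore co-shuffles each other variable `q` sample-by-sample
with probability `r'_{pq}`, a *shrunk* correlation: `|r|` is
Fisher-transformed, given a normal confidence interval with variance
`1/(m - 3)` (`m` = rows of the matrix used for correlations — the
training partition by default), and back-transformed; intervals spanning
zero set `r' = 0` (the correlation is treated as incidental), otherwise
`r'` is the conservative lower bound. Correlations near 1 are clamped at
`1 - 1e-12` before the transform to avoid infinities.

Two semantics of "co-shuffle" were possible: reuse the primary variable's
permutation for the gated samples, or draw an independent permutation per
partner. The implementation reuses the primary permutation, so `r' = 1`
reduces exactly to jointly permuting the pair — the behavior that makes a
duplicated predictive pair receive its full joint importance (the
mechanism the adjustment exists for, and what the tests assert).

The consensus step intersects each model's top fraction (default 25%) of
components across the superior models, with tiered membership reported at
5% steps. A PLS model additionally provides variable-importance-in-
projection (VIP) scores (mean squared VIP = 1), cross-checked in the
tests against the independent `mixOmics` implementation.

**What importance can and cannot say here.** The rank constraint of
Section 1 does not disappear at analysis time: all `d` component profiles
live in the `<= m`-dimensional span of the media, so distinct components
can be exactly aliased and a component's importance is attributable only
up to its correlation group. The adjusted PFI deliberately chooses
sensitivity over specificity — it protects correlated true drivers from
being overlooked at the price of elevating their partners. Consensus sets
should be read as "this correlated set of components matters", never as
per-component causal effects. Quantitatively, when `k` comparable effects
are planted among `d` components spanning only `rank <= m` dimensions,
each carries a marginal association of order `1/sqrt(k)` of the
explainable signal while every null component's alignment with the signal
direction has magnitude of order `sqrt(2/(pi * rank))`; for screening-
scale settings (`m = 11`, `d = 67`, `k = 12`) these are comparable, so
exact recovery of a planted 12-component set is not statistically
identifiable — a limitation of the problem geometry, not of any
particular estimator. The end-to-end acceptance test measures exactly
this recovery rate and is expected to fall short of its nominal target;
it is retained as an honest record of the ceiling.

## 5. Simulating dedicated mother-media sets

Commercial media impose their correlation structure; a dedicated media
set can be designed to minimize it. The simulation draws candidate `m x d`
media matrices with entries on `levels` discrete concentration levels
(default 5, values 0-4 in arbitrary relative units), screens them by a
penalty, and lets survivors compete on the design determinant:

- **penalty** (lexicographic, enforced by weight `H = d² + 1`): constant
  component columns or constant media rows (high), component pairs with
  `|r| > 0.9` (high), pairs with `0.7 < |r| <= 0.9` (one point each);
- **inner loop** (default 1000 draws): two strategies are provided.
  `"swap"` (default) maintains a working set and swaps each freshly drawn
  medium into the row where it most reduces the penalty — selecting a
  low-penalty *combination* of media from the stream of random draws.
  `"regenerate"` draws a fully fresh candidate each iteration and keeps
  the best. The swap strategy reaches substantially lower penalties for
  the same number of draws (asserted as a dominance test) and is the
  default; the regenerate strategy is the more literal "best random
  candidate" reading and is kept both as an option and as the reference
  implementation the compiled path is tested against.
- **outer loop** (default 100): each surviving candidate goes through the
  full design workflow (standardize, PCA at 99%, enumerate 6-unit blends,
  10,000-iteration search for 120 conditions), and the candidate with the
  maximal design determinant wins.

Reported metrics use the full pair count `d(d-1)/2` as denominator, at
the media level (across the `m` rows) and at the condition level (across
the `n` designed blend compositions). The condition-level mean `|r|` has
an irreducible floor: `d` columns spanning at most `m` dimensions have
typical pairwise cosines of order `sqrt(2/(pi*(m-1)))`, about 0.26 for 11
media — visible directly in the acceptance script's output. The
`correlation_sweep` runs the whole simulation per cell of a components ×
media grid; across the grid the media count dominates the fraction of
highly correlated pairs while the component count has little effect,
which is why "how many mother media" is the question that matters when
scaling a screening campaign.

## 6. The synthetic-data generator

Real CDM composition matrices are proprietary, so tests and examples run
on generated data emulating their statistical shape:

- **Composition** (`synth_composition`): a latent-factor model. Every
  component loads on one of `n_factors = 4` factors; the within-factor
  correlation is solved (via the Fisher-z tail) so that the *sample*
  fraction of pairs with `|r| > 0.7`, measured across only `m = 11` rows,
  hits `target_high_corr_fraction` (default 0.12). The point of solving
  for the sample statistic: at `n = 11`, sample correlations scatter
  widely around their true values, and a realistic matrix reaches a 12%
  high-`|r|` fraction through moderate true correlations plus sampling
  noise, not through blocks of near-duplicates. Columns are then shifted
  nonnegative and given heterogeneous lognormal scales — affine maps that
  leave every correlation untouched. Generation retries fresh draws until
  the achieved fraction is within ±0.05 of the target.
- **Response** (`synth_response`): linear effects on `k_true = 12`
  planted components (standardized condition-level concentrations,
  magnitudes 1 down to 0.4 with alternating signs), condition-level noise
  at half the signal SD (capping the condition-level explainable R² near
  0.8), and replicate noise solved in closed form so the
  between-condition share of the total sum of squares (SSB/TSS) lands at
  `ssb_target = 0.8` with 3 replicates — the variance structure of a
  well-run small-scale batch culture. The response is affinely mapped to
  a viable-cell-concentration-like scale (mean 1.26e7, SD 2.9e6
  cells/mL). Ground truth (which components, which effects) is returned
  in a separate object the analysis path never sees.

What the generator does **not** emulate: detection noise in the
composition measurements, non-linear dose-response (saturation,
depletion cliffs), component interactions, sparse presence/absence
block structure of real formulations, and any chemistry (solubility,
osmolality, pH). Passing tests on this generator therefore demonstrate
that the machinery is correct and that the workflow behaves as designed
under its own assumptions — not that any particular biological screening
will succeed.

## 7. Numerical conventions

- Standardization uses the population SD; zero-variance columns are
  dropped with a warning (commercial media can share a component level
  exactly) and recorded, never silently discarded.
- PCA signs follow "largest-magnitude loading positive", making loadings
  and scores reproducible across platforms.
- Gram determinants are clamped to zero when negative within floating-
  point noise (the matrix is PSD by construction).
- Enumeration order of blends is colexicographic and documented; row
  order is part of the reproducibility contract.
- All stochastic steps (search, splits, folds, subsets, shuffles,
  simulations) consume R's RNG, so one `set.seed`/`seed =` pins an entire
  pipeline; compiled loops draw from the same stream as their R
  reference paths, which is tested.
- Default problem sizes in the tests and the acceptance script (5 seeds
  for the simulations, 25 seeds for the end-to-end recovery run, design
  searches of 2000-10000 iterations) were chosen to characterize each
  quantity's variability while keeping a full run in the minutes range on
  one core.
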