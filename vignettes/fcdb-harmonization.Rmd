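---
title: "Harmonizing two food composition databases: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing two food composition databases: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcdblink)
```

## The problem and the model

A dish corpus in the Nutrition5k dialect carries, per dish, the served mass
of each ingredient plus energy and macronutrient values computed under a
source FCDB ("declared" side, B). Re-labelling the corpus under a target
FCDB (A) requires five stages: parsing and reshaping, curation, matching,
imputation, and aggregation. The dish total for component $c$ under FCDB
$A$ is

$$T_{d,c} = \sum_{i \in d} \frac{g_{i}}{100}\, x_{m(i),c}$$

where $g_i$ is the served mass of use $i$ and $x_{m(i),c}$ the per-100 g
value of the matched item $m(i)$. Everything downstream (agreement battery,
regression) compares $T^{A}$ with the declared totals $T^{B}$ via
$\Delta = T^A - T^B$.

### Why carbohydrates disagree by construction

The declared side reports carbohydrate *by difference*
($100 - \text{water} - \text{protein} - \text{fat} - \text{ash} -
\text{alcohol}$), which includes dietary fiber; the target side defines
*available* carbohydrates (soluble carbohydrates + starch), which excludes
it. With no other noise, every dish's carbohydrate difference is exactly
the negated fiber mass of its ingredients. This single definitional fact
produces the negative median carbohydrate difference that the package's
synthetic world reproduces and its tests pin down.

## Tunable parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| trace thresholds | 0.6 / 0.06 / 0.006 | component unit | analytical quantification criteria; resolved to 0.5 / 0.05 / 0.005 |
| totals tolerance | 1e-3 (relative) | — | declared dish totals vs block sums; violations warn, never error, because raw corpora contain real mass errors that curation fixes later |
| outlier rule | mass > 100 × ingredient median, ≥ 3 uses | g | reproducible stand-in for eyeball-plus-image inspection; detection only, corrections are explicit table rows |
| similarity metric | SD-scaled Euclidean on (energy, protein, fat, carb, water) | per 100 g | the methodology names the five criteria but no metric; scaling stops kcal dominating grams; ties break to the smallest food_id |
| chloride factor | 35.453/22.990 ≈ 1.5417 | — | Cl/Na molar-mass ratio, our reading of "calculated from the value for sodium" |
| energy conversion | 4.184 kJ/kcal | — | kcal primary in all reports |
| MM tuning | c₀ = 1.5476 (b = 0.5), c = 4.685, 500 subsamples, tol 1e-8, 200 iter | — | 50% breakdown S stage + 95% efficiency M step, the lmrob-style convention; seed is a required config field |

## Numerical and design choices

* **Dialect presets.** The public cafeteria files order the dish header
  `dish_id, total_calories, total_mass, …` with no ingredient-count column;
  a second `mass_first` preset carries `num_ingrs` and puts mass first.
  Default is the public preset. UTF-8, "." decimals, no thousands
  separators, enforced.
* **Duplicate dish ids** across café files are preserved and warned about;
  nothing in the format forbids them.
* **Missing summands in derived components** (equivalents, PUFA sums):
  policy is configurable; the default treats missing as zero *with a flag*,
  because the source computed equivalents database-wide despite heavy PUFA
  missingness. All-missing inputs yield missing, except the residual PUFA
  sum whose empty/missing input is defined as 0 (flagged).
* **Negative available carbohydrates** (fiber > carbohydrate-by-difference)
  are floored at 0 with a warning: a negative nutrient mass is meaningless.
* **Quantiles** are type-7 everywhere (linear interpolation of order
  statistics), because medians and quartiles feed acceptance checks.
* **Quintile ties** go to the lower quintile (right-closed cuts). Heavy
  ties can leave fewer than five distinct classes; the cross-tab records
  this (`degenerate`) instead of resampling.
* **KS test** uses estimated parameters without a Lilliefors correction, as
  in the methodology it follows; the Wilcoxon signed-rank test is exact for
  n ≤ 25 without ties and a continuity-corrected normal approximation
  above.
* **Bland–Altman** plots use the conventional axes (x = pairwise mean,
  y = difference); the numbers are unaffected by the axis convention.
* **Δ sign convention** is harmonized-minus-declared throughout, applied
  uniformly to the bias, the limits of agreement and the difference
  summaries, so a reported bias and its difference-distribution mean can
  never disagree in sign.
* **Recipes** must sum to 100 g and carry no yield or retention factors —
  deliberately mirroring the upstream limitation; the recipe inherits the
  cooked flag if any component is cooked.
* **CIs** are estimate ± 1.96 × robust SE (asymptotic normal), matching the
  symmetric presentation of the published coefficient table. Joint tests
  report both χ² and F references (df₂ = n − p).
* **Exact-fit degeneracy.** When more than half the residuals are exactly
  zero the S scale collapses to 0; the fit returns the exact-fit
  coefficients with zero covariance rather than dividing by zero.

## The MM estimator, from scratch

`robustbase` is not a dependency; `fit_mm()` implements the two stages
directly. The S stage draws 500 elemental subsamples of size p, applies two
cheap IRLS steps toward the S objective to each candidate, keeps the best
five by M-scale (the scale solving mean ρ(r/s) = 0.5 with the 50%-breakdown
bisquare), and refines those to convergence. The M step then runs IRLS with
the 95%-efficiency bisquare at the fixed S scale until the largest
coefficient change is below 1e-8 (cap 200 iterations; non-convergence is
flagged, not hidden). The covariance is the standard asymptotic form
$s^2\,\overline{\psi^2}/\overline{\psi'}^{\,2}\,(X^\top X)^{-1}$.

## What the synthetic world does and does not establish

`generate_synthetic()` writes paired FCDBs sharing items (B = A times
per-component lognormal noise, with B's carbohydrate redefined to include
fiber when the offset is on), dish files with 1 + Poisson(2.5) ingredients
(median 3, cap 12) and lognormal per-use masses (median 40 g, so dish
masses have median ≈ 150 g, right-skewed), a planted strategy mix (~70%
exact), cooked/raw discrepancy flags on ~25% of ingredients (their declared
macros deflated by 10%), planted trace and missing cells on components each
imputation strategy can resolve, two plate-only dishes, blanked ingredient
names (one catalogue-recoverable, one "deprecated" needing the manual map),
and one ×1000 mass outlier with its correction row. The generator computes
every dish total itself by direct arithmetic; the pipeline must reproduce
those totals to ~1e-9 and the strategy audit exactly.

A green synthetic run establishes that the *mechanics* are right: parsing,
curation, matching, imputation, aggregation, the agreement statistics, and
the qualitative carbohydrate-deficit mechanism. It does **not** establish
the published corpus-level numbers (median mass 145 g over 5004 dishes,
the specific difference summaries and regression coefficients): those
require the proprietary Italian FCDB, the real Nutrition5k download and the
nutritionists' full curation tables, none of which can ship here. The
cross-tab agreement and kappa checks instead enter through the published
5×5 percentage matrices, which are inputs, not claims.

The planted regression betas default to the published carbohydrate-model
coefficients; residual SD 3 g, 10% gross outliers at +40 g (one-sided, the
harder case for a location estimator) were fixed once as a plausible
contamination geometry. Stochastic suites run scaled down to fit a desk
budget (n = 600 × 50 replicates for recovery, n = 200 × 300 for the Wald
size, fast-S subsamples reduced to 30–50 in simulations); thresholds —
≥ 90% CI coverage, MM bias < OLS bias, Wald size in [0.02, 0.10] — were
fixed before running, the size band being the 99% binomial envelope around
0.05 at 300 replicates, slightly widened for the asymptotic χ² reference at
n = 200.

## Known limitations

* Table-driven matching only: no fuzzy name resolution, by design.
* No yield/retention correction anywhere.
* Borrowed values adopt the source FCDB's component definitions untouched,
  so borrowed ingredients dilute the definitional carbohydrate signal; the
  offset-only test world therefore sets the borrowed fraction to 0.
* The imputation plan is first-match-wins over an ordered rule table;
  plans with overlapping rules must order them deliberately.
* The asymptotic MM covariance omits the finite-sample S-stage correction
  terms; at the corpus sizes involved (hundreds to thousands of dishes)
  the difference is well inside the reported precision.
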