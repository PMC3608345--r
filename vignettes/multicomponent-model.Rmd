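---
title: "The multicomponent anthropometric model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multicomponent anthropometric model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthrocomp)
```

## The model

Body composition in growing boys is summarised here by three components
measured by dual-energy X-ray absorptiometry (DXA): fat mass (FM), bone
mineral content (BMC) and lean soft tissue (LST), all in kg. The package
implements a *simultaneous* anthropometric predictor of the three: a single
multivariate linear model

$$ Y_{n\times 3} = X_{n\times 5}\,B_{5\times 3} + \varepsilon_{n\times 3}, $$

whose five predictors are stature (cm), body mass (kg), the suprailiac and
horizontal abdominal skinfolds (mm), and the somatic maturity offset (years
from peak height velocity, PHV). The model is **intercept-free**: a subject
with all-zero measurements is predicted zero mass, and each component is a
plain inner product of the measurement vector with a coefficient column.
Estimating the three equations jointly, rather than as three unrelated
regressions, is what lets a single parsimonious predictor set serve all
three components and keeps the between-component error structure in view
(Pillai trace tests operate on the full residual cross-product matrices).

The published coefficient matrix for boys aged 8–18 is embedded as a
delimited-text resource and returned by `published_coefficients()`:

```{r}
published_coefficients()
```

The maturity offset, when not measured directly, is computed from the
anthropometric equation for boys implemented in `maturity_offset()`, using
age, stature, sitting height, body mass and leg length (stature minus
sitting height). It is negative before the growth spurt's peak and positive
after; in the development sample it spans roughly −4.7 to 4.5 years.

Body mass used for prediction is the scale-measured mass, not the mass a
DXA scan reconstructs; the two are close but not identical, and the scale
measurement is the one available in field settings, which is the model's
use case.

### Worked example

```{r}
rec <- anthropometric_record(
  height = 148.3, weight = 40.0,
  sk_suprailiac = 18.7, sk_horiz_abdominal = 20.0, phv = -1.6
)
predict_components(rec)
product_breakdown(rec)
```

The component totals come out near the subject's body mass (the weight
column of the coefficient matrix sums to 0.995 across components), which is
the mass-closure property one expects of a three-component decomposition.

### Extrapolation and negative masses

The coefficients were developed on a specific range of inputs (e.g. stature
120.3–196.8 cm, suprailiac skinfold 2.8–64.5 mm). Out-of-range inputs are
*predicted anyway* but flagged with an `anthrocomp_extrapolation` warning;
an intercept-free linear map can then produce negative masses, which are
returned unclipped with their own warning class so that downstream code can
decide what to do. Units are fixed (cm, kg, mm, years); nothing is inferred
from magnitudes.

## Fitting conventions

`fit_multivariate_ls()` solves the normal equations
$\hat B = (X'X)^{-1}X'Y$, which for a full-column-rank design is identical
to stacking the three univariate least-squares fits column-wise (the test
suite asserts this equivalence to 1e-10 against R's QR path). Rank-deficient
designs are refused with the names of the dependent columns.

Two conventions deserve explicit statement because the literature is
inconsistent about them for intercept-free models:

* **R².** For fits without an intercept, `r2` uses the *uncentered* total
  sum of squares $\sum y_i^2$ — the same convention `summary.lm()` prints —
  and `adj_r2` follows the matching $1-(1-R^2)\,n/(n-p)$ form. This is the
  convention under which the published precision values of the development
  study are internally consistent with the published residual errors. The
  centered version is always reported alongside as `r2_centered`, because
  the cross-validated statistic (below) is conventionally centered and the
  two should not be compared across conventions.
* **Degrees of freedom.** `see_residual` uses $\sqrt{SSE/(n-p)}$ with $p$
  the number of fitted columns and no extra intercept df.

### Pillai trace tests

`pillai_trace_test()` compares the fitted model to the model without a term
set: $H$ is the growth of the residual cross-product matrix when the terms
are removed, $E$ the full model's residual cross-product, and
$V=\mathrm{tr}[H(H+E)^{-1}]$. The F approximation uses
$s=\min(q,h)$, $m=(|h-q|-1)/2$, $n^*=(\nu_e-q-1)/2$ with $q$ responses, $h$
hypothesis df and $\nu_e=n-p$ error df; for $h=1$ the transform is exact,
which is why the package's type-I-error simulations drop a single column —
the 0.05 nominal level is then a sharp target rather than an approximation.
Noise-free (degenerate) problems, where $H$ and $E$ both vanish, are
refused with a classed error rather than returning an ill-conditioned
trace.

### Collinearity

`collinearity_ratio()` reports the ratio of the extreme eigenvalues of
$X'X$ and the conventional bands: below 100 weak, 100–1000 (inclusive)
moderate, above 1000 severe. The default operates on the raw $X'X$;
`scale = "center"` or `"correlation"` are available because the bands are
sometimes applied to scaled matrices. For this model's predictors, whose
units differ by two orders of magnitude, the raw ratio is large
(≈10⁴ for moments-typical cohorts) while the correlation-scaled ratio is
≈70; the development study reported a single intermediate value (≈167)
whose scaling convention is not recoverable, so no acceptance-grade claim
is attached to the diagnostic — it is a reporting tool.

### Common-predictor selection

`select_common_predictors()` mimics the development pipeline: an
intercept-free forward/backward stepwise per response with partial-F
thresholds (defaults `entry_alpha = removal_alpha = 0.05`; both
configurable since the original thresholds are unstated), intersection of
the three retained sets, then a joint pruning pass that removes
intersection members whose Pillai test is non-significant *and* whose
removal keeps the collinearity category at moderate or better. Every entry
and removal is logged with its statistic and p-value, making a selection
replayable; the test suite replays the log and checks it reproduces the
retained sets. An empty intersection is a legitimate result (returned with
an empty `final`, not an error).

## Cross-validation

`press_loo()` computes the leave-one-out prediction error per response with
the hat-matrix identity: the deleted residual is $e_i/(1-h_{ii})$, so

$$ \mathrm{PRESS} = \sum_i \frac{e_i^2}{(1-h_{ii})^2}, $$

with the leverages $h_{ii}$ taken from the QR factorisation of $X$ (they
are non-negative and sum to $p$). `press_naive()` performs the literal $n$
delete-one refits and is retained as an independent oracle; the two agree
to 1e-8 relative on randomized problems. Leverages within `tol` of 1 are
refused by observation index, since the deleted residual is then undefined.

The cross-validated coefficient of determination is
$R^2_{PRESS} = 1-\mathrm{PRESS}/\sum_i(y_i-\bar y)^2$ (centered
denominator, `r2_press()`), which can be negative for models that predict
worse than the mean; because each deleted residual dominates its ordinary
counterpart, $R^2_{PRESS}$ never exceeds the fitted $R^2$ in either
convention. The package also reports `rmse_press` $=\sqrt{\mathrm{PRESS}/n}$
(kg) under its own name: the development study's printed per-response
"PRESS standard errors" are not reproducible from its printed PRESS values
under any df convention we could identify, so the package deliberately does
not claim to reproduce that statistic.

### Technical error of measurement

For duplicate measurement pairs, `technical_error()` implements the
Dahlberg form $\mathrm{TEM}=\sqrt{\sum_i d_i^2/2m}$ and
$\mathrm{TEM}\%=100\cdot\mathrm{TEM}/\bar x$ (the exact formula behind the
development study's error table is not printed there; Dahlberg's is the
standard choice for intra-observer error and is documented here as such).
`generate_duplicates()` inverts the estimator for testing: a repeat
measurement equal to the first plus Gaussian error with SD
$\tau\sqrt 2$ has expected TEM $\tau$.

## The synthetic-cohort generator

No subject-level data accompany the published model, so the package ships
a generator that emulates the development sample's *printed* statistical
structure: per-variable means, SDs and observed ranges for ten variables
(stature, body mass, sitting height, age, PHV, the two skinfolds, FM, BMC,
LST), and their pairwise correlations.

Three design problems had to be solved once, and their resolutions are part
of the package's contract:

* **The published correlation table is incomplete.** The three
  response–response pairs are filled by a product rule through body mass
  (the strongest shared covariate): e.g.
  $r(\mathrm{FM},\mathrm{LST}) := r(\mathrm{FM},W)\,r(\mathrm{LST},W)$.
  Sitting height has no published correlations at all; it enters through a
  single assumed $r(\mathrm{Sh},\mathrm{Ht}) = 0.97$ (sitting height tracks
  stature very closely throughout growth) and the same product rule through
  stature. The completed matrix is indefinite (smallest eigenvalue ≈
  −0.28, an unavoidable consequence of mixing printed and imputed entries),
  so the generator samples from the nearest positive-semidefinite repair
  (`Matrix::nearPD`, unit diagonal kept). Both matrices are stored:
  `correlation` exactly as entered, `correlation_psd` as sampled. The
  repair moves some entries by up to ≈0.12, so round-trip checks are
  written against the repaired matrix, which is the generator's actual
  target.
* **Range truncation distorts moments.** The printed ranges are sample
  min–max values and are strongly asymmetric around the means (FM: mean
  9.3, SD 7.5, range 1.3–41.8 — the real distribution is right-skewed).
  Rejecting Gaussian draws outside the ranges would inflate the FM mean by
  ≈20%. `generate_cohort()` therefore uses a Gaussian copula with
  *doubly-truncated-normal marginals whose latent location and scale are
  solved numerically so that the post-truncation mean and SD equal the
  printed targets*. Every draw lies inside its range and the marginal
  moments are matched by construction, at the cost of mild correlation
  attenuation through the copula (observed ≲0.03 at these parameter
  values, inside the ±0.05 round-trip tolerance the tests enforce).
* **The printed age SD is infeasible for this family.** SD 2.99 on the
  range 8–18 exceeds the truncated-normal supremum
  $(b-a)/\sqrt{12}\approx 2.887$ (ages in such samples are nearly discrete
  uniform, whose SD is larger). The generator attains ≈2.84; for this
  reason the SD round-trip tolerance is 7% where the mean tolerance is 2%
  (with an absolute floor of 2% of the SD for PHV, whose mean of −0.5 y is
  too close to zero for a relative criterion to be meaningful).

Gaussian marginals are an explicit modelling choice, not a claim about the
population: skinfolds are visibly right-skewed, and a range-truncated
lognormal option (`lognormal_skinfolds = TRUE`) is provided but off by
default so that the default generator stays moment-faithful. PHV is drawn
jointly as a correlated covariate (that is how the correlation table
treats it); `phv_from_equation = TRUE` instead recomputes it from age,
stature, sitting height and mass for consistency testing, at the cost of
its marginal no longer being moment-calibrated.

`generate_from_coefficients()` serves a different purpose — estimator
validation against a known truth — and so draws the five predictors from an
*untruncated* multivariate normal (exact second moments) and builds
responses as $XB+\varepsilon$ with configurable noise SDs, defaulting to
the development study's per-response residual errors (1.666, 0.192,
1.748 kg). With those defaults at $n=408$, refitting recovers the embedded
coefficients without bias and reproduces the development study's fitted and
cross-validated precision within ±0.02 — the package's tests run 200 such
replicates, alongside 1000-replicate type-I-error calibration of the Pillai
test at $n=30$ and 50 randomized PRESS oracle-equivalence problems at
$n\le 60$; these sizes give Monte-Carlo error comfortably inside the bands
being checked while keeping the default suite fast.

What the generator does **not** emulate, and what passing tests therefore
do not establish about real data: measurement skew and heteroscedasticity
(DXA dispersion grows with body size), the discrete age structure and
athlete/non-athlete strata of the development sample, age-group mean
trajectories beyond what the age/PHV correlations induce, and any
population other than boys aged 8–18. Conclusions about real cohorts
require real cohorts.

All generators are pure functions of their arguments plus a `seed`; the
caller's RNG state is saved and restored around every draw, and the same
seed reproduces a cohort bit for bit.

## Numerical choices

* Normal-equation solve via LU on $X'X$ after an explicit QR rank check
  (the classical-inverse route is the method being implemented; the rank
  check supplies the error message the contract requires).
* Leverage guard in `press_loo()`: `tol = 1e-8` on $1-h_{ii}$.
* Pillai kernel refuses `rcond(H+E) < 1e-12`, and the test wrapper
  additionally refuses degenerate noise-free problems by comparing
  $\max|H+E|$ to $\max|Y'Y|$ at 1e-10 relative.
* Collinearity boundary convention: ratios of exactly 100 or 1000 classify
  as moderate; a smallest eigenvalue below 1e-12 of the largest reports an
  infinite ratio and `severe`.
* Truncated-normal moment matching minimises a scaled squared error with
  Nelder-Mead from two starts (the target parameters and a flat-density
  start) to tolerance 1e-14; quantiles and moments are evaluated in the
  numerically favourable tail via mirroring.
* Stepwise ties: the single best (smallest p) candidate enters per
  forward step and the single worst leaves per backward step, so the
  elimination order is deterministic; the trace records it.

## Limitations

The embedded equations are for boys aged 8–18 only; no female or adult
coefficients are shipped, and no alternative skinfold equations are
provided. DXA itself is a three-component convention, not the
four-component gold standard, so the model inherits that reference's
assumptions. The selection pipeline can be validated only against
synthetic constructions (the original candidate-by-candidate elimination
order was never published), and the collinearity diagnostic's published
magnitude cannot be tied to a scaling convention, as discussed above.
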