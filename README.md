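# anthrocomp

Simultaneous anthropometric prediction of body composition for boys aged
8–18. From five field measurements — stature (cm), body mass (kg), the
suprailiac and horizontal abdominal skinfolds (mm), and the somatic
maturity offset (years from peak height velocity) — the package predicts
the three DXA body components at once: **fat mass (FM)**, **bone mineral
content (BMC)** and **lean soft tissue (LST)**, all in kg.

The core is an intercept-free multivariate linear model

```
Y (n x 3) = X (n x 5) B (5 x 3) + E,
```

fitted by least squares through the normal equations, with the three
response equations estimated *jointly* rather than as unrelated
regressions. Around the published coefficient matrix (embedded as a
plain-text resource) the package provides the full model-development
pipeline so the approach can be studied, stress-tested and re-derived on
synthetic cohorts:

* `predict_components()`, `product_breakdown()` — apply the published
  coefficients, with per-term product tables and extrapolation warnings;
* `maturity_offset()` — the anthropometric maturity-offset equation for
  boys (years from peak height velocity);
* `fit_multivariate_ls()`, `pillai_trace_test()`, `collinearity_ratio()`,
  `select_common_predictors()` — multivariate least squares, Pillai trace
  term tests with the standard F approximation, eigenvalue-ratio
  collinearity bands, and logged common-predictor stepwise selection;
* `press_loo()`, `press_naive()`, `r2_press()`, `technical_error()` —
  leave-one-out PRESS cross-validation (hat-matrix shortcut, with the
  literal delete-one refit kept as an oracle) and Dahlberg technical error
  of measurement;
* `generate_cohort()`, `generate_from_coefficients()`,
  `generate_duplicates()`, `cohort_summary()` — seeded synthetic cohorts
  matching the development sample's published means, SDs, ranges and
  correlation structure (Gaussian copula with moment-calibrated truncated
  marginals);
* `cmd_predict()` / `cmd_fit()` / `cmd_validate()` / `cmd_simulate()` —
  file-to-file pipeline commands, plus a thin shell wrapper in
  `inst/cli/anthrocomp`.

Intended users: exercise scientists, pediatric clinicians and
biostatisticians who need DXA-free body-composition estimates in field
settings, or who want a fully tested reference implementation of the
simultaneous-prediction methodology.

## Worked example

A 13-year-old boy: stature 148.3 cm, body mass 40.0 kg, suprailiac
skinfold 18.7 mm, horizontal abdominal skinfold 20.0 mm, maturity offset
−1.6 y (1.6 years before peak height velocity).

```r
library(anthrocomp)

rec <- anthropometric_record(
  height = 148.3, weight = 40.0,
  sk_suprailiac = 18.7, sk_horiz_abdominal = 20.0, phv = -1.6
)
predict_components(rec)
#> Body composition (kg): FM 9.28 | BMC 1.57 | LST 28.39
```

So the model attributes 9.28 kg of this boy's mass to fat, 1.57 kg to bone
mineral and 28.39 kg to lean soft tissue — 39.25 kg in total, closing to
within 2% of his measured 40.0 kg body mass, as expected of a
three-component decomposition. The per-term breakdown shows where each
kilogram comes from (products in kg):

```r
product_breakdown(rec)
#> Per-term products of the multicomponent prediction
#>           predictor measure beta_fm product_fm beta_bmc product_bmc beta_lst product_lst
#>              height   148.3 -0.0857    -12.709   0.0032      0.4746   0.0820      12.161
#>              weight    40.0  0.3139     12.556   0.0392      1.5680   0.6419      25.676
#>       sk_suprailiac    18.7  0.1970      3.684  -0.0095     -0.1777  -0.1964      -3.673
#>  sk_horiz_abdominal    20.0  0.2350      4.700  -0.0105     -0.2100  -0.2321      -4.642
#>                 phv    -1.6 -0.6571      1.051   0.0525     -0.0840   0.7047      -1.128
#> Totals (kg): FM 9.28 | BMC 1.57 | LST 28.39
```

The development pipeline runs end to end on synthetic cohorts. Here a
known-truth cohort at the development-sample size (n = 408, noise at the
published residual errors) is refitted and cross-validated:

```r
coh <- generate_from_coefficients(408, seed = 7)
X <- as.matrix(coh[, 1:5]); Y <- as.matrix(coh[, 6:8])
press_loo(X, Y)
#> PRESS leave-one-out cross-validation (n = 408)
#>                   fm     bmc       lst
#> PRESS      1199.0128 13.8985 1198.8909
#> R^2 PRESS     0.9455  0.9457    0.9818
#> RMSE PRESS    1.7143  0.1846    1.7142
```

The cross-validated R² values of ~0.95–0.98 say that even under
leave-one-out deletion the model explains the bulk of the between-subject
variance at this noise level.

See `vignettes/multicomponent-model.Rmd` for the model's assumptions, the
fitting and cross-validation conventions, the synthetic-cohort design, and
known limitations.

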