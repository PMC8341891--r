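# distallom

Distortion-aware allometric regression for fossil measurement data.

## The problem

Allometry — the scaling of one body measurement against another — is
estimated from ontogenetic series by regressing log-transformed
measurements: `log10(y) = α·log10(x) + β`, where the slope α is the
coefficient of allometry (1 = isometry). For fossils this is
complicated by taphonomic distortion: crushing, shearing and
displacement perturb some measurements away from their in-life values.
The usual remedies — dropping visibly distorted specimens, or ignoring
the problem — either discard scarce data or violate the homoscedasticity
assumption of ordinary least squares.

`distallom` implements the statistical alternative: keep every
specimen, score each *measurement* as distorted (`C = 1`) or not
(`C = 0`), and fit

```
Y = αX + β + ε + Cγ,   ε ~ N(0, σ²),  γ ~ N(0, τ²)
```

so that distorted measurements carry extra mean-zero noise. Marginally
this is a two-group heteroscedastic regression, `Var(Y|X) = σ² + C·τ²`
— the exact marginal form of a linear mixed model with a per-specimen
random distortion effect. When the flags carry no real signal the fit
collapses to OLS with `τ̂² = 0`, so cautious over-flagging is safe.

The package is aimed at palaeontologists and morphometricians working
with small (n ≈ 10–50), partially deformed specimen samples. It
provides:

* **measurement IO** — schema-mapped CSV reading, per-measurement
  distortion flags, pairwise (not listwise) handling of missing
  measurements, Shapiro–Wilk screening
  (`read_measurements()`, `to_log_pairs()`, `normality_screen()`);
* **estimators** — OLS (`fit_ols()`) and the distortion-aware model
  (`fit_distortion_model()`, ML or REML via a 1-D profile likelihood in
  `λ = τ²/σ²`), a boundary-aware likelihood-ratio test for the
  distortion variance (`lrt_distortion()`), and mm-scale prediction
  (`predict_feature()`);
* **a generative simulator** of distorted allometric datasets
  (`simulate_dataset()`) with binomial or fixed-count distortion
  designs;
* **a Monte Carlo study driver** (`run_study()`) comparing the
  estimators across sample sizes on shared draws, with paired t-tests
  and kernel-density summaries;
* **a nonparametric specimen bootstrap** (`run_bootstrap()`) with
  percentile 95% intervals.

Results are tibbles throughout; fitted objects have `tidy()`/`glance()`
methods and study/bootstrap results have `autoplot()` methods.

## Worked example

A synthetic cranial table ships with the package: 16 specimens, snout
length missing for one (the feature was not measurable), 8 of the 15
snout measurements flagged distorted.

```r
library(distallom)

path <- system.file("extdata", "synthetic_cranial_measurements.csv",
                    package = "distallom")
tab   <- read_measurements(path)
pairs <- to_log_pairs(tab, "skull_length", "snout_length")
fit   <- fit_distortion_model(pairs)   # REML by default
fit
#> Allometric fit (hetero-reml), n = 15 (8 distorted)
#>   slope (coef. of allometry): 1.067
#>   intercept:                  -0.7631
#>   residual SD (sigma):        0.05052
#>   distortion SD (tau):        0.1517
#>   log-likelihood:             15.28

lrt_distortion(pairs)
#>   statistic    df p_value
#> 1      7.89     1 0.00497

predict_feature(fit, 250)   # expected snout length on a 250 mm skull
#> 62.4 mm
```

The fitted slope of ~1.07 is close to isometry; the distortion SD
(τ̂ ≈ 0.15 log10 units, i.e. roughly ±40% on the mm scale) is three
times the residual SD, and the likelihood-ratio test (χ²(1) = 7.89,
p = 0.005) says the flagged measurements really are noisier. A
5000-replicate specimen bootstrap compares the three modelling choices:

```r
bt <- run_bootstrap(pairs, bootstrap_config(replicates = 5000, seed = 1))
bt$summary[, c("model", "median", "q2.5", "q97.5")]
#>   model           median  q2.5 q97.5
#> 1 glmm_full        1.07  0.352  1.32
#> 2 ols_full         0.846 0.154  1.28
#> 3 ols_undistorted  1.11  0.822  1.33
```

The distortion-aware fit and the undistorted-only regression agree
(medians 1.07 vs 1.11) while naive OLS on the full table is dragged
toward 0.85 by the deformed snouts — the pattern the model is designed
to correct, here without discarding half the sample.

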