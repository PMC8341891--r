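---
title: "Distortion-aware allometric regression: model, estimation and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distortion-aware allometric regression: model, estimation and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Allometric scaling between a focal measurement $y$ (mm) and a reference
measurement $x$ (mm) follows a power law, linear after log
transformation. All fitting in `distallom` happens on the base-10 log
scale: a slope of 1 is isometry, and parameters stay interpretable
against the mm scale (an intercept difference of $\delta$ multiplies
every back-transformed prediction by $10^\delta$).

Taphonomic distortion is modelled as extra, mean-zero, Gaussian noise
attached only to measurements scored as distorted. With
$c_i \in \{0, 1\}$ the per-measurement distortion flag,

$$ y_i = \alpha x_i + \beta + \varepsilon_i + c_i \gamma_i, \qquad
   \varepsilon_i \sim N(0, \sigma^2), \quad \gamma_i \sim N(0, \tau^2). $$

A mixed-model formulation would give each distorted specimen its own
random effect $\gamma_i$; because each specimen contributes one
observation per feature pair, the marginal distribution is exactly a
heteroscedastic linear regression with

$$ \mathrm{Var}(y_i \mid x_i) = \sigma^2 + c_i\,\tau^2 . $$

`distallom` fits this marginal form directly. The likelihood is
identical to the mixed model's and no latent variables are needed.
Key assumptions, stated plainly:

* distortion is **non-directional** (mean zero). Crushing that
  systematically shortens a feature violates this and should be
  modelled as a fixed effect instead — out of scope here;
* flags are assigned **per measurement**, not per specimen, since
  deformation is rarely uniform across a skull or skeleton;
* the reference measurement $x$ is treated as reliable. Total lengths
  are typically the most robust measurements; if a reference
  measurement is itself flagged, `to_log_pairs()` warns and keeps the
  focal flag.

## Estimation

For fixed variance ratio $\lambda = \tau^2/\sigma^2$, weighted least
squares with weights $w_i = 1/(1 + c_i\lambda)$ gives closed-form
coefficients, and the profiled residual variance is the weighted RSS
over $n$ (ML) or $n - 2$ (REML). That reduces the whole fit to a
smooth one-dimensional search over $\log\lambda$, run on $[-12, 12]$
with tolerance $10^{-8}$, plus an explicit evaluation of the boundary
$\lambda = 0$. If the boundary value is at least as good as the
interior optimum, the boundary is taken, so a fit with no detectable
distortion variance is *exactly* the OLS fit — there is no numerical
fuzz to confuse downstream equality checks, and the likelihood-ratio
statistic is non-negative by construction. The search needs no random
restarts: the profile objective is a smooth function of one variable,
and the test suite verifies the optimum against a staged
two-dimensional grid search over $(\sigma^2, \tau^2)$ and against an
independent generalized-least-squares implementation.

REML is the default criterion, as is conventional for variance
components (it removes the downward bias from estimating two fixed
effects). The likelihood-ratio test always refits both models by plain
ML. Because the null hypothesis $\tau^2 = 0$ sits on the boundary of
the parameter space, referring the statistic to $\chi^2_1$ is
conservative; the standard 50:50 mixture of a point mass at zero and
$\chi^2_1$ is available via `boundary_mixture = TRUE` but the plain
reference is the default, matching common practice.

With fewer than about five measurements in either flag group the
variance component is poorly identified. The fit warns rather than
refuses: in that regime the estimate tends to the boundary and the
model degrades gracefully to OLS, which is the behaviour a cautious
scorer wants. With an empty (or full) distorted group $\tau^2$ is not
identifiable at all and is fixed at zero with a warning.

## What the simulator emulates

`simulate_dataset()` generates datasets mimicking a small cranial
measurement series: log10 reference sizes drawn from
$N(2.39, 0.14^2)$ (about a 245 mm skull, varying by roughly a third),
generating slope $0.91$ and intercept $-0.37$ (slightly negative
allometry of a snout-type measurement), and distortion noise with SD
$0.4$ — about 1.5 times the typical residual SD, i.e. deformation
strong enough to matter.

Residual variation is specified as "mean 0.3, SD 0.1". The package
reads this as a **per-dataset residual SD** drawn from $N(0.3, 0.1)$
(truncated positive by redraw; the truncation triggers with
probability $\approx 0.13\%$), with the errors themselves mean-zero.
The alternative, literal reading — errors drawn from $N(0.3, 0.1)$,
shifting every response up by $0.3$ — would make OLS on clean data
recover an intercept near $-0.07$ rather than the generating $-0.37$,
destroying the validity check that clean-data fits match the
generating parameters; it is retained for sensitivity analysis as
`resid_interpretation = "literal_mean"`. Under the default reading the
marginal clean-data residual variance is
$E[s^2] = 0.3^2 + 0.1^2 = 0.1$, which the simulator tests verify by
Monte Carlo.

Draws come from a single seeded stream in a fixed order — $x$, then
the dataset-level residual SD, then $\varepsilon$, then $\gamma$, then
$c$ — so one integer seed pins down the entire dataset.

Two distortion designs are provided. The binomial design flags each
specimen independently with probability $p$ (default $0.5$) and
redraws until both groups have at least five members, honouring the
block-size guidance for variance components; this is only feasible
from $n = 15$ up, so below that the fixed-count design must be used
(5 undistorted / 5 distorted at $n = 10$; a largely distorted
5/10 variant is available at $n = 15$). The study driver applies
exactly this mapping by default.

What the simulator does **not** emulate — and hence what passing tests
cannot certify about real data: directional (biased) deformation,
measurement error in $x$, non-Gaussian residuals, correlation between
distortion severity and size, and missing-data mechanisms that depend
on distortion. The bootstrap module exists precisely because real
tables violate some of these.

## The simulation study

`run_study()` draws **one** dataset per replicate and lets every model
see a view of that same draw: OLS on the clean responses (the
idealised benchmark), OLS on the distorted responses, the
distortion-aware fit, and OLS on the unflagged subset (the discard
tradition). Sharing draws makes the models directly comparable and the
paired t-test between replicate slope estimates well-defined.

Summaries per model and sample size are the mean, median and empirical
2.5%/97.5% quantiles (the "95% interval" of a replicate distribution;
linear-interpolation convention, `type = 7`) plus a Gaussian kernel
density on a 512-point grid spanning the estimates ± three bandwidths
(normal-reference bandwidth). Density grids are exported as data;
bandwidth choice is presentational and nothing numerical is compared
on it. Replicates whose fit fails (e.g. a singular subset) are dropped
and counted, and a study errors only if an entire cell fails.

## The bootstrap

`run_bootstrap()` resamples whole specimens with replacement and
refits, reporting percentile intervals — no BCa or studentised
corrections, keeping the interval definition identical to the
simulation study's. Each model resamples **its own data domain**: the
undistorted-only model resamples the unflagged subset at that subset's
size, so its distribution is an honest bootstrap of its own estimator
rather than a mixture over random subset sizes (the alternative,
resampling the full table then subsetting, is available via
`resample_full_then_subset = TRUE`). Degenerate resamples — fewer than
two distinct $x$ values, or an emptied flag group for the
distortion-aware model — are skipped and counted rather than redrawn,
preserving independence across replicates; if more than half the
resamples are degenerate the bootstrap aborts with an error naming the
model.

## Numerical choices, in one place

* log base 10 everywhere; all variances are on the log10 scale.
* Profile search on $\log\lambda \in [-12, 12]$, tolerance $10^{-8}$;
  boundary $\lambda = 0$ evaluated explicitly and preferred on ties.
* REML divisor $n - 2$ (two fixed effects); OLS `residual_sd` uses the
  unbiased $n - 2$ divisor while its log-likelihood is evaluated at
  the ML variance, so likelihood comparisons are like-for-like.
* LRT statistic truncated at zero; $\chi^2_1$ reference by default.
* Quantiles: `type = 7`; densities: `stats::density`, `bw.nrd0`,
  512 points, `cut = 3`.
* Binomial designs redraw at most 10,000 times before erroring.

## Problem sizes used by the test suite

The packaged tests run the full 2000-replicate recovery experiment at
$n = 50$, a 500-replicate interval-width comparison at $n = 25$,
300-replicate paired-test runs at each of $n = 10, 15, 25, 50$, and a
200-dataset null-variance experiment at $n = 8000$ — the latter because
the sampling SD of $\hat\tau^2$ under a true zero is
$\approx \sigma^2\sqrt{8/n}$, so demonstrating that the estimate
concentrates below 0.005 needs several thousand observations; at the
study's own $n = 25$ roughly half the null estimates land on the
boundary exactly and the rest scatter at the $0.04$ scale. Oracle
comparisons (grid search, GLS cross-checks) run at $n \le 40$ where
they are exact enough to be meaningful.

## Limitations

* Only distortion in $y$ is modelled; errors-in-$x$ and reduced major
  axis variants are out of scope.
* One distortion class: all flagged measurements share a single
  $\tau^2$. Graded severity scores would need a variance function with
  more levels.
* The LRT's plain $\chi^2_1$ reference is conservative near the
  boundary; use the mixture option when the test's power matters.
* Percentile bootstrap intervals can be optimistic at $n \lesssim 15$;
  they are reported as the field convention, not as exact coverage.
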