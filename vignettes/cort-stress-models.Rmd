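---
title: "Gamma-likelihood models of the corticosterone stress response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamma-likelihood models of the corticosterone stress response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cortmodels)
```

## The scientific problem

Glucocorticoid concentrations are the standard physiological read-out of
the acute stress response in vertebrates: within a few minutes of a
stressor the hypothalamic–pituitary–adrenal (HPA) axis drives circulating
levels up from a low baseline, and they stay elevated while the stressor
persists. In birds the relevant hormone is corticosterone (CORT), measured
in plasma in ng/ml. Wildlife managers comparing control methods — lethal
shooting versus live trapping followed by confinement — can use CORT to ask
which method imposes the shorter and smaller physiological strain: a bird
killed before its HPA axis responds should show baseline-like CORT, while a
bird held in a bag for up to three and a half hours should show a sustained
elevation that grows with time since capture.

The package analyses a three-group design: *shot* birds (sampled at death,
time written as 0), *baseline* birds (live-trapped, bled in under 3 minutes
— before handling can raise CORT), and *trapped* birds (live-trapped, held
10–210 minutes before sampling). Each bird is sampled once, so the time
course is built across birds, not within them.

## Models

### Gamma errors throughout

CORT is strictly positive and right-skewed, and its spread grows with its
mean, so every model uses a gamma error distribution parameterized by shape
$k$ and mean $\mu$ (scale $\mu/k$). Under this parameterization the
coefficient of variation is $1/\sqrt{k}$ at any mean, which matches the
roughly constant-CV behaviour of hormone assays, and the mean function of
any model plugs in directly.

All fits maximize the *exact* gamma log-likelihood, including the shape.
For the treatment GLM the mean coefficients come from IRLS
(`stats::glm`, `Gamma` family) — for a gamma GLM these are the exact ML
estimates of the mean structure and are orthogonal to the shape — after
which the shape is maximized by a one-dimensional profile optimization.
This matters because the likelihood-ratio test and AICc both consume
log-likelihoods: a moment-based dispersion would make them incoherent.

### Treatment comparison

`fit_gamma_glm()` fits CORT on treatment; `likelihood_ratio_test()` refers
$2(\ell_{\text{full}} - \ell_{\text{null}})$ to $\chi^2$ with df equal to
the difference in mean-parameter counts (2 for three groups).
`pairwise_contrasts()` forms all three unordered group differences on the
link scale with Wald standard errors from the ML covariance and applies the
Bonferroni correction $\min(1, 3p)$.

Two choices here were genuinely open:

* **Link.** The package defaults to the log link: concentrations are
  positive and treatment effects on hormones are naturally multiplicative.
  The canonical inverse link is also available (`link = "inverse"`), and
  the link used is recorded in the fit.
* **Contrast reference distribution.** Wald $z$ (normal) statistics are
  used rather than $t$-type statistics with an estimated denominator df.
  This is the simplest defensible contract, but it is mildly liberal at
  small group sizes (6–7 birds); the type-I simulations below quantify the
  effect at the whole-model level.

### Time-course models

Three mean models of CORT versus time since capture $t$, all with gamma
errors and jointly estimated shape:

* null: $\mu(t) = \mu$ (k = 2 parameters: mean + shape);
* logistic: $\mu(t) = a / (1 + e^{-b (t - x_0)})$ (k = 4) — asymptote $a$
  (ng/ml), rate $b$ (min$^{-1}$), inflection time $x_0$ (min), at which
  $\mu = a/2$; biologically, a surge that stabilizes while the stressor
  persists;
* quadratic: $\mu(t) = a + b t + c t^2$ (k = 4) — a transient response
  with a peak and decline when $c < 0$.

The shape counts once in $k$, so the comparison bookkeeping for an $n=63$
dataset is residual df 62/60/60 and $k$ = 2/4/4. Shot birds enter these
fits at $t = 0$: the time-course stage does not differentiate treatments,
and death at stressor onset pins the shot group to the curve's intercept
region. This convention is a package decision — an intercept-only model
with residual df 62 requires all 63 birds, and time 0 is the only value
consistent with "no time under stress".

### Selection, weights, pseudo-R²

`aicc()` implements $-2\ell + 2k + 2k(k+1)/(n-k-1)$; `akaike_weights()`
normalizes $e^{-\Delta/2}$ over the candidate set. Weights are always
computed from *unrounded* AICc — weights recomputed from a
display-rounded ΔAICc of 2.8 give 0.8022/0.1978, and tables printed
elsewhere may differ in the third decimal purely through rounding.
`select_best()` applies the parsimony rule: among models within 2 AICc of
the best, the smallest $k$ wins, ties broken by name order ("simplest"
needs a tie-break, and parameter count then lexicographic order is the
least surprising one).

Pseudo-R² is deviance-based by decision:
$1 - D(\text{fit})/D(\text{null})$ with the shape-free gamma deviance
$D = 2\sum_i[-\log(y_i/\mu_i) + (y_i-\mu_i)/\mu_i]$. Since the label
"pseudo-R²" is not unique, the likelihood-ratio variant
$1 - \exp\{(2/n)(\ell_0 - \ell_1)\}$ is computed alongside
(`pseudo_r2_lr()`, and a column in `compare_time_models()`) so both
readings are available.

### The sex-varying family

`build_sex_model_family()` enumerates the logistic null plus the seven
models in which each non-empty subset of $\{a, b, x_0\}$ is duplicated by
sex; the gamma shape is always shared (per-sex shapes would change the
$k$ bookkeeping: the family's $k$ values are 4, 5, 5, 5, 6, 6, 6, 7).
`fit_sex_family()` warm-starts every member from the pooled logistic fit,
which both speeds the fits up and guarantees the fitted family respects
the nesting of the null member (each member's log-likelihood can only
improve on its starting value). A sex with fewer than 4 birds makes its
per-sex parameters practically inestimable and is rejected.

## Numerical choices

* **Transforms.** Positivity-constrained parameters ($a$, the constant
  mean, the shape) are optimized as logs; $b$ and $x_0$ are unconstrained.
  The quadratic keeps its natural coefficients — its positivity constraint
  is on the *fitted means*, enforced by an infinite objective outside the
  feasible region, which preserves the model's unconstrained form.
* **Starts.** Logistic: all combinations of $a_0 \in \{\max y, 1.5\max y\}$,
  $x_{0,0} \in \{\operatorname{median} t, \bar t\}$,
  $b_0 \in \{4/\operatorname{range}(t), 0.1\}$, with a moment-style shape
  start from $\operatorname{var}(y/\mu_0)$. Quadratic: the least-squares
  parabola (shifted upward if it dips non-positive) plus a flat start.
  These are scale-free in the data.
* **Optimizer.** A Nelder–Mead stage (relative tolerance $10^{-8}$) from
  every start, then a BFGS polish (relative tolerance $10^{-9}$) of the two
  best simplex results; the best final value over all starts wins, with
  ties going to the earlier start. Sigmoid likelihoods have plateaus (for
  data with no late-time information, $a$ and $b$ trade off), and the
  simplex stage is what makes the fit robust there.
* **Uncertainty.** The covariance is the inverse numerical Hessian
  (observed information) at the optimum, on the transformed scale.
  Prediction bands (`predict_with_ci()`) use the delta method — numerical
  gradient of the mean in the transformed parameters — with normal
  quantiles, floored at 0; a singular information matrix yields `NA` bands
  with the mean still returned. A parametric bootstrap
  (`method = "bootstrap"`: refit on datasets simulated from the fitted
  model) is available as a cross-check; the test suite compares the two at
  250 refits with a 30% width tolerance chosen for the Monte-Carlo noise
  at that size.
* **Overflow.** The logistic mean is evaluated through `plogis`, exact and
  finite at $|b(t - x_0)| = 800$ and beyond.
* **Degenerate inputs.** Empty data, non-positive CORT, all-identical
  times for a time-course model, and $n \le k+1$ are rejected with
  explicit errors rather than producing garbage fits.

## The synthetic-data generator

`sim_config()` / `simulate_cort_data()` generate datasets with exactly the
statistical structure the analysis assumes: gamma CORT whose mean follows
the logistic time course, times uniform within each group's window, shot
birds at a fixed low mean, and sexes assigned by permutation so counts are
exact for every seed. Replicates (`simulate_replicates()`) use
deterministic counter-derived child seeds, so Monte-Carlo studies are
reproducible from one master seed.

The default configuration is the emulated study design, fixed once:

* groups 7 shot / 6 baseline / 50 trapped (63 birds); baseline times on
  (1, 3) min, trapped on (10, 210) min;
* 30 females. The study the design emulates reported 30 females and 34
  males against a total of 63 — an arithmetic inconsistency in the
  published tally (30 + 34 = 64). The generator keeps the total and the
  female count and assigns 33 males, the only reconciliation that
  preserves both the group sizes and the female count;
* logistic curve $a = 45$ ng/ml, $b = 0.12$ min$^{-1}$, $x_0 = 25$ min —
  calibrated so the curve passes ~5 ng/ml at 5 min, ~20 ng/ml at 25 min
  and ~45 ng/ml from 50 min on, the qualitative trajectory the emulated
  study describes; its exact fitted coefficients were never published;
* baseline birds take their mean from the curve at their sampling time
  (≈ 4–5 ng/ml near the intercept); a fixed-mean mode
  (`baseline_from_curve = FALSE`) is available;
* shot mean 2.38 ng/ml; shapes from reading the published mean ± spread
  values as mean ± SD: trapped CV 17.20/41.00 ≈ 0.42 → shape ≈ 5.68, shot
  CV 0.58/2.38 → shape ≈ 16.8. Whether those published spreads are SD or
  SE is unstated; the SD reading gives the more dispersed (conservative)
  data, and `summarize_groups()` reports both SD and SE so either reading
  can be compared;
* no sex effect by default (the emulated study found none); per-sex curves
  (`curve_female`, `curve_male`) switch on an effect for power studies.

What the generator does **not** emulate: assay measurement error as a
separate layer (it is absorbed into the gamma CV), any decline of CORT
after stressor removal, within-bird correlation (each bird is sampled
once, so there is none to model), capture-order or site effects, and any
dependence of dispersion on time. Tests passing on generated data
therefore demonstrate correctness of the estimators and selection
machinery under the assumed model, not robustness to field-data
pathologies such as assay censoring or outlier birds.

## What the simulations show

The test suite and `scripts/acceptance.R` compute, among others:

* near-noiseless recovery (shape $10^4$, $n = 200$): logistic parameters
  within 1% of truth;
* stochastic recovery at the study's realistic noise (200 replicates,
  $n = 200$, $a = 45$, $b = 0.15$, $x_0 = 20$, shape 6, times uniform
  0–210): median relative bias of each parameter within ±10%, and AICc
  picks the logistic over null and quadratic in ≥ 90% of replicates;
* type-I error of the LRT at the 7/6/50 design (500 equal-mean gamma
  replicates, shape 5): rejection rate at $\alpha = 0.05$ within
  [0.03, 0.08] — the asymptotic $\chi^2$ reference is adequate but not
  exact at these group sizes;
* sex-family specificity: with no simulated sex effect the shared-
  parameter null stays within 2 AICc of the best member in ≥ 80% of 100
  study replicates; a strong effect ($a$ differing 30 vs 60 ng/ml,
  $n = 200$) puts an $a$-varying model first.

These problem sizes (200 recovery replicates at $n = 200$; 500 LRT
replicates; 100 sex-family replicates) are the package's chosen Monte-Carlo
scale: large enough that the binomial noise on each rate is a small
fraction of the band being checked, small enough to run routinely.

## Limitations

* The time-course stage pools all 63 birds with shot birds at $t = 0$; if
  shot birds' CORT were systematically below the curve intercept, the
  intercept region would be biased low. With 7 birds at one time point the
  effect is small, but it is a modelling convention, not biology.
* Wald contrasts and delta-method bands are asymptotic; at $n = 6$–7 per
  small group, adjusted p-values near a threshold deserve a bootstrap
  cross-check (provided for bands; not for contrasts).
* AICc's small-sample correction assumes the usual regularity; the
  logistic's plateau directions can make the effective dimension smaller
  than $k$ when the data carry no late-time information.
* Pseudo-R² for gamma models is convention-dependent; both conventions are
  reported, and values from other software may match either.
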