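# cortmodels

Stress-physiology analysis of plasma corticosterone (CORT) in wild birds
subjected to different capture and control methods, built for wildlife-
management studies that compare a lethal shooting group, a baseline group
(bled within 3 minutes of net activation) and a live-trapping–confinement
group sampled 10–210 minutes after capture.

CORT is a strictly positive, right-skewed concentration, so every model in
the package uses a gamma error distribution parameterized by shape *k* and
mean *μ* (scale = *μ*/*k*). The package implements:

- **Treatment comparison** — a gamma GLM of CORT on treatment group, a
  likelihood-ratio test against the intercept-only null
  (2·(ℓ₁ − ℓ₀) ~ χ² with df equal to the difference in mean parameters),
  and Wald pairwise contrasts on the link scale with Bonferroni adjustment
  (p·m capped at 1). The gamma shape is maximized jointly with the mean, so
  log-likelihoods are exact, not moment approximations.
- **Time-course models** — maximum-likelihood fits of three gamma mean
  models of CORT versus time since capture *t*: a constant null, the
  logistic growth curve

  μ(t) = a / (1 + exp(−b·(t − x₀)))

  with asymptote *a*, rate *b* and inflection time *x₀*, and the quadratic
  μ(t) = a + b·t + c·t², with delta-method (or parametric-bootstrap) 95%
  confidence bands for predictions.
- **Model selection** — AICc (−2ℓ + 2k + 2k(k+1)/(n−k−1)), ΔAICc, Akaike
  weights, deviance pseudo-R², and the parsimony rule: among models within
  2 AICc units of the best, keep the simplest.
- **Sex-varying model family** — the logistic null plus the seven models in
  which each non-empty subset of {a, b, x₀} is duplicated by sex (shared
  gamma shape), compared by AICc.
- **Synthetic data** — a seeded generator reproducing the study's sampling
  design (63 birds: 7 shot / 6 baseline / 50 trapped, 30 females, baseline
  bleeds < 3 min, confinement times on 10–210 min, gamma CORT on a logistic
  time course), so the whole pipeline is testable without raw field data.

## Worked example

```r
library(cortmodels)

ds <- simulate_cort_data()      # default 63-bird study design
summarize_groups(ds)
#>   treatment     n mean_cort sd_cort se_cort
#> 1 shot          7      2.00   0.665   0.251
#> 2 baseline      6      2.34   0.973   0.397
#> 3 trapped      50     43.9   20.9     2.96
```

Trapped–confined birds sit around 44 ng/ml while shot and baseline birds
are both near 2 ng/ml. The treatment effect and its pairwise structure:

```r
full <- fit_gamma_glm(ds)
likelihood_ratio_test(full, fit_gamma_glm(ds, "intercept_only"))
#>   statistic    df  p_value
#> 1      96.4     2 1.18e-21
pairwise_contrasts(full)
#>   contrast           estimate std_error statistic    p_raw    p_adj
#> 1 shot - baseline      -0.160     0.278    -0.576 5.65e- 1 1   e+ 0
#> 2 shot - trapped       -3.09      0.202   -15.3   6.73e-53 2.02e-52
#> 3 baseline - trapped   -2.93      0.216   -13.6   7.14e-42 2.14e-41
```

Both trapped contrasts reject overwhelmingly; shot versus baseline does
not — the pattern expected when shooting kills before the
hypothalamic–pituitary–adrenal axis can mount a response. The time-course
comparison:

```r
cmp <- compare_time_models(ds)
cmp
#>   name      resid_df  aicc delta_aicc     k   weight pseudo_r2
#> 1 logistic        60  446.        0       4 9.98e- 1     0.871
#> 2 quadratic       60  458.       12.4     4 2.07e- 3     0.844
#> 3 null            62  579.      133.      2 1.04e-29    NA
select_best(cmp)
#> [1] "logistic"

fit <- attr(cmp, "fits")$logistic
predict_with_ci(fit, c(5, 25, 50, 120))
#>    time  mean  lo95  hi95
#> 1     5  3.36  2.79  3.93
#> 2    25 19.5  14.4  24.6
#> 3    50 45.7  40.2  51.1
#> 4   120 50.4  44.6  56.3
```

The logistic model carries essentially all the Akaike weight: CORT rises
from a few ng/ml shortly after capture through ~20 ng/ml near the
inflection and stabilizes at the asymptote while confinement persists.
`autoplot(fit)` draws the curve with its confidence ribbon over the data,
and `fit_sex_family(ds)` fits and ranks the eight sex-varying logistic
models (with no simulated sex effect, the shared-parameter null wins).

The full pipeline, with a machine-readable report:

```r
report <- run_cort_analysis(default_study_config())
render_report(report, "markdown")
```

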