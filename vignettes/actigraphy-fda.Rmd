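---
title: "Functional data analysis of 24-hour actigraphy: models and design choices"
author: "actfda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional data analysis of 24-hour actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actfda)
```

## The problem

Wrist actigraphy records movement continuously as activity counts per short
epoch. Summaries such as daily totals, or cosinor fits that force the daily
rhythm into a cosine shape, discard most of the information in the diurnal
profile — which is exactly where circadian disturbance shows up in
psychiatric and ageing populations. This package treats each recorded day as
a *function* of clock time and analyses the collection of day-curves with
functional data analysis: functional principal component analysis (fPCA)
describes the dominant modes of day-to-day variation, generalized estimating
equations (GEE) relate per-day component scores to determinants while
respecting that days are nested in subjects, and function-on-scalar
regression (FoSR) estimates *when* during the day a determinant acts.

## From epochs to valid day curves

A day is the 24-hour local-clock interval, represented by 1440 minute
values; minute values are sums of twelve 5-second epochs, and a minute is
unobserved if any constituent epoch is missing. Three rules govern
preprocessing:

* **Validity.** A day is valid when at least 960 minutes (16 hours) were
  observed. The boundary is inclusive. We implement the wear-time rule as a
  single per-day criterion; a separate night-window threshold would need a
  definition of "night" that the rule itself does not supply.
* **Inclusion.** A subject enters analysis with at least one valid weekday
  and one valid weekend day (Saturday/Sunday by calendar date). Excluded
  subjects are logged with the failing rule.
* **Imputation.** An unobserved minute on a valid day is replaced by the
  subject's activity at the same minute averaged over their other valid
  days — a person-specific diurnal prior. If a minute is unobserved on
  *every* valid day, we fall back to linear interpolation across the daily
  grid of the subject's mean profile (circularly, so gaps spanning midnight
  interpolate between 23:xx and 00:xx) and log a warning. Observed values
  are never modified, and the operation is idempotent.

Season is assigned from the calendar date with fixed astronomical
boundaries (21 December – 20 March winter, then spring, summer, autumn in
three-month blocks starting on the 21st). Days shifted by daylight-saving
transitions are truncated or NA-padded to 1440 minutes and then face the
validity rule like any other day.

## Fourier pre-smoothing and fPCA

Each complete day curve is projected onto nine Fourier basis functions on
the 1440-minute grid: the constant and sine/cosine pairs at harmonics
\(k = 1, \dots, 4\) of the 24-hour period,

$$\phi_0(t) = 1/\sqrt{T}, \qquad
  \sqrt{2/T}\sin(2\pi k t / T), \quad \sqrt{2/T}\cos(2\pi k t / T),$$

with \(T = 1440\). Nine functions capture the major diurnal trends while
discarding minute-level noise. The basis is exactly orthonormal under the
discrete inner product on minute midpoints, which buys an important
simplification: PCA of the 9-dimensional coefficient vectors *is* fPCA of
the discretized curves — same eigenvalues, same eigenfunctions. We compute
in coefficient space (a 9×9 eigenproblem) and keep brute-force PCA of the
1440-point curves as an independent oracle in the test suite; on noiseless
fixtures the two agree to eigenvalue relative error below 1e-8 and
principal angles below 1e-6 degrees.

Conventions that matter downstream:

* **Sign orientation.** An eigenfunction is only defined up to sign; we
  flip each one so that its largest-magnitude Fourier coefficient is
  positive, making "+/-" pattern labels reproducible.
* **Retention.** The smallest K whose variance proportions sum to at least
  0.75 is retained. Applied to the reference per-component shares
  34.3/16.5/14.8/11.8 percent this retains four components at 77.4 percent.
* **Variance proportions** are taken over all nine eigenvalues of the
  centered coefficient covariance. Centering removes the mean curve, not
  the constant *direction*: day-level curves still vary in overall level,
  and that variation (loading mostly on \(\phi_0\)) is typically the first
  component.
* **Standardization.** Component scores are pooled-standardized (SD over
  all subject-days equals \(\sqrt{\lambda_k}\)), and continuous covariates
  are z-scored before regression, so association coefficients read as
  "score SDs per covariate SD". Whether to standardize is a genuine choice;
  the per-SD convention makes coefficients comparable across components and
  determinants and matches the magnitude range of published tables.
* fPCA is fitted on the pooled set of all valid subject-days — one
  analysis at the day level, not per-subject — because the scientific unit
  of variation here is the day.

## GEE association models

Each retained component's standardized day-level score is regressed on
determinants with Gaussian identity-link GEE, one cluster per subject.
The working correlation is exchangeable: repeated days of one person share
a common correlation \(\alpha\), which matches the generative structure of
a subject-level random effect. Independence is available as an option. The
moment estimator for \(\alpha\) uses cross-day residual products; the
closed-form inverse of the exchangeable working covariance keeps each
iteration at a handful of cluster-aggregated matrix products. Inference
uses the robust sandwich covariance, so standard errors remain valid when
the working correlation is wrong.

The covariate structure mirrors the standard epidemiological layout: a
base block (age, sex, education, partner status, BMI, chronic diseases,
cigarettes/day, drinks/day, work/school day, season with winter reference)
always adjusted for, plus exactly one clinical covariate per model
(diagnostic group, symptom score, or antidepressant use; benzodiazepine use
is accepted as an optional extra). Clinical covariates never co-occur
because they are strongly intercorrelated. Missing covariates are handled
complete-case per model with the dropped count recorded.

Multiple testing is controlled by Benjamini–Hochberg FDR. The family is
all non-reference covariate tests within one (component × model) fit; the
family definition is a choice, it is recorded in the output so users can
re-pool p-values across another family if they prefer. q-values come from
`stats::p.adjust(method = "BH")`; the test suite checks them against a
direct implementation of the step-up definition.

Calibration of this estimator is simulation-tested at the study's design
scale: recovery of a true workday effect within three robust SEs in ≥95%
of 200 replicates at 200 subjects × 14 days; type-I error of a pure-noise
covariate within [0.03, 0.07] over 1000 replicates at 150 clusters of 5;
and 95% CI coverage within [0.92, 0.97] over 500 replicates at 150
clusters of 7. Cluster counts below ~50 are known territory for sandwich
anti-conservatism; no small-sample correction is applied, so interpret
robust SEs cautiously in small cohorts.

## Function-on-scalar regression

For time-localized effects, minute curves are aggregated into 144
ten-minute bins and averaged over each subject's valid days, giving one
diurnal profile per subject. Because curves are day-averaged, day-varying
covariates must be collapsed: the workday flag becomes the proportion of
valid days that are workdays, and season becomes the modal season (ties
broken in fixed level order). These conventions are recorded in the output.

The model is \(Y_i(t) = \sum_j x_{ij}\beta_j(t) + E_i(t)\) with each
\(\beta_j\) expanded in ten cubic B-splines over the day. The stacked
least-squares problem factorizes as
\(\hat B = (X'X)^{-1} X' Y \Theta(\Theta'\Theta)^{-1}\), so the fit is
exact and fast; with the basis saturated at the grid size it reduces to
independent pointwise OLS, which the tests use as an oracle. Estimation is
unpenalized by default — ten B-splines already smooth heavily at this grid
— with an optional second-difference penalty whose weight is chosen by
generalized cross-validation.

Pointwise bands use a subject-level sandwich covariance of the basis
coefficients. The global per-covariate test is a Wald statistic on the
covariate's full basis-coefficient block referred to a Hotelling-\(T^2\)
F distribution, \(F = T^2(n-p-q+1)/((n-p)q) \sim F_{q, n-p-q+1}\), which
is exact under Gaussian errors with arbitrary residual covariance across
the grid — this is what keeps the global test calibrated at moderate n
where a naive \(\chi^2_q\) reference with an estimated covariance is
anticonservative. A subject-resampling bootstrap is provided as a robust
alternative. Simulation checks: global type-I error within [0.03, 0.07]
over 500 replicates at n = 150; integrated squared error of a sinusoidal
effect of amplitude a below \(0.05\,a^2\,24\) with ≥90% pointwise band
coverage.

## The synthetic cohort generator

No public dataset carries this design (minute-level wrist actigraphy, two
weeks per subject, psychiatric covariates), so the package ships a
generator whose defaults *are* the study conditions the pipeline targets:

* 359 subjects × 14 consecutive days, 1440 minutes/day;
* nine orthonormal modes of daily variation in Fourier-coefficient space.
  The four leading modes are interpretable (overall daytime level,
  early-vs-late morning timing, biphasic-vs-monophasic shape with a midday
  trough, early-vs-late biphasic timing) and carry variance shares
  34.3/16.5/14.8/11.8 percent; five minor modes share the remaining 22.6
  percent, standing in for the residual smooth shape variability real
  curves exhibit. The 75-percent rule therefore retains four components at
  77.4 percent by construction;
* score decomposition \(\xi_{ijk} = \Gamma_k'z_{ij} + b_{ik} + e_{ijk}\):
  each eigenvalue is the *total* score variance; the covariate-explained
  part (under nominal design variances) is subtracted and the remainder
  split equally between the subject and day levels, giving a within-person
  day-to-day score correlation of 0.5. That ICC is a free design choice —
  the motivating analyses do not report one — and 0.5 is a realistic
  middle ground for behavioural day-level traits;
* default covariate effects are per-SD magnitudes typical of a
  multivariable actigraphy association table (largest: workday on the
  biphasic component, 0.73 SD); all clinical covariates act simultaneously
  in generation even though the analysis models them separately, mirroring
  their real-world correlation;
* covariate marginals match an adult psychiatric cohort (age 50 ± 12, 63%
  female, BMI 26.5 ± 5, diagnostic groups 25/49/26%, group-dependent
  symptom scores and antidepressant use); workday flags are Bernoulli(0.4)
  and season follows each subject's simulated 14-day calendar window;
* minute-level white noise (SD 25) on top of the smooth curve, floored at
  zero. Flooring (rather than log-normal generation) keeps the linear
  score model exact away from the floor and matches count-like actigraphy;
  with the default night-time mean level ~60 about 2–3% of minutes
  truncate, which mildly attenuates recovered effects — the price of
  realistic near-zero night activity;
* non-wear gaps: Poisson(2) gaps per day with geometric mean length 30
  minutes. This emulates everyday device removal; it rarely invalidates a
  whole day, so attrition stays milder than in field cohorts where
  multi-hour removals occur.

Everything is reproducible from a single integer seed, and the realized
scores are stored so recovery can be checked against truth.

**What passing tests do and do not show.** The generator produces smooth
Fourier-band-limited curves plus white noise. Real actigraphy has
heavier-tailed, autocorrelated minute noise, activity bouts, and non-wear
that correlates with behaviour; none of that is emulated, so the test
suite validates the *estimators* under the stated model, not robustness to
real-device artefacts. Cross-component score correlation induced by shared
covariate effects (e.g. workday acting on several components at once) is
emulated, and its consequence is visible in the synthetic end-to-end run:
with neighbouring eigenvalues only ~11 percent apart, fitted components
2 and 3 are partially rotated mixtures of the generating modes — exactly
what would happen in real data, and the reason component *labels* should
be read from their effect curves, not assumed.

## Numerical choices and problem sizes

* Basis projections solve the normal equations; with the orthonormal
  Fourier basis this is an inner product, but the code path stays a
  general least-squares solve.
* Eigenvalues are clamped at zero; a component with zero variance yields
  zero-width effect curves and zero standardized scores.
* The exchangeable \(\alpha\) is clamped inside
  \((-1/(\max_i n_i - 1), 1)\); with all clusters of size one it is fixed
  at 0 and the fit equals OLS exactly.
* GEE iterations stop when the coefficient change falls below 1e-10
  relative; convergence is typically 3–5 iterations.
* Simulation-based checks in the test suite use 20 seeds at 100 × 14 for
  eigenstructure recovery (day-level score variance only, so the precision
  bound is governed by the curve count; within-person correlation would
  shrink the effective sample and is exercised in the GEE checks instead),
  200–1000 replicates for GEE calibration at 150–200 clusters, and 50–500
  replicates for FoSR recovery and calibration at n = 150. These sizes
  were chosen to make Monte-Carlo error small relative to each asserted
  tolerance while keeping the default test run fast.

## Known limitations

* No smoothed/penalized fPCA and no basis sizes other than the
  configurable Fourier dimension; with 9 coefficients, penalization has
  little to add.
* Sandwich SEs without small-sample correction; be careful below ~50
  clusters.
* The FoSR analytic global test assumes Gaussian errors; use the bootstrap
  for heavy-tailed outcomes.
* Family structure between participants (siblings) is ignored: every
  subject is an independent cluster.
* Timezone handling is limited to truncating/padding daylight-saving days;
  no timezone inference from timestamps.

## A minimal run

```{r example, eval = FALSE}
cfg <- simulation_config(n_subjects = 60, seed = 1)
ds <- simulate_actigraphy(cfg)
res <- run_pipeline(pipeline_config(out_dir = tempfile(), seed = 1),
                    dataset = ds)
res$fpca
head(res$assoc$table)
```
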