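# actfda — functional data analysis of 24-hour actigraphy

`actfda` analyses wrist-actigraphy rest–activity data as functional data.
It is aimed at epidemiologists and clinical researchers who have
epoch- or minute-level activity counts for a cohort (typically ~1–2 weeks
per person) and want to relate *patterns* of daily activity — not just
totals — to sociodemographic, lifestyle, sampling and clinical
determinants.

The pipeline:

1. **Preprocessing.** Days are 24-hour clock intervals of 1440 minutes
   (minutes = sums of twelve 5-second epochs). A day is *valid* with ≥960
   observed minutes (16 h); a subject is *included* with ≥1 valid weekday
   and ≥1 valid weekend day; unobserved minutes on valid days are imputed
   from the subject's same minute averaged over their other valid days.
2. **fPCA.** Each day curve is pre-smoothed in a 9-function Fourier basis
   (constant + 4 sine/cosine harmonics of the 24-h period) and the pooled
   day-level coefficient vectors are decomposed into functional principal
   components. With the orthonormal basis, the 9×9 coefficient-space
   eigenproblem is exactly fPCA of the discretized curves. Components are
   retained up to ≥75% cumulative variance, and each day gets a
   standardized score per component:
   ξ<sub>dk</sub> = ⟨x<sub>d</sub> − μ, φ<sub>k</sub>⟩ / √λ<sub>k</sub>.
3. **GEE.** Standardized scores are regressed on determinants with
   Gaussian identity-link generalized estimating equations, one cluster
   per subject, exchangeable working correlation, robust (sandwich)
   variance, and Benjamini–Hochberg FDR q-values within each
   (component × model) family. Separate models per clinical covariate
   avoid psychiatric-covariate collinearity.
4. **FoSR.** Per-subject diurnal profiles (10-minute bins averaged over
   valid days) are regressed on determinants with function-on-scalar
   regression: β<sub>j</sub>(t) in a 10-function B-spline basis, pointwise
   sandwich bands, and a Hotelling-F global test per covariate block.

A synthetic actigraphy generator (`simulation_config()` /
`simulate_actigraphy()`) with known mean curve, eigenfunctions, covariate
effects, within-person day correlation and non-wear gaps makes the entire
pipeline testable without access to cohort data.

## Worked example

```r
library(actfda)

cfg <- simulation_config(n_subjects = 60, seed = 1)   # synthetic cohort
ds  <- simulate_actigraphy(cfg)
res <- run_pipeline(pipeline_config(out_dir = tempfile(), seed = 1),
                    dataset = ds)

res$fpca
#> Functional PCA of 840 day-curves (9-function Fourier basis)
#>   retained 4 components, cumulative variance 77.7%
#>   component 1: eigenvalue 2.095e+06 (36.3% of variance)
#>   component 2: eigenvalue 9.259e+05 (16.0% of variance)
#>   component 3: eigenvalue 8.007e+05 (13.9% of variance)
#>   component 4: eigenvalue 6.675e+05 (11.6% of variance)
```

Four components carry 77.7% of day-to-day curve variability in this
synthetic cohort (the generator's design shares are 34.3/16.5/14.8/11.8%).
Component 1 is the overall daily activity level; its association table
rows read as "score SDs per covariate SD":

```r
tab <- res$assoc$table
head(subset(tab, model == "none" & component == 1 & !ref,
            c(variable, level, beta, se, p, q)))
#>    variable level     beta     se       p      q
#>         age       -0.11709 0.0895 0.19101 0.3820
#>         bmi       -0.29239 0.1065 0.00606 0.0363
#>     chronic        0.00771 0.0890 0.93093 0.9309
#>  cigarettes       -0.12015 0.0917 0.18987 0.3820
#>      drinks        0.11156 0.0818 0.17255 0.3820
```

Here higher BMI is associated with lower overall activity (−0.29 SD per
BMI SD, q = 0.036); at n = 60 subjects most other effects are not yet
separable from noise. `plot_component(res$fpca, 1)` draws the mean curve
±1 score SD, and `plot_fosr(res$fosr$none)` shows each determinant's
time-varying coefficient β(t) with 95% pointwise bands.

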