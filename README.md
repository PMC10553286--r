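# eatrhythm

Infant sleep—wake patterns, meal timing, and the gut microbiota all undergo
rapid maturation across the first year of life, and regular eating may act
as a zeitgeber that supports maturing sleep. `eatrhythm` implements the
analysis pipeline for testing that idea on longitudinal infant cohorts: it
quantifies day-to-day meal-timing regularity with the **Eating Regularity
Index (ERI)**, relates the index to actigraphy-derived sleep composites
with multilevel models, and asks whether gut-microbiota maturation markers
mediate the association. It is written for researchers in pediatric sleep,
chronobiology, and microbiome epidemiology.

## The index

For each subject and assessment, every diary day becomes a binary vector
over 15-min epochs of the 24-h day (96 entries; 1 where a meal starts). A
uniform simple moving average of width *k* = 4 epochs is applied twice with
wrap-around at midnight, turning each meal into a triangular bump so that
epochs near a meal get weight decreasing with distance. The similarity of
two days is the cosine of their smoothed profiles,

  s(a, b) = ⟨a, b⟩ / (‖a‖·‖b‖) ∈ [0, 1],

and the ERI is the mean over all C(n, 2) day pairs: 0 = highly irregular,
1 = highly regular meal timing. Subjects with fewer than 5 valid diary days
are excluded rather than scored.

Around the index, the package provides:

- **Synthetic cohorts** (`simulate_cohort()`): diaries driven by a latent
  regularity parameter calibrated to the ERI scale, sleep composites with
  configurable true slopes and subject random intercepts, and
  Dirichlet-multinomial stool microbiota with two enterotypes, rising
  diversity with age, and switchable mediation ground truth.
- **Microbiota markers** (`compute_markers()`): observed species, Shannon,
  bias-corrected Chao1; normalized weighted UniFrac; 2-cluster k-medoids
  enterotyping with Calinski–Harabasz and prediction-strength scores; and
  a random-forest bacterial maturation index (out-of-bag predicted age
  minus actual age).
- **Association models** (`fit_multilevel()`, `fit_age_glm()`,
  `age_trend_anova()`): five multilevel composite models with AIC/BIC
  random-structure selection and Satterthwaite df, per-age linear models,
  and the one-way ANOVA + Tukey age trend of the ERI.
- **Mediation** (`baron_kenny()`, `mediation_screen()`): the Baron & Kenny
  causal-steps procedure over every marker × composite pair.
- **Orchestration** (`run_pipeline()`): simulate or read data, run every
  stage, and write per-stage CSVs plus a deterministic markdown report.

## Worked example

```r
library(eatrhythm)

cfg <- cohort_config(n_subjects = 80, seed = 42)
coh <- simulate_cohort(cfg)

eri <- compute_eri_cohort(coh$diary, k = 4, min_days = 5)
dat <- merge(eri[!eri$excluded, ], coh$sleep)

head(eri[, c("subject_id", "age_months", "eri", "n_days_used")], 3)
#>   subject_id age_months       eri n_days_used
#> 1       S001          3 0.6040592          11
#> 2       S001          6 0.3847224          11
#> 3       S001         12 0.5473971          11

fit_multilevel(dat, "SleepVariability")
#> SleepVariability ~ eri + sex + exact_age + breastfeeding + mean_meals_per_day + daytime_meal_ratio + structure_score  [random: intercept; n = 240 obs, 80 subjects]
#>   (Intercept)          t(209.752) = -1.553, b = -1.383, p = 0.122
#>   eri                  t(152.605) = -4.788, b = -2.243, p = <0.001
#>   sex                  t(75.554) = 0.021, b = 0.004, p = 0.983
#>   ...
```

The `eri` row is the association of interest: the configured ground truth
of this synthetic cohort couples Sleep Variability to realized regularity
with slope −2, and the multilevel model recovers an estimate of −2.24 with
t(152.6) = −4.79 — more regular eaters have less variable sleep, with the
meal-count and parental-structure covariates controlled. `run_pipeline()`
executes the same stages end to end and writes `eri.csv`, `markers.csv`,
`model_coefficients.csv`, `mediation.csv` and a combined `report.md` into
an output directory.

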