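---
title: "Methods: the Eating Regularity Index, sleep associations, and microbiota mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Eating Regularity Index, sleep associations, and microbiota mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eatrhythm)
```

# Scope

`eatrhythm` quantifies how regular an infant's day-to-day meal timing is,
relates that regularity to actigraphy-derived sleep composites across the
first year of life, and asks whether gut-microbiota maturation markers
mediate the association. The package covers the full analysis path — diary
I/O, the index itself, microbiota markers, multilevel association models,
and causal-steps mediation — together with a synthetic cohort generator with
known ground truth, so that every stage can be exercised and validated
without access to cohort data.

Out of scope by design: deriving the five sleep composites from raw
actigraphy (they are inputs here), 16S rRNA sequence processing and taxonomy
assignment (the taxa count table is an input), and questionnaire item
scoring (the parental Structure score enters as a numeric covariate).

# The Eating Regularity Index

For each subject and assessment, every recorded day is converted into a
binary profile over 15-minute epochs of the 24-h day (96 entries): an entry
is 1 if at least one meal *starts* in that epoch. Meal ends are ignored, and
repeated starts within one epoch do not raise the entry above 1.

A uniform simple moving average (SMA) of width $k$ epochs is applied twice,
circularly. One pass turns a unit impulse into a plateau of width $k$ at
height $1/k$; the second pass produces a triangular bump spanning $2k - 1$
epochs, so epochs closer to the meal receive higher weight. Smoothing
conserves total mass. Two choices here were genuinely open:

* **Wrap-around at midnight.** Profiles are treated as circular, so a meal
  at 23:50 neighbours one at 00:10. The alternative (zero-padding) would
  make midnight meals systematically less similar across days for reasons
  that have nothing to do with regularity; infants demonstrably feed across
  midnight, so the circular convention is used throughout.
* **Even-width kernel alignment.** For even $k$ the window cannot be
  centred; the package fixes the window at epoch $t$ to
  $[t - \lfloor (k-1)/2 \rfloor,\; t + \lceil (k-1)/2 \rceil]$ (one epoch
  more forward than backward). Day profiles are processed identically, so
  the half-epoch phase shift cancels in every day-pair comparison.

The similarity of two days is the cosine of their smoothed profiles, a
value in $[0, 1]$ for non-negative vectors. The **ERI** of a
subject-assessment is the mean cosine over all $\binom{n}{2}$ day pairs:
1 for perfectly repeating meal schedules, 0 for days with no overlapping
(smoothed) meal support.

Zero-meal days are dropped before pairing — the cosine of a zero vector is
undefined — and logged. Subjects retaining fewer than `min_days = 5` days
are excluded rather than scored; the 5-day threshold is interpreted as "at
least five retained diary days", not necessarily consecutive calendar days
(diary dates are treated as labels; the index is order-invariant anyway).

The default kernel width $k = 4$ (one hour) is the width that maximizes
between-subject ERI variability, the property that makes the index
informative as an individual-differences measure; `select_sma_interval()`
reproduces this diagnostic on any cohort and picks the width winning the
most age groups (ties to the smaller width, which smooths less). Both SMA
passes use the same width.

Two meal covariates accompany the index, computed over retained days: the
mean number of meals per day, and the fraction of meals starting in the
daytime window 07:00–19:00. The window is half-open ([07:00, 19:00)) so no
meal can be counted twice at a boundary.

# The synthetic cohort generator

The generator emulates a longitudinal design of `n_subjects` infants
assessed at 3, 6 and 12 months with 11 diary days per assessment at 15-min
resolution.

**Diaries.** Each subject has a latent trait regularity $r \sim
\mathrm{Beta}(5, 2)$ — a right-shifted distribution placing most infants
at moderate-to-high regularity. Eating regularity matures over the first
year, so the regularity realized at each assessment is
$r_{age} = r + \delta_{age} + \eta$, with deterministic offsets
$\delta = (-0.033, 0, +0.033)$ at 3/6/12 months (matching the size of the
reported developmental increase in eating regularity) and
$\eta \sim N(0, 0.1)$ expressing individually varying developmental pace;
$r_{age}$ is clamped to (0, 1). Per assessment, a template schedule of
meal clock times is drawn (mean meal counts decreasing 8 → 6.5 → 5 across
the three ages, with meals weighted 70% toward daytime); each day perturbs
the template with Gaussian timing jitter of SD given by the jitter map at
$r_{age}$ and adds/drops meals independently (p = 0.05 each), then wraps
modulo 24 h and floors onto the epoch grid. The Gaussian jitter model is a
stand-in — no distributional form for diary timing noise is established —
chosen because a single SD knob maps monotonically onto the ERI.

**The calibrated jitter map.** The map from $r$ to jitter SD is the inverse
of a fixed calibration curve of mean realized ERI against jitter SD,
measured once under the default design and frozen into the package. This
puts the latent regularity parameter *on the ERI scale*:
$E[\mathrm{ERI} \mid r] \approx r$ over the achievable range (about
0.30–0.96; day-level meal add/drop keeps perfect similarity out of reach).
The point of this choice is interpretability of effect sizes: a configured
slope of a sleep composite on $r$ is then recoverable, up to attenuation,
as the coefficient on the *observed* ERI. With an uncalibrated map the ERI
is a nonlinear compression of $r$ and coefficients on it are biased by the
reciprocal of the compression slope — an artefact of parameterization, not
of the models.

**Attenuation.** The realized ERI measures $r_{age}$ with noise (finite
day pairs, add/drop events, template redraws): per-assessment noise SD is
about 0.06 against a between-subject SD of about 0.16. Regressing a
composite on the measured index therefore attenuates coefficients by a
factor of roughly 0.9 relative to the same model fitted on true realized
regularity — the classic errors-in-variables effect, with 11 diary days
per assessment setting the noise floor. The validation suite bounds this
explicitly: the multilevel model on true $r_{age}$ recovers the configured
slope within two standard errors at nominal coverage, while the ratio of
the ERI coefficient to the true-regularity coefficient stays within
0.75–1.05 and averages about 0.9. Consumers of effect sizes on the ERI
scale should expect this mild conservatism; it cannot be calibrated away
without distorting the index's own scale.

**Sleep and covariates.** Each composite follows
$y = b\,r + c\,\mathrm{age} + u_{\mathrm{subject}} + \varepsilon$ with
defaults $b = -2$ for Sleep Variability, $-1.5$ for Sleep Activity and
Sleep Timing, $0$ for Sleep Day and Sleep Night (mirroring the pattern of
associations the analysis is designed to detect), a mild maturation trend
$c = -0.05$/month, random intercepts with SD 0.5 and residual SD 1. With
these values the strongest association yields $t \approx 6$ at 300
subjects, matching the magnitude such composites show in cohorts of this
size. Sex is Bernoulli(0.5); breastfeeding is 1 for everyone at 3 months
(by design: essentially all infants in such cohorts are breastfed at that
age) and Bernoulli(0.7)/Bernoulli(0.4) at 6/12 months; the parental
Structure score is subject-level, correlated 0.3 with $r$ — parents who
value schedules have more regular infants, which is exactly the confounding
the Structure covariate exists to control.

**Microbiota.** Counts are Dirichlet-multinomial over 22 reference genera
in five phyla, mixing two base compositions: a Bifidobacterium-dominated
profile (enterotype A) and a Bacteroides-dominated one (enterotype B), with
P(B) rising 0.2 → 0.45 → 0.7 across age — the canonical compositional
shift of the first year. The Dirichlet precision rises with age (15 → 35 →
80), producing the expected increase in alpha diversity. Sequencing depth
is 10,000 reads per sample.

**Mediation modes.** A latent per-assessment mediator $m$ modulates the
Dirichlet precision by $e^{1.5 (m - \bar m)}$. Under `mediation_mode =
"none"`, $m$ is independent noise: markers vary but carry no regularity
signal. Under `"full"`, $m = 3 r_{age} + N(0, 0.5)$, and the designated composite
(default Sleep Variability) is generated from the *realized, standardized
Shannon index* of the simulated samples — not from $r$ — so conditioning on
the measurable marker genuinely blocks the path. `"partial"` adds half the
direct effect back. The coefficients (3, 0.5, 1.5) were fixed by power
reasoning before any acceptance runs: they give the step-1–3 regressions of
the causal-steps procedure clear power at around 150–300 subjects while
keeping marker noise realistic.

Random streams are partitioned per subject and stage (`seed` + subject
index + stage offset), so enlarging a cohort never perturbs existing
subjects.

**What the generator does not emulate.** Meal-time jitter need not be
Gaussian in real diaries; the age trajectory of regularity is a simple
shift-plus-noise around a stable trait, with no autocorrelated
developmental path; parental reporting biases,
missing diary days, device-removal artefacts, compositional zero-inflation
beyond the Dirichlet-multinomial, and any real taxonomic structure finer
than 22 genera are all absent. Passing tests therefore demonstrate that the
*pipeline* recovers what it is pointed at under its stated assumptions, not
that those assumptions hold in any particular cohort.

# Microbiota maturation markers

* **Alpha diversity**: Observed species (count of taxa present), Shannon
  entropy — computed with the *natural* logarithm, stated prominently
  because the base changes values — and the bias-corrected Chao1,
  $S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))$, which stays defined when no
  doubletons occur (routine in small synthetic samples). Computation is
  delegated to `vegan`.
* **Weighted UniFrac** (normalized): branch-length- and abundance-weighted
  community distance, delegated to `phyloseq` behind the package's
  interface. Two numerical points discovered in validation: the normalized
  form depends on the root position, so unrooted trees are rooted
  deterministically at their first tip rather than left to a random
  re-rooting; and the fast implementation assumes binary trees, so
  polytomies are resolved with zero-length edges (value-preserving,
  verified against a brute-force branch enumeration).
* **Enterotypes**: k-medoids (deterministic BUILD+SWAP, `cluster::pam`) at
  $k = 2$ on the weighted-UniFrac matrix, scored by the Calinski–Harabasz
  pseudo-F computed from the squared-distance decomposition, plus a
  Tibshirani–Walther prediction strength from one seeded 2-fold
  co-membership split (no protocol is canonical here; one seeded split is
  the simplest reproducible choice). Partitions with prediction strength
  below 0.8 — the usual stability threshold — are flagged non-separable.
  Exact distance ties in the fold assignment are broken by an
  infinitesimal seeded jitter so that structureless (all-equal) distance
  matrices score at chance instead of inheriting a deterministic
  tie-break. The cluster with higher mean Bifidobacterium relative
  abundance is labelled A, the other B.
* **Bacterial maturation index**: a random-forest regression of
  chronological age on genus-level relative abundances
  (`randomForest`, 500 trees); each training sample's predicted age is its
  out-of-bag prediction, so the index (predicted − actual age) involves no
  leakage and is centred near zero on the training distribution. Genus
  level and out-of-bag evaluation are the package's choices where finer
  conventions are unsettled.
* **Phylum abundances**: counts collapsed by the `p__` annotation and
  normalized per sample; unannotated taxa go to `other` with a warning.

# Association models

Five multilevel models — one per sleep composite — regress the composite on
the ERI plus sex, exact age, breastfeeding, mean meals/day, daytime meal
ratio, and the parental Structure score, with subject random effects
(`lme4`/`lmerTest`). The random structure (intercept vs intercept + ERI
slope) is chosen by AIC under maximum likelihood — AIC comparison across
random structures requires ML — with BIC reported and disagreement flagged;
the selected model is refit under REML, and fixed effects carry
Satterthwaite approximate denominator degrees of freedom (hence fractional
df). Predictors enter unstandardized. Rows with missing values are
listwise-deleted per model, with the count reported; no imputation is
attempted. Covariates that are constant on the analysis rows are dropped
automatically — which is what removes breastfeeding from any 3-month-only
model, where every infant is breastfed.

Per-age models are ordinary linear models (identity link) with the same
fixed effects, one row per subject. The ERI age trend uses one-way ANOVA
with Tukey HSD pairwise comparisons at family-wise 95% confidence.

# Mediation

The Baron–Kenny causal-steps procedure, with the same covariate set and a
subject random intercept in every step (dropped automatically for
one-row-per-subject data; whether the original protocol kept the random
intercept in steps 2–3 is unsettled, so the package includes it and says
so): step 1 $Y \sim X$, step 2 $M \sim X$, steps 3–4 the $M$ and $X$ terms
of $Y \sim X + M$. Verdicts: `full` when steps 1–3 pass at $\alpha = 0.05$
and the step-4 direct effect does not; `partial` when the direct effect
remains significant but attenuated; `no_mediation` when step 2 or 3 fails;
`not_computed` when there is no total effect to mediate — the remaining
models are then not fitted. A Sobel test of the indirect effect is reported
as a labelled extra and never drives the verdict. The screen crosses all
candidate markers with all five composites; p-values are unadjusted by
default (matching a fixed 0.05 alpha-level convention), with an optional
Benjamini–Hochberg variant reported alongside.

# Numerical and operational choices

* Clock times are floored to their epoch (an event "within" an epoch
  belongs to it); `24:00` is out of range by definition of the [0, 1440)
  clock.
* Readers reject rather than coerce: malformed rows abort with line
  numbers, zero-sum samples and missing branch lengths are fatal, and
  every accepted file round-trips exactly.
* All generators and model stages are deterministic under a seed; the
  pipeline report contains no timestamps, so a fixed seed reproduces it
  byte-identically (timings go to a separate log).
* Problem sizes used in the validation suite — up to 300 subjects × 3
  assessments for parameter recovery, 1000 refits for the type-I error
  check, 200 samples per condition for marker properties — were chosen as
  the smallest designs at which the targeted operating characteristics are
  statistically stable.

# Known limitations

* The ERI attenuation described above means coefficients on the observed
  index are mildly conservative relative to effects on latent regularity;
  anyone simulating alternative designs should recalibrate the jitter map
  if they change the day count, epoch width, kernel width, or add/drop
  rates, since the frozen calibration curve is specific to those defaults.
* The enterotype prediction strength uses a single 2-fold split; averaging
  over many splits would stabilize it at extra cost.
* The per-age linear models assume one row per subject and will refuse
  repeated measures rather than silently mixing levels.
* Printed association coefficients in the motivating literature are not
  used as validation surfaces anywhere: cohort-dependent quantities are
  checked as properties (recovery, error rates, discrimination) on
  synthetic data instead.
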