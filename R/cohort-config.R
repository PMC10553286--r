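# Configuration for the synthetic cohort generator.

#' Calibrated jitter map: latent regularity on the ERI scale
#'
#' Default mapping from latent regularity \code{r} to the day-to-day meal
#' timing jitter SD (minutes). The map inverts a fixed calibration curve of
#' mean realized ERI against jitter SD, measured once under the default
#' design (11 diary days, 15-min epochs, SMA width 4, meal add/drop
#' probability 0.05), so that \code{E[ERI | r] ~= r} over the achievable ERI
#' range: the latent regularity parameter lives on the same scale as the
#' index itself, and slopes configured on latent regularity are recovered on
#' the ERI scale by the association models. Values of \code{r} above the
#' achievable maximum (~0.96; day-to-day meal add/drop keeps perfect
#' similarity out of reach) map to zero jitter, values below the asymptotic
#' minimum (~0.29) to the largest calibrated jitter.
#'
#' @param r Latent regularity in [0, 1].
#' @return Jitter SD in minutes, monotone non-increasing in \code{r}.
#' @export
calibrated_jitter_map <- function(r) {
  sd_grid <- c(0, 3, 6, 9, 12, 16, 20, 25, 30, 36, 42, 50, 60, 75, 90,
               110, 140, 180, 240, 320, 480)
  eri_grid <- c(0.9587, 0.9403, 0.9221, 0.9012, 0.8763, 0.8390, 0.8006,
                0.7539, 0.7113, 0.6671, 0.6298, 0.5897, 0.5491, 0.5047,
                0.4722, 0.4398, 0.4051, 0.3720, 0.3403, 0.3142, 0.2956)
  r <- pmin(pmax(r, min(eri_grid)), max(eri_grid))
  stats::approx(x = rev(eri_grid), y = rev(sd_grid), xout = r)$y
}

#' Configure a synthetic infant cohort
#'
#' Bundles and validates every knob of the synthetic cohort generator. The
#' defaults describe a longitudinal design of assessments at 3, 6 and 12
#' months with 11 diary days per assessment at 15-min epoch resolution, a
#' right-shifted latent regularity distribution (Beta(5, 2)), meal counts
#' decreasing with age, and sleep composites linearly coupled to latent
#' regularity with subject random intercepts.
#'
#' @param n_subjects Number of infants.
#' @param ages_months Assessment ages in months.
#' @param days_per_assessment Diary days recorded per assessment.
#' @param epoch_minutes Diary resolution in minutes; must divide 1440.
#' @param seed Base seed. The generator derives one stream per subject and
#'   stage from it, so adding subjects never perturbs existing ones.
#' @param regularity_jitter_map Function mapping latent regularity r in [0, 1]
#'   to the day-to-day meal-timing jitter SD in minutes. Must be monotone
#'   non-increasing in r. The default [calibrated_jitter_map()] puts latent
#'   regularity on the ERI scale (expected realized ERI approximately equals
#'   r), so configured effect sizes are recoverable from models on the
#'   observed ERI.
#' @param meals_per_day_by_age Named numeric vector (names = ages) of mean
#'   daily meal counts; defaults decrease from 8 at 3 months to 5 at
#'   12 months.
#' @param meal_add_prob,meal_drop_prob Per-day probability of one extra meal /
#'   of dropping each template meal; creates realistic day-to-day variation in
#'   meal counts.
#' @param r_shape Beta shape parameters of the latent trait regularity
#'   distribution (the subject's mid-infancy level).
#' @param r_age_offsets Named numeric vector (names = ages) of deterministic
#'   shifts of realized regularity per assessment age; the default encodes
#'   the developmental increase of eating regularity across the first year
#'   (about +0.03 per step from 3 to 12 months).
#' @param r_age_sd SD of per-assessment regularity deviations around
#'   trait + offset: infants' regularity develops at individually varying
#'   pace, so realized regularity at each age is
#'   \code{r_age = r + offset(age) + N(0, r_age_sd)}, clamped to (0, 1).
#' @param effect_sizes Named numeric vector of true slopes of each sleep
#'   composite on latent regularity.
#' @param age_slope Common true slope of every composite on exact age
#'   (months), a mild maturation trend.
#' @param sd_intercept,sd_resid SD of subject random intercepts and of the
#'   residual noise of the sleep composites.
#' @param structure_cor Target correlation between the parental Structure
#'   score and latent regularity.
#' @param breastfeeding_prob Named vector of breastfeeding probabilities per
#'   age; the 3-month value is forced to 1 (all infants primarily breastfed).
#' @param mediation_mode One of \code{"none"}, \code{"full"}, \code{"partial"}:
#'   how the designated microbiota marker sits on the regularity-to-sleep
#'   path. Under \code{"full"} the designated composite depends on regularity
#'   only through the mediator; under \code{"none"} the mediator is
#'   independent noise.
#' @param med_composite,med_a,med_b Designated mediated composite and the
#'   true path coefficients (regularity -> mediator, mediator -> composite).
#' @param depth Sequencing depth per stool sample (multinomial total).
#' @param concentration_by_age Named vector of Dirichlet precision per age;
#'   higher values give richer, more even communities, so diversity rises
#'   with age.
#' @param enterotype_b_prob Named vector of P(Bacteroides-rich enterotype)
#'   per age, encoding the Bifidobacterium-to-Bacteroides shift.
#' @return Validated list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_subjects = 50,
                          ages_months = c(3, 6, 12),
                          days_per_assessment = 11,
                          epoch_minutes = 15,
                          seed = 1,
                          regularity_jitter_map = calibrated_jitter_map,
                          meals_per_day_by_age = c("3" = 8, "6" = 6.5, "12" = 5),
                          meal_add_prob = 0.05,
                          meal_drop_prob = 0.05,
                          r_shape = c(5, 2),
                          r_age_offsets = c("3" = -0.033, "6" = 0,
                                            "12" = 0.033),
                          r_age_sd = 0.1,
                          effect_sizes = c(SleepActivity = -1.5,
                                           SleepDay = 0,
                                           SleepNight = 0,
                                           SleepTiming = -1.5,
                                           SleepVariability = -2),
                          age_slope = -0.05,
                          sd_intercept = 0.5,
                          sd_resid = 1,
                          structure_cor = 0.3,
                          breastfeeding_prob = c("3" = 1, "6" = 0.7, "12" = 0.4),
                          mediation_mode = c("none", "full", "partial"),
                          med_composite = "SleepVariability",
                          med_a = 3,
                          med_b = 1,
                          depth = 10000,
                          concentration_by_age = c("3" = 15, "6" = 35, "12" = 80),
                          enterotype_b_prob = c("3" = 0.2, "6" = 0.45, "12" = 0.7)) {
  mediation_mode <- match.arg(mediation_mode)
  stopifnot(n_subjects >= 1, days_per_assessment >= 1,
            length(ages_months) >= 1, !anyDuplicated(ages_months))
  epochs_per_day(epoch_minutes)   # validates divisibility
  if (!is.function(regularity_jitter_map)) {
    stop("regularity_jitter_map must be a function of r in [0, 1]")
  }
  grid <- seq(0, 1, by = 0.05)
  sds <- vapply(grid, regularity_jitter_map, numeric(1))
  if (any(sds < 0) || any(diff(sds) > 1e-9)) {
    stop("regularity_jitter_map must be non-negative and monotone ",
         "non-increasing in r")
  }
  ages_chr <- as.character(ages_months)
  if (r_age_sd < 0) stop("r_age_sd must be non-negative")
  for (nm in c("meals_per_day_by_age", "breastfeeding_prob",
               "concentration_by_age", "enterotype_b_prob",
               "r_age_offsets")) {
    v <- get(nm)
    if (!all(ages_chr %in% names(v))) {
      stop(nm, " must be named with every assessment age")
    }
  }
  probs <- c(meal_add_prob, meal_drop_prob, structure_cor,
             breastfeeding_prob, enterotype_b_prob)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (depth < 1) stop("sequencing depth must be >= 1")
  comps <- c("SleepActivity", "SleepDay", "SleepNight",
             "SleepTiming", "SleepVariability")
  if (!all(comps %in% names(effect_sizes))) {
    stop("effect_sizes must name all five sleep composites")
  }
  if (!med_composite %in% comps) stop("unknown med_composite")
  structure(mget(c("n_subjects", "ages_months", "days_per_assessment",
                   "epoch_minutes", "seed", "regularity_jitter_map",
                   "meals_per_day_by_age", "meal_add_prob", "meal_drop_prob",
                   "r_shape", "r_age_offsets", "r_age_sd",
                   "effect_sizes", "age_slope", "sd_intercept",
                   "sd_resid", "structure_cor", "breastfeeding_prob",
                   "mediation_mode", "med_composite", "med_a", "med_b",
                   "depth", "concentration_by_age", "enterotype_b_prob")),
            class = "cohort_config")
}

# Deterministic per-subject, per-stage seeds; adding subjects or stages never
# perturbs earlier streams. Kept well below .Machine$integer.max.
subject_seed <- function(config, i, stage) {
  offset <- c(diary = 0L, sleep = 20000019L, microbiota = 40000007L)[[stage]]
  as.integer((config$seed %% 1000003L) * 1009L + offset + i)
}
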