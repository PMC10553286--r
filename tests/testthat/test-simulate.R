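# Synthetic cohort generator: determinism, grid/wrap invariants, configured
# trends and couplings, degenerate-noise limits.

test_that("config validation rejects bad inputs", {
  expect_error(cohort_config(epoch_minutes = 25), "divisor")
  expect_error(cohort_config(regularity_jitter_map = function(r) r * 30),
               "monotone")
  expect_error(cohort_config(regularity_jitter_map = function(r) -5),
               "monotone|non-negative")
  expect_error(cohort_config(meal_add_prob = 1.5), "probabilities")
  expect_error(cohort_config(depth = 0), "depth")
  expect_error(cohort_config(meals_per_day_by_age = c("3" = 8)), "named")
  expect_error(cohort_config(effect_sizes = c(SleepActivity = 1)),
               "five sleep composites")
})

test_that("the calibrated jitter map is monotone and hits the endpoints", {
  r <- seq(0, 1, by = 0.01)
  sd <- calibrated_jitter_map(r)
  expect_true(all(diff(sd) <= 1e-9))
  expect_equal(calibrated_jitter_map(1), 0)
  expect_gt(calibrated_jitter_map(0), 400)
})

test_that("diaries are deterministic under seed and respect the epoch grid", {
  cfg <- cohort_config(n_subjects = 8, seed = 99)
  d1 <- simulate_diaries(cfg)
  d2 <- simulate_diaries(cfg)
  expect_identical(d1, d2)
  mm <- d1$diary$meal_min[!is.na(d1$diary$meal_min)]
  expect_true(all(mm >= 0 & mm < 1440))
  expect_true(all(mm %% cfg$epoch_minutes == 0))
  # per-subject streams: adding subjects never perturbs existing ones
  d3 <- simulate_diaries(cohort_config(n_subjects = 12, seed = 99))
  expect_identical(d1$diary,
                   d3$diary[d3$diary$subject_id %in% d1$diary$subject_id, ])
  keep <- d3$truth$subject_id %in% d1$truth$subject_id
  expect_identical(d1$truth, d3$truth[keep, ])
})

test_that("degenerate noise gives identical days", {
  cfg <- cohort_config(n_subjects = 4, seed = 5,
                       regularity_jitter_map = function(r) 0 * r,
                       meal_add_prob = 0, meal_drop_prob = 0)
  d <- simulate_diaries(cfg)$diary
  for (s in unique(d$subject_id)) for (a in unique(d$age_months)) {
    days <- split(d$meal_min[d$subject_id == s & d$age_months == a],
                  d$day[d$subject_id == s & d$age_months == a])
    expect_true(all(vapply(days, identical, logical(1), y = days[[1]])))
  }
  # and therefore ERI exactly 1
  e <- compute_eri_cohort(d)
  expect_true(all(abs(e$eri - 1) < 1e-12))
})

test_that("mean meals per day follows the configured age trend", {
  cfg <- cohort_config(n_subjects = 200, seed = 31)
  d <- simulate_diaries(cfg)$diary
  meals <- tapply(!is.na(d$meal_min), paste(d$subject_id, d$age_months, d$day),
                  sum)
  age_of <- as.numeric(sub(".* (\\d+) .*", "\\1",
                           sub("^(\\S+) (\\S+) (\\S+)$", "\\1 \\2 \\3",
                               names(meals))))
  m_by_age <- tapply(meals, age_of, mean)
  expect_gt(m_by_age[["3"]], m_by_age[["6"]])
  expect_gt(m_by_age[["6"]], m_by_age[["12"]])
})

test_that("sleep composites recover configured slopes and null couplings", {
  # null effects: composite uncorrelated with latent regularity
  cfg0 <- cohort_config(n_subjects = 500, seed = 17,
                        effect_sizes = c(SleepActivity = 0, SleepDay = 0,
                                         SleepNight = 0, SleepTiming = 0,
                                         SleepVariability = 0))
  d0 <- simulate_diaries(cfg0)
  s0 <- simulate_sleep_and_covariates(d0$truth, cfg0)
  dat0 <- merge(s0$sleep, d0$truth)
  for (cm in sleep_composite_names()) {
    expect_lt(abs(cor(dat0$r, dat0[[cm]])), 0.1)
  }

  # b = -2 on Sleep Variability: Monte-Carlo mean of the OLS slope of the
  # composite on true realized regularity recovers the configured truth
  sl <- vapply(1:8, function(rep) {
    cfg <- cohort_config(n_subjects = 300, seed = 1000 + rep)
    d <- simulate_diaries(cfg)
    ss <- simulate_sleep_and_covariates(d$truth, cfg)
    dat <- merge(ss$sleep, d$truth)
    coef(lm(SleepVariability ~ r_age + exact_age, data = dat))[["r_age"]]
  }, numeric(1))
  expect_lt(abs(mean(sl) - (-2)), 0.3)

  cfg <- cohort_config(n_subjects = 300, seed = 23)
  d <- simulate_diaries(cfg)
  s <- simulate_sleep_and_covariates(d$truth, cfg)
  dat <- merge(s$sleep, d$truth)

  # breastfeeding is 1 for every infant at 3 months
  expect_true(all(s$sleep$breastfeeding[s$sleep$age_months == 3] == 1))
  # sex is 0/1 and constant within subject
  expect_true(all(s$sleep$sex %in% 0:1))
  expect_true(all(tapply(s$sleep$sex, s$sleep$subject_id,
                         function(x) length(unique(x))) == 1))
  # Structure score correlates positively with latent regularity
  subj <- dat[!duplicated(dat$subject_id), ]
  expect_gt(cor(subj$structure_score, subj$r), 0.15)
})

test_that("zero random-intercept variance leaves no within-subject correlation", {
  cfg <- cohort_config(n_subjects = 400, seed = 41, sd_intercept = 0,
                       effect_sizes = c(SleepActivity = 0, SleepDay = 0,
                                        SleepNight = 0, SleepTiming = 0,
                                        SleepVariability = 0),
                       age_slope = 0)
  d <- simulate_diaries(cfg)
  s <- simulate_sleep_and_covariates(d$truth, cfg)
  wide <- reshape(s$sleep[, c("subject_id", "age_months", "SleepDay")],
                  idvar = "subject_id", timevar = "age_months",
                  direction = "wide")
  cors <- cor(wide[, -1])[upper.tri(diag(3))]
  expect_true(all(abs(cors) < 0.12))   # ICC sigma_b^2/(sigma_b^2+sigma_e^2) = 0
})

test_that("microbiota counts converge to the base composition at high concentration", {
  cfg <- cohort_config(n_subjects = 3, seed = 13, depth = 1e5,
                       concentration_by_age = c("3" = 1e7, "6" = 1e7,
                                                "12" = 1e7),
                       enterotype_b_prob = c("3" = 0, "6" = 0, "12" = 0))
  m <- simulate_microbiota(simulate_diaries(cfg)$truth, cfg)
  base <- taxa_reference()$base_A
  prop <- sweep(m$counts, 2, colSums(m$counts), "/")
  expect_lt(max(abs(prop - base)), 0.02)
  expect_true(all(m$truth$enterotype == "A"))
})

test_that("alpha diversity rises with age as configured", {
  cfg <- cohort_config(n_subjects = 200, seed = 53)
  m <- simulate_microbiota(simulate_diaries(cfg)$truth, cfg)
  sh <- alpha_diversity(m$counts)$shannon
  by_age <- tapply(sh, m$meta$age_months, mean)
  expect_lt(by_age[["3"]], by_age[["6"]])
  expect_lt(by_age[["6"]], by_age[["12"]])
})

test_that("under mediation_mode none the marker is independent of regularity", {
  cfg <- cohort_config(n_subjects = 500, seed = 61, mediation_mode = "none")
  d <- simulate_diaries(cfg)
  s <- simulate_sleep_and_covariates(d$truth, cfg)
  m <- simulate_microbiota(s$truth, cfg)
  sh <- alpha_diversity(m$counts)$shannon
  dat <- merge(data.frame(sample_id = m$meta$sample_id,
                          subject_id = m$meta$subject_id,
                          age_months = m$meta$age_months, shannon = sh),
               merge(s$sleep, d$truth))
  # partial correlation of marker with the composite given r (within age)
  a6 <- dat[dat$age_months == 6, ]
  res_m <- resid(lm(shannon ~ r, a6))
  res_y <- resid(lm(SleepVariability ~ r, a6))
  expect_lt(abs(cor(res_m, res_y)), 0.12)
  # and the marker itself is uncoupled from r
  expect_lt(abs(cor(a6$shannon, a6$r)), 0.12)
})

test_that("under mediation_mode full the marker carries the r signal", {
  cfg <- cohort_config(n_subjects = 150, seed = 67, mediation_mode = "full")
  coh <- simulate_cohort(cfg)
  sh <- alpha_diversity(coh$counts)$shannon
  dat <- merge(cbind(coh$meta, shannon = sh),
               merge(coh$sleep, coh$truth))
  a6 <- dat[dat$age_months == 6, ]
  expect_gt(cor(a6$shannon, a6$r_age), 0.3)
  expect_gt(cor(a6$SleepVariability, a6$shannon), 0.3)
  # sleep stage refuses to run blind in a mediated configuration
  expect_error(simulate_sleep_and_covariates(coh$truth, cfg), "mediator")
})
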