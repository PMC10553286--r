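# Association models: multilevel models of sleep composites on the ERI with
# AIC/BIC random-structure selection, per-age linear models, and the one-way
# ANOVA + Tukey age trend of the ERI.

default_covariates <- function() {
  c("sex", "exact_age", "breastfeeding", "mean_meals_per_day",
    "daytime_meal_ratio", "structure_score")
}

# Drop predictors that are constant on the analysis rows (e.g. breastfeeding
# in a 3-month-only design, where every infant is breastfed).
drop_constant_predictors <- function(data, predictors) {
  keep <- vapply(predictors, function(p) {
    v <- data[[p]]
    length(unique(v[!is.na(v)])) > 1
  }, logical(1))
  list(predictors = predictors[keep], dropped = predictors[!keep])
}

coef_table_lmer <- function(fit) {
  s <- as.data.frame(stats::coef(summary(fit)))   # lmerTest: Satterthwaite df
  data.frame(term = rownames(s), estimate = s[, "Estimate"],
             se = s[, "Std. Error"], df = s[, "df"], t = s[, "t value"],
             p = s[, "Pr(>|t|)"], row.names = NULL,
             stringsAsFactors = FALSE)
}

coef_table_lm <- function(fit) {
  s <- as.data.frame(stats::coef(summary(fit)))
  data.frame(term = rownames(s), estimate = s[, "Estimate"],
             se = s[, "Std. Error"], df = fit$df.residual,
             t = s[, "t value"], p = s[, "Pr(>|t|)"], row.names = NULL,
             stringsAsFactors = FALSE)
}

build_formula <- function(outcome, predictors, random = NULL,
                          group = "subject_id") {
  rhs <- paste(predictors, collapse = " + ")
  if (!is.null(random)) {
    re <- switch(random,
                 intercept = sprintf("(1 | %s)", group),
                 slope = sprintf("(1 + %s | %s)", predictors[1L], group))
    rhs <- paste(rhs, re, sep = " + ")
  }
  stats::as.formula(paste(outcome, "~", rhs))
}

#' Choose the random-effects structure by AIC/BIC
#'
#' Fits the random-intercept and the random-intercept-plus-slope (slope on
#' the focal predictor, the first in \code{predictors}) variants under
#' maximum likelihood and selects the structure with the lower AIC; BIC is
#' reported alongside and any AIC/BIC disagreement flagged. Non-converging
#' variants are disqualified. With at most one observation per subject the
#' variance components are unidentifiable and the selection falls back to a
#' fixed-effects model.
#'
#' @param data Model data frame.
#' @param outcome Outcome column name.
#' @param predictors Fixed-effect column names; first is the focal predictor
#'   that receives the random slope in the richer variant.
#' @param group Grouping column (default \code{"subject_id"}).
#' @return List of class \code{"rs_selection"}: \code{chosen} (one of
#'   \code{"intercept"}, \code{"slope"}, \code{"none"}), \code{criteria}
#'   (data frame of AIC/BIC per candidate), \code{agreement} (AIC and BIC
#'   prefer the same structure).
#' @export
select_random_structure <- function(data, outcome,
                                    predictors = c("eri", default_covariates()),
                                    group = "subject_id") {
  predictors <- drop_constant_predictors(data, predictors)$predictors
  if (max(table(data[[group]])) < 2) {
    return(structure(list(chosen = "none",
                          criteria = data.frame(),
                          agreement = NA,
                          reason = "at most one observation per subject"),
                     class = "rs_selection"))
  }
  cand <- c("intercept", "slope")
  fits <- lapply(cand, function(rs) {
    f <- build_formula(outcome, predictors, random = rs, group = group)
    tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(f, data = data, REML = FALSE))),
      error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  conv <- ok
  conv[ok] <- vapply(fits[ok], function(f) {
    length(f@optinfo$conv$lme4$messages) == 0 ||
      !any(grepl("failed to converge", f@optinfo$conv$lme4$messages))
  }, logical(1))
  crit <- data.frame(structure = cand,
                     converged = conv,
                     AIC = ifelse(ok, vapply(fits, function(f)
                       if (is.null(f)) NA_real_ else stats::AIC(f),
                       numeric(1)), NA_real_),
                     BIC = ifelse(ok, vapply(fits, function(f)
                       if (is.null(f)) NA_real_ else stats::BIC(f),
                       numeric(1)), NA_real_),
                     stringsAsFactors = FALSE)
  usable <- which(conv)
  if (!length(usable)) {
    return(structure(list(chosen = "none", criteria = crit, agreement = NA,
                          reason = "no random-effects variant converged"),
                     class = "rs_selection"))
  }
  by_aic <- cand[usable][which.min(crit$AIC[usable])]
  by_bic <- cand[usable][which.min(crit$BIC[usable])]
  structure(list(chosen = by_aic, criteria = crit,
                 agreement = identical(by_aic, by_bic), reason = NULL),
            class = "rs_selection")
}

#' Fit a multilevel association model
#'
#' Linear mixed model of a sleep composite (or any outcome) on the ERI plus
#' covariates, with subject random effects. The random structure is either
#' fixed by the caller or chosen by [select_random_structure()] under ML;
#' the reported model is refit under REML with Satterthwaite approximate
#' denominator degrees of freedom, the convention behind fractional df in
#' longitudinal sleep reports. Rows with missing values in any model variable
#' are listwise-deleted (count reported).
#'
#' @inheritParams select_random_structure
#' @param random \code{"auto"} (AIC selection), \code{"intercept"},
#'   \code{"slope"}, or \code{"none"} (plain linear model).
#' @return Object of class \code{"ml_model"}: \code{coef} (term / estimate /
#'   se / df / t / p), \code{random_structure}, \code{selection},
#'   \code{AIC}, \code{BIC}, \code{n_obs}, \code{n_subjects},
#'   \code{n_dropped}, \code{dropped_predictors}, \code{fit}.
#' @export
fit_multilevel <- function(data, outcome,
                           predictors = c("eri", default_covariates()),
                           random = "auto", group = "subject_id") {
  vars <- c(outcome, predictors, group)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("data lacks column(s): ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[, vars])
  n_dropped <- sum(!cc)
  data <- data[cc, , drop = FALSE]
  dp <- drop_constant_predictors(data, predictors)
  predictors <- dp$predictors
  X <- stats::model.matrix(build_formula(outcome, predictors), data)
  if (qr(X)$rank < ncol(X)) {
    ali <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(ali, collapse = ", "))
  }
  selection <- NULL
  if (identical(random, "auto")) {
    selection <- select_random_structure(data, outcome, predictors, group)
    random <- selection$chosen
  }
  if (identical(random, "none")) {
    fit <- stats::lm(build_formula(outcome, predictors), data = data)
    coef_tab <- coef_table_lm(fit)
    conv <- TRUE
  } else {
    f <- build_formula(outcome, predictors, random = random, group = group)
    fit <- suppressWarnings(suppressMessages(
      lmerTest::lmer(f, data = data, REML = TRUE)))
    coef_tab <- coef_table_lmer(fit)
    conv <- length(fit@optinfo$conv$lme4$messages) == 0 ||
      !any(grepl("failed to converge", fit@optinfo$conv$lme4$messages))
  }
  structure(list(coef = coef_tab,
                 outcome = outcome, predictors = predictors,
                 random_structure = random, selection = selection,
                 AIC = stats::AIC(fit), BIC = stats::BIC(fit),
                 n_obs = nrow(data),
                 n_subjects = length(unique(data[[group]])),
                 n_dropped = n_dropped,
                 dropped_predictors = dp$dropped,
                 converged = conv, fit = fit),
            class = "ml_model")
}

#' @export
print.ml_model <- function(x, digits = 3, ...) {
  cat(sprintf("%s ~ %s  [random: %s; n = %d obs, %d subjects]\n",
              x$outcome, paste(x$predictors, collapse = " + "),
              x$random_structure, x$n_obs, x$n_subjects))
  tab <- x$coef
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-20s t(%.3f) = %.3f, b = %.3f, p = %s\n",
                tab$term[i], tab$df[i], tab$t[i], tab$estimate[i],
                format.pval(tab$p[i], digits = digits, eps = 1e-3)))
  }
  invisible(x)
}

#' Per-age linear association model
#'
#' Ordinary linear model (identity link) for a single assessment age, with
#' the same fixed effects as the multilevel model; constant covariates are
#' dropped automatically, which removes breastfeeding from the 3-month model
#' where every infant is breastfed.
#'
#' @inheritParams fit_multilevel
#' @param age Assessment age to restrict to (rows with
#'   \code{age_months == age}); NULL uses the data as passed.
#' @return An \code{"ml_model"} object with \code{random_structure "none"}.
#' @export
fit_age_glm <- function(data, outcome, age = NULL,
                        predictors = c("eri", default_covariates()),
                        group = "subject_id") {
  if (!is.null(age)) data <- data[data$age_months == age, , drop = FALSE]
  if (anyDuplicated(data[[group]])) {
    stop("per-age model expects one row per subject")
  }
  if (nrow(data) <= length(predictors) + 1) {
    stop("not enough rows (", nrow(data), ") to estimate ",
         length(predictors) + 1, " coefficients")
  }
  fit_multilevel(data, outcome, predictors, random = "none", group = group)
}

#' Age trend of the ERI: one-way ANOVA with Tukey HSD
#'
#' Tests whether the ERI differs between assessment ages with a one-way
#' ANOVA and locates the differences with Tukey honest-significant-difference
#' pairwise comparisons at family-wise 95% confidence.
#'
#' @param eri Numeric vector of ERI values.
#' @param age Assessment age of each value (>= 2 groups, each with >= 2
#'   values).
#' @return List of class \code{"age_trend"}: \code{F}, \code{df1},
#'   \code{df2}, \code{p}, \code{tukey} (data frame comparison / diff / lwr /
#'   upr / p_adj), \code{group_means}.
#' @export
age_trend_anova <- function(eri, age) {
  keep <- !is.na(eri) & !is.na(age)
  eri <- eri[keep]; age <- factor(age[keep])
  if (nlevels(age) < 2) stop("need at least 2 age groups")
  if (any(table(age) < 2)) stop("each age group needs at least 2 values")
  fit <- stats::aov(eri ~ age)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$age
  structure(list(F = an["age", "F value"],
                 df1 = an["age", "Df"], df2 = an["Residuals", "Df"],
                 p = an["age", "Pr(>F)"],
                 tukey = data.frame(comparison = rownames(tk),
                                    diff = tk[, "diff"], lwr = tk[, "lwr"],
                                    upr = tk[, "upr"], p_adj = tk[, "p adj"],
                                    row.names = NULL,
                                    stringsAsFactors = FALSE),
                 group_means = tapply(eri, age, mean)),
            class = "age_trend")
}

#' @export
print.age_trend <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.2f, p = %s\n",
              x$df1, x$df2, x$F, format.pval(x$p, digits = 3, eps = 1e-3)))
  print(x$tukey, digits = 3)
  invisible(x)
}
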