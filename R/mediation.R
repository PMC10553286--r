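# Baron & Kenny causal-steps mediation of microbiota markers on the
# ERI -> sleep-composite paths.

term_row <- function(model, term) {
  i <- match(term, model$coef$term)
  if (is.na(i)) stop("term '", term, "' absent from model")
  model$coef[i, , drop = FALSE]
}

verdict_from_steps <- function(p1, p2, p3, p4, b1, b4, alpha) {
  if (is.na(p1) || p1 >= alpha) {
    return(list(verdict = "not_computed",
                stop_reason = "no total effect of X on Y (step 1)"))
  }
  if (is.na(p2) || p2 >= alpha) {
    return(list(verdict = "no_mediation",
                stop_reason = "X not associated with M (step 2)"))
  }
  if (is.na(p3) || p3 >= alpha) {
    return(list(verdict = "no_mediation",
                stop_reason = "M not associated with Y given X (step 3)"))
  }
  if (p4 >= alpha) {
    list(verdict = "full", stop_reason = NA_character_)
  } else if (abs(b4) < abs(b1)) {
    list(verdict = "partial", stop_reason = NA_character_)
  } else {
    list(verdict = "no_mediation",
         stop_reason = "direct effect not attenuated (step 4)")
  }
}

#' Baron & Kenny 4-step mediation test
#'
#' Sequential causal-steps procedure for a mediator M on the X -> Y path,
#' with covariates and a subject random intercept in every step (dropped
#' automatically when each subject contributes a single row):
#' step 1 regresses Y on X, step 2 M on X, steps 3 and 4 read the M and X
#' coefficients of the joint model Y ~ X + M. The verdict is \code{"full"}
#' when steps 1-3 are significant and the step-4 direct effect is not,
#' \code{"partial"} when the direct effect stays significant but attenuated,
#' \code{"no_mediation"} when step 2 or 3 fails, and \code{"not_computed"}
#' when there is no total effect to mediate (the later models are then not
#' fitted). A Sobel test of the indirect effect is reported as a labelled
#' extra; it plays no role in the verdict.
#'
#' @param data Data frame holding all variables on common rows.
#' @param x,m,y Column names of the independent variable, mediator (numeric,
#'   or 0/1 for the enterotype) and outcome.
#' @param covariates Control-variable column names entered in steps 1, 3, 4
#'   (and, with X, in step 2).
#' @param group Subject identifier column for the random intercept.
#' @param alpha Per-step significance level (default 0.05).
#' @return List of class \code{"bk_mediation"}: per-step coefficient rows,
#'   \code{verdict}, \code{stop_reason}, \code{degenerate}, \code{sobel}
#'   (z and p, when steps 2-3 were fitted), and the step p-values/estimates.
#' @export
baron_kenny <- function(data, x = "eri", m, y,
                        covariates = default_covariates(),
                        group = "subject_id", alpha = 0.05) {
  mv <- data[[m]]
  if (is.null(mv)) stop("mediator column '", m, "' not found")
  if (length(unique(mv[!is.na(mv)])) < 2) {
    stop("mediator '", m, "' is constant; mediation undefined")
  }
  cc <- stats::complete.cases(data[, c(x, m, y, covariates, group)])
  data <- data[cc, , drop = FALSE]
  degenerate <- abs(stats::cor(data[[x]], data[[m]])) > 0.999
  random <- if (max(table(data[[group]])) >= 2) "intercept" else "none"
  fit_step <- function(outcome, predictors) {
    tryCatch(fit_multilevel(data, outcome, predictors, random = random,
                            group = group),
             error = function(e) e)
  }
  res <- list(x = x, m = m, y = y, alpha = alpha, degenerate = degenerate,
              step1 = NULL, step2 = NULL, step3 = NULL, step4 = NULL,
              sobel = NULL)
  class(res) <- "bk_mediation"
  if (degenerate) {   # M aliased with X: steps 3-4 cannot separate them
    res$verdict <- "not_computed"
    res$stop_reason <- "mediator is collinear with the independent variable"
    return(res)
  }
  p1 <- p2 <- p3 <- p4 <- NA_real_; b1 <- b4 <- NA_real_
  s1 <- fit_step(y, c(x, covariates))
  if (inherits(s1, "error")) {
    res$verdict <- "not_computed"; res$stop_reason <- conditionMessage(s1)
    return(res)
  }
  res$step1 <- term_row(s1, x); p1 <- res$step1$p; b1 <- res$step1$estimate
  if (p1 < alpha) {
    s2 <- fit_step(m, c(x, covariates))
    if (inherits(s2, "error")) {
      res$verdict <- "not_computed"; res$stop_reason <- conditionMessage(s2)
      return(res)
    }
    res$step2 <- term_row(s2, x); p2 <- res$step2$p
    s34 <- fit_step(y, c(x, m, covariates))
    if (inherits(s34, "error")) {       # e.g. M aliased with X
      res$degenerate <- TRUE
      res$verdict <- "not_computed"; res$stop_reason <- conditionMessage(s34)
      return(res)
    }
    res$step3 <- term_row(s34, m); p3 <- res$step3$p
    res$step4 <- term_row(s34, x); p4 <- res$step4$p
    b4 <- res$step4$estimate
    a_est <- res$step2$estimate; a_se <- res$step2$se
    b_est <- res$step3$estimate; b_se <- res$step3$se
    z <- (a_est * b_est) /
      sqrt(b_est^2 * a_se^2 + a_est^2 * b_se^2)
    res$sobel <- c(z = z, p = 2 * stats::pnorm(-abs(z)))
  }
  v <- verdict_from_steps(p1, p2, p3, p4, b1, b4, alpha)
  res$verdict <- v$verdict
  res$stop_reason <- v$stop_reason
  res$p_steps <- c(step1 = p1, step2 = p2, step3 = p3, step4 = p4)
  res$b_total <- b1
  res$b_direct <- b4
  res
}

#' @export
print.bk_mediation <- function(x, ...) {
  cat(sprintf("Baron-Kenny mediation: %s -> %s -> %s\n", x$x, x$m, x$y))
  ps <- x$p_steps
  if (!is.null(ps)) {
    cat("  step p-values:",
        paste(sprintf("%s = %s", names(ps),
                      format.pval(ps, digits = 3, eps = 1e-3)),
              collapse = ", "), "\n")
  }
  cat("  verdict:", x$verdict,
      if (!is.na(x$stop_reason %||% NA)) paste0("(", x$stop_reason, ")") else "",
      "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen all marker-composite pairs for mediation
#'
#' Runs [baron_kenny()] over the cross product of candidate microbiota
#' markers and sleep composites, returning one ordered row per pair. P-values
#' are used unadjusted at \code{alpha} by default; \code{p_adjust = "BH"}
#' additionally reports Benjamini-Hochberg-adjusted step p-values (within
#' each step, across pairs) and a verdict recomputed from them.
#'
#' @param data Data frame with the ERI, markers, composites, covariates and
#'   subject ids on common rows.
#' @param markers Character vector of mediator column names.
#' @param composites Character vector of outcome column names.
#' @inheritParams baron_kenny
#' @param p_adjust \code{"none"} (default, mirrors a fixed 0.05 alpha level)
#'   or \code{"BH"}.
#' @return Data frame, one row per marker x composite, with the step
#'   p-values, total/direct effects, verdict and stop reason; the full
#'   \code{bk_mediation} objects are attached as attribute \code{"fits"}.
#' @export
mediation_screen <- function(data, markers, composites = sleep_composite_names(),
                             x = "eri", covariates = default_covariates(),
                             group = "subject_id", alpha = 0.05,
                             p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!length(markers)) stop("marker set must be non-empty")
  grid <- expand.grid(marker = markers, composite = composites,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    bk <- baron_kenny(data, x = x, m = grid$marker[i], y = grid$composite[i],
                      covariates = covariates, group = group, alpha = alpha)
    fits[[i]] <- bk
    ps <- bk$p_steps %||% rep(NA_real_, 4)
    rows[[i]] <- data.frame(
      marker = grid$marker[i], composite = grid$composite[i],
      p_step1 = ps[[1]], p_step2 = ps[[2]], p_step3 = ps[[3]],
      p_step4 = ps[[4]],
      b_total = bk$b_total %||% NA_real_,
      b_direct = bk$b_direct %||% NA_real_,
      verdict = bk$verdict, stop_reason = bk$stop_reason %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") {
    for (s in paste0("p_step", 1:4)) {
      out[[paste0(s, "_adj")]] <- stats::p.adjust(out[[s]], method = "BH")
    }
    out$verdict_adj <- vapply(seq_len(nrow(out)), function(i) {
      verdict_from_steps(out$p_step1_adj[i], out$p_step2_adj[i],
                         out$p_step3_adj[i], out$p_step4_adj[i],
                         out$b_total[i], out$b_direct[i], alpha)$verdict
    }, character(1))
  }
  attr(out, "fits") <- fits
  out
}
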