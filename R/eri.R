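# Eating Regularity Index: binary meal-start epoch profiles, double circular
# SMA smoothing, all-pairs cosine similarity.

#' Binarize one diary day into an epoch profile
#'
#' Converts the meal start times of a single day into a binary vector over the
#' 24-h epoch grid: entry \code{e} is 1 if at least one meal starts in epoch
#' \code{e} and 0 otherwise. At the default 15-min resolution the profile has
#' 96 entries. Multiple meals falling in the same epoch still give a 1 (the
#' profile encodes presence of a meal start, not counts).
#'
#' @param meal_min Numeric vector of meal start times in minutes since
#'   midnight, each in \code{[0, 1440)}. May be empty (a zero-meal day).
#' @param epoch_minutes Epoch width in minutes; must divide 1440. Default 15.
#' @return Integer 0/1 vector of length \code{1440 / epoch_minutes}.
#' @examples
#' p <- binarize_day(c(0, 450))   # meals at 00:00 and 07:30
#' which(p == 1)                  # epochs 1 and 31 (0-based indices 0 and 30)
#' @export
binarize_day <- function(meal_min, epoch_minutes = 15) {
  n_epochs <- epochs_per_day(epoch_minutes)
  prof <- integer(n_epochs)
  if (length(meal_min)) {
    meal_min <- meal_min[!is.na(meal_min)]
    if (any(meal_min < 0 | meal_min >= 1440)) {
      stop("meal times must lie in [0, 1440) minutes")
    }
    prof[unique(floor(meal_min / epoch_minutes)) + 1L] <- 1L
  }
  prof
}

epochs_per_day <- function(epoch_minutes) {
  if (length(epoch_minutes) != 1L || epoch_minutes < 1 ||
      1440 %% epoch_minutes != 0) {
    stop("epoch_minutes must be a positive divisor of 1440")
  }
  as.integer(1440 / epoch_minutes)
}

#' Double circular simple moving average
#'
#' Applies a uniform moving-average kernel of width \code{k} epochs twice to an
#' epoch profile, with wrap-around at midnight so that meals near 00:00
#' neighbour meals near 23:45. For even \code{k} the kernel is centred
#' left-biased: the window at epoch t covers \code{[t - floor((k-1)/2),
#' t + ceiling((k-1)/2)]} (indices modulo profile length). A single smoothing
#' pass conserves total mass, so \code{sum(double_sma(x, k)) == sum(x)}.
#'
#' The double pass turns a unit impulse into a triangular bump spanning
#' \code{2k - 1} epochs, so epochs closer to a meal receive higher values.
#'
#' @param x Numeric epoch profile (typically from [binarize_day()]).
#' @param k Kernel width in epochs, \code{1 <= k <= length(x)}. \code{k = 1}
#'   is the identity.
#' @param passes Number of smoothing passes; the index uses 2.
#' @return Numeric vector of the same length as \code{x}.
#' @export
double_sma <- function(x, k, passes = 2L) {
  if (k < 1 || k != round(k)) stop("k must be a positive integer")
  if (k > length(x)) stop("k must not exceed the profile length")
  y <- as.numeric(x)
  if (k == 1L) return(y)
  kern <- rep(1 / k, k)
  for (i in seq_len(passes)) {
    y <- as.numeric(stats::filter(y, kern, sides = 2, circular = TRUE))
  }
  y
}

#' Cosine similarity between two epoch profiles
#'
#' \code{dot(a, b) / (||a|| ||b||)}. For non-negative profiles the value lies
#' in \code{[0, 1]}: 1 for proportional profiles, 0 for disjoint support.
#'
#' @param a,b Numeric vectors of equal length; both must be non-zero.
#' @return Similarity in \code{[0, 1]}.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity is undefined for a zero profile; drop zero-meal days")
  }
  sum(a * b) / (na * nb)
}

# All-pairs cosine similarities of the columns of a profile matrix (epochs x
# days), returned as the upper-triangle data frame. Vectorised via crossprod.
pairwise_cosines <- function(mat) {
  cp <- crossprod(mat)                       # days x days dot products
  nrm <- sqrt(diag(cp))
  cs <- cp / tcrossprod(nrm)
  idx <- which(upper.tri(cs), arr.ind = TRUE)
  data.frame(day_i = idx[, 1L], day_j = idx[, 2L],
             cosine = cs[idx], row.names = NULL)
}

#' Eating Regularity Index for one subject-assessment
#'
#' Each recorded day is binarized onto the epoch grid, smoothed with a double
#' circular SMA of width \code{k}, and compared to every other day of the same
#' subject-assessment by cosine similarity. The ERI is the mean over all
#' \code{choose(n, 2)} day pairs; 0 means highly irregular and 1 highly
#' regular meal timing.
#'
#' Days without any meal are dropped before pairing (cosine similarity is
#' undefined on a zero vector); subjects retaining fewer than \code{min_days}
#' days are flagged excluded and receive no ERI. Two meal-pattern covariates
#' are returned alongside: the mean number of meals per retained day, and the
#' fraction of meals starting in the daytime window 07:00-19:00 (half-open).
#'
#' @param days List of numeric vectors, one per diary day, each holding meal
#'   start times in minutes since midnight.
#' @param k SMA kernel width in epochs (default 4, i.e. 1 h at 15-min epochs).
#' @param epoch_minutes Epoch width in minutes (default 15).
#' @param min_days Minimum retained days for inclusion (default 5; must be
#'   at least 2 or no day pair exists).
#' @return List of class \code{"eri_result"}: \code{eri}, \code{n_days_used},
#'   \code{pairwise} (data frame day_i/day_j/cosine), \code{mean_meals_per_day},
#'   \code{daytime_meal_ratio}, \code{excluded}, \code{exclude_reason},
#'   \code{n_days_dropped} (zero-meal days).
#' @seealso [compute_eri_cohort()] for whole-cohort computation,
#'   [select_sma_interval()] for choosing \code{k}.
#' @export
compute_eri <- function(days, k = 4, epoch_minutes = 15, min_days = 5) {
  if (min_days < 2) stop("min_days must be >= 2 (no day pairs otherwise)")
  stopifnot(is.list(days))
  n_meals <- vapply(days, function(d) length(d[!is.na(d)]), integer(1))
  keep <- n_meals > 0L
  res <- list(eri = NA_real_, n_days_used = sum(keep),
              pairwise = NULL,
              mean_meals_per_day = NA_real_, daytime_meal_ratio = NA_real_,
              excluded = FALSE, exclude_reason = NA_character_,
              n_days_dropped = sum(!keep))
  class(res) <- "eri_result"
  if (sum(keep) < min_days) {
    res$excluded <- TRUE
    res$exclude_reason <- sprintf("only %d valid diary days (< %d required)",
                                  sum(keep), as.integer(min_days))
    return(res)
  }
  days <- days[keep]
  prof <- vapply(days, function(d) {
    double_sma(binarize_day(d, epoch_minutes), k)
  }, numeric(epochs_per_day(epoch_minutes)))
  res$pairwise <- pairwise_cosines(prof)
  res$eri <- mean(res$pairwise$cosine)
  all_meals <- unlist(days, use.names = FALSE)
  all_meals <- all_meals[!is.na(all_meals)]
  res$mean_meals_per_day <- length(all_meals) / length(days)
  res$daytime_meal_ratio <- mean(all_meals >= 420 & all_meals < 1140)
  res
}

#' @export
print.eri_result <- function(x, ...) {
  if (x$excluded) {
    cat("ERI: excluded (", x$exclude_reason, ")\n", sep = "")
  } else {
    cat(sprintf("ERI = %.4f over %d days (%d pairs); %.1f meals/day, %.0f%% daytime\n",
                x$eri, x$n_days_used, nrow(x$pairwise),
                x$mean_meals_per_day, 100 * x$daytime_meal_ratio))
  }
  invisible(x)
}

#' Eating Regularity Index for a whole diary cohort
#'
#' Applies [compute_eri()] to every subject-assessment of a long-format diary
#' table, as produced by [read_meal_diary()] or [simulate_diaries()].
#'
#' @param diary Data frame with columns \code{subject_id}, \code{age_months},
#'   \code{day}, \code{meal_min} (NA meal_min marks a recorded zero-meal day).
#' @inheritParams compute_eri
#' @return Data frame with one row per subject-assessment: \code{subject_id},
#'   \code{age_months}, \code{eri}, \code{n_days_used}, \code{n_days_dropped},
#'   \code{mean_meals_per_day}, \code{daytime_meal_ratio}, \code{excluded},
#'   \code{exclude_reason}.
#' @export
compute_eri_cohort <- function(diary, k = 4, epoch_minutes = 15, min_days = 5) {
  check_diary(diary)
  key <- interaction(diary$subject_id, diary$age_months, drop = TRUE, sep = "\r")
  out <- lapply(split(diary, key), function(d) {
    days <- split(d$meal_min, d$day)
    r <- compute_eri(days, k = k, epoch_minutes = epoch_minutes,
                     min_days = min_days)
    data.frame(subject_id = d$subject_id[1L], age_months = d$age_months[1L],
               eri = r$eri, n_days_used = r$n_days_used,
               n_days_dropped = r$n_days_dropped,
               mean_meals_per_day = r$mean_meals_per_day,
               daytime_meal_ratio = r$daytime_meal_ratio,
               excluded = r$excluded, exclude_reason = r$exclude_reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$subject_id, out$age_months), , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_diary <- function(diary) {
  need <- c("subject_id", "age_months", "day", "meal_min")
  miss <- setdiff(need, names(diary))
  if (length(miss)) {
    stop("diary is missing required column(s): ", paste(miss, collapse = ", "))
  }
  invisible(diary)
}

#' Select the SMA kernel width by between-subject ERI variability
#'
#' For every candidate kernel width the ERI is computed for all included
#' subjects, and the between-subject standard deviation of the ERI is taken
#' within each age group. The chosen width is the candidate that attains the
#' maximal SD in the largest number of age groups; ties go to the smallest
#' width. The full SD table is returned for inspection, mirroring the
#' diagnostic used to fix the default width of 4 epochs (1 h).
#'
#' @param diary Long-format diary table (see [compute_eri_cohort()]).
#' @param candidate_ks Integer vector of candidate kernel widths.
#' @inheritParams compute_eri
#' @return List of class \code{"sma_selection"}: \code{table} (data frame
#'   age_months x k x sd_eri x n_subjects), \code{wins_by_k}, \code{chosen_k}.
#' @export
select_sma_interval <- function(diary, candidate_ks = 1:10, epoch_minutes = 15,
                                min_days = 5) {
  if (!length(candidate_ks)) stop("candidate_ks must be non-empty")
  candidate_ks <- sort(unique(as.integer(candidate_ks)))
  tabs <- lapply(candidate_ks, function(k) {
    res <- compute_eri_cohort(diary, k = k, epoch_minutes = epoch_minutes,
                              min_days = min_days)
    res <- res[!res$excluded, , drop = FALSE]
    sds <- tapply(res$eri, res$age_months, stats::sd)
    data.frame(age_months = as.numeric(names(sds)), k = k,
               sd_eri = as.numeric(sds),
               n_subjects = as.integer(table(res$age_months)),
               row.names = NULL)
  })
  tab <- do.call(rbind, tabs)
  ages <- unique(tab$age_months)
  if (any(tapply(tab$n_subjects, tab$age_months, max) < 2)) {
    stop("need at least 2 included subjects per age group")
  }
  # winner per age group = smallest k attaining the maximal SD
  winners <- vapply(ages, function(a) {
    sub <- tab[tab$age_months == a, ]
    sub$k[which.max(sub$sd_eri)]
  }, numeric(1))
  wins <- table(factor(winners, levels = candidate_ks))
  chosen <- candidate_ks[which.max(wins)]   # ties -> smallest k (first max)
  structure(list(table = tab,
                 wins_by_k = wins,
                 chosen_k = as.integer(chosen)),
            class = "sma_selection")
}

#' @export
print.sma_selection <- function(x, ...) {
  cat("SMA kernel-width selection (between-subject SD of ERI)\n")
  cat("chosen k =", x$chosen_k, "\n")
  print(stats::xtabs(sd_eri ~ age_months + k, data = x$table))
  invisible(x)
}
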