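# Readers and writers for all tabular inputs: meal diaries, sleep composites,
# covariates, taxa count tables and newick phylogenies. Readers validate
# strictly and reject rather than coerce; every accepted file round-trips.

fmt_hhmm <- function(min) sprintf("%02d:%02d", min %/% 60, min %% 60)

#' Read a meal-time diary CSV
#'
#' Expects columns \code{subject_id}, \code{age_months}, \code{date},
#' \code{meal_start} (\code{HH:MM} clock time; empty for a recorded day with
#' no meals). Times are floored to the epoch grid (an event within an epoch
#' belongs to that epoch), duplicate (subject, date, epoch) records are
#' collapsed, and day indices follow the order dates first appear within each
#' subject-assessment (dates are labels only). Malformed rows abort the read
#' with their line numbers listed.
#'
#' @param path CSV file path.
#' @param epoch_minutes Epoch width in minutes (default 15).
#' @return Long diary data frame: \code{subject_id}, \code{age_months},
#'   \code{day}, \code{date}, \code{meal_min} (NA marks a zero-meal day).
#' @export
read_meal_diary <- function(path, epoch_minutes = 15) {
  epochs_per_day(epoch_minutes)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("subject_id", "age_months", "date", "meal_start")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("diary file is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  age <- suppressWarnings(as.numeric(tab$age_months))
  problems <- character()
  if (any(is.na(age))) {
    problems <- c(problems, sprintf("line %d: unparseable age_months '%s'",
                                    which(is.na(age)) + 1L,
                                    tab$age_months[is.na(age)]))
  }
  ms <- trimws(tab$meal_start)
  meal_min <- rep(NA_real_, nrow(tab))
  has_time <- !is.na(ms) & nzchar(ms)
  ok <- grepl("^[0-9]{1,2}:[0-9]{2}$", ms[has_time])
  hh <- suppressWarnings(as.numeric(sub(":.*", "", ms[has_time])))
  mm <- suppressWarnings(as.numeric(sub(".*:", "", ms[has_time])))
  valid <- ok & !is.na(hh) & !is.na(mm) & hh < 24 & mm < 60
  if (any(!valid)) {
    bad <- which(has_time)[!valid]
    problems <- c(problems, sprintf(
      "line %d: unparseable or out-of-range time '%s'", bad + 1L, ms[bad]))
  }
  if (length(problems)) {
    stop("malformed diary rows:\n  ", paste(problems, collapse = "\n  "))
  }
  meal_min[has_time] <- floor((hh * 60 + mm) / epoch_minutes) * epoch_minutes
  out <- data.frame(subject_id = tab$subject_id, age_months = age,
                    date = tab$date, meal_min = meal_min,
                    stringsAsFactors = FALSE)
  # collapse duplicate (subject, assessment, date, epoch) records
  key <- paste(out$subject_id, out$age_months, out$date, out$meal_min,
               is.na(out$meal_min), sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  # day index = order of first appearance of date within subject-assessment
  grp <- paste(out$subject_id, out$age_months, sep = "\r")
  out$day <- unsplit(lapply(split(out$date, grp), function(d) {
    match(d, unique(d))
  }), grp)
  out <- out[order(out$subject_id, out$age_months, out$day, out$meal_min), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("subject_id", "age_months", "day", "date", "meal_min")]
}

#' Write a meal-time diary CSV
#'
#' Counterpart of [read_meal_diary()]; times are written back as
#' \code{HH:MM}, zero-meal days as empty \code{meal_start}.
#'
#' @param diary Long diary data frame (with a \code{date} column, or one is
#'   synthesized from the day index).
#' @param path Output path.
#' @export
write_meal_diary <- function(diary, path) {
  check_diary(diary)
  date <- if ("date" %in% names(diary)) diary$date else
    sprintf("day%02d", diary$day)
  utils::write.csv(data.frame(
    subject_id = diary$subject_id, age_months = diary$age_months,
    date = date,
    meal_start = ifelse(is.na(diary$meal_min), "", fmt_hhmm(diary$meal_min)),
    stringsAsFactors = FALSE), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_numeric_cols <- function(tab, cols, what) {
  miss <- setdiff(cols, names(tab))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
  for (cl in cols) {
    v <- tab[[cl]]
    if (!is.numeric(v) || anyNA(v)) {
      stop(what, " column '", cl, "' must be numeric without missing values")
    }
  }
  invisible(tab)
}

sleep_composite_names <- function() {
  c("SleepActivity", "SleepDay", "SleepNight", "SleepTiming",
    "SleepVariability")
}

#' Read a sleep-composite table CSV
#'
#' One row per subject-assessment with all five composites
#' (\code{SleepActivity}, \code{SleepDay}, \code{SleepNight},
#' \code{SleepTiming}, \code{SleepVariability}), all numeric and complete.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_composites <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_numeric_cols(tab, c("age_months", sleep_composite_names()),
                     "composite table")
  if (!"subject_id" %in% names(tab)) {
    stop("composite table is missing required column(s): subject_id")
  }
  tab
}

#' Read a covariate table CSV
#'
#' One row per subject-assessment with \code{sex} (0 male / 1 female),
#' \code{exact_age} (fractional months), \code{breastfeeding} (0/1) and the
#' parental \code{structure_score}.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_covariates <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_numeric_cols(tab, c("age_months", "sex", "exact_age",
                            "breastfeeding", "structure_score"),
                     "covariate table")
  if (!"subject_id" %in% names(tab)) {
    stop("covariate table is missing required column(s): subject_id")
  }
  for (cl in c("sex", "breastfeeding")) {
    if (!all(tab[[cl]] %in% c(0, 1))) {
      stop("covariate column '", cl, "' must be coded 0/1")
    }
  }
  tab
}

#' @rdname read_composites
#' @param tab Table to write.
#' @export
write_composites <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_covariates
#' @param tab Table to write.
#' @export
write_covariates <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a taxa count table (TSV)
#'
#' Tab-separated, first column \code{taxon} (rank-annotated labels), one
#' column per sample, non-negative integer counts. Samples whose counts sum
#' to zero are rejected by name.
#'
#' @param path TSV file path.
#' @return Integer matrix, taxa x samples, taxon labels as rownames.
#' @export
read_taxa_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1L] != "taxon") {
    stop("taxa table must have 'taxon' as its first column")
  }
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(counts) <- tab$taxon
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("taxa counts must be non-negative integers without missing values")
  }
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop("taxa table has zero-sum sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Write a taxa count table (TSV)
#'
#' Counterpart of [read_taxa_table()]; a write/read round trip reproduces the
#' matrix exactly.
#'
#' @param counts Integer matrix, taxa x samples.
#' @param path Output path.
#' @export
write_taxa_table <- function(counts, path) {
  tab <- data.frame(taxon = rownames(counts), counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a newick phylogeny for UniFrac
#'
#' Branch lengths are mandatory (UniFrac is length-weighted); if
#' \code{taxa} labels are supplied, any taxon absent from the tree tips is a
#' fatal error listing the mismatches.
#'
#' @param path Newick file path.
#' @param taxa Optional character vector of taxon labels that must be tips.
#' @return An \code{ape::phylo} object.
#' @export
read_tree <- function(path, taxa = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick tree: ", path)
  validate_tree(tree, taxa)
}

validate_tree <- function(tree, taxa = NULL) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    bad <- if (is.null(tree$edge.length)) "all edges" else
      paste(which(is.na(tree$edge.length)), collapse = ", ")
    stop("tree is missing branch length(s) on edge(s): ", bad)
  }
  if (!is.null(taxa)) {
    missing_tips <- setdiff(taxa, tree$tip.label)
    if (length(missing_tips)) {
      stop("taxa absent from tree tips: ",
           paste(missing_tips, collapse = ", "))
    }
  }
  tree
}
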