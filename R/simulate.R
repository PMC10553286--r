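# Synthetic cohort generator: meal diaries, sleep composites + covariates,
# and age-structured stool microbiota with known ground truth.

#' Simulate meal diaries for a synthetic cohort
#'
#' Each subject receives a latent trait regularity \code{r ~ Beta(r_shape)};
#' the regularity realized at each assessment is
#' \code{r_age = r + r_age_offsets[age] + N(0, r_age_sd)} (clamped to
#' (0, 1)), encoding the developmental increase of eating regularity with
#' individually varying pace. Per assessment, a template schedule of meal
#' clock times is drawn; every diary day perturbs the template with Gaussian
#' timing jitter whose SD is \code{regularity_jitter_map(r_age)},
#' independently drops each template meal with \code{meal_drop_prob} and
#' adds an extra meal with \code{meal_add_prob}; times are wrapped modulo
#' 24 h and floored to the epoch grid. Each subject draws from its own
#' seeded random stream.
#'
#' @param config A [cohort_config()].
#' @return List with \code{diary} (long data frame: \code{subject_id},
#'   \code{age_months}, \code{day}, \code{meal_min}; zero-meal days keep one
#'   row with \code{meal_min = NA}) and \code{truth} (one row per
#'   subject-assessment: trait \code{r}, realized \code{r_age}, jitter SD;
#'   simulation bookkeeping, never an analysis input).
#' @export
simulate_diaries <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ages <- config$ages_months
  subj <- sprintf("S%03d", seq_len(config$n_subjects))
  per_subject <- lapply(seq_len(config$n_subjects), function(i) {
    set.seed(subject_seed(config, i, "diary"))
    r <- stats::rbeta(1, config$r_shape[1], config$r_shape[2])
    r_age <- vapply(ages, function(a) {
      min(max(r + config$r_age_offsets[[as.character(a)]] +
                stats::rnorm(1, 0, config$r_age_sd), 0.02), 0.98)
    }, numeric(1))
    sd_jit <- config$regularity_jitter_map(r_age)
    age_v <- numeric(0); day_v <- integer(0); meal_v <- numeric(0)
    for (k_age in seq_along(ages)) {
      a <- ages[k_age]
      mu <- config$meals_per_day_by_age[[as.character(a)]]
      n_tpl <- max(1L, round(stats::rnorm(1, mu, 1)))
      # template: mostly daytime meals, some at night (young infants feed
      # around the clock; the daytime weight leaves room for night feeds)
      day_meal <- stats::runif(n_tpl) < 0.7
      tpl <- ifelse(day_meal, stats::runif(n_tpl, 420, 1140),
                    stats::runif(n_tpl, 0, 1440) %% 1440)
      tpl <- sort(tpl)
      for (d in seq_len(config$days_per_assessment)) {
        keep <- stats::runif(n_tpl) >= config$meal_drop_prob
        times <- tpl[keep]
        if (length(times)) {
          times <- times + stats::rnorm(length(times), 0, sd_jit[k_age])
        }
        if (stats::runif(1) < config$meal_add_prob) {
          times <- c(times, stats::runif(1, 0, 1440))
        }
        times <- floor((times %% 1440) / config$epoch_minutes) *
          config$epoch_minutes
        times <- sort(unique(times))
        if (!length(times)) times <- NA_real_   # recorded zero-meal day
        age_v <- c(age_v, rep(a, length(times)))
        day_v <- c(day_v, rep(d, length(times)))
        meal_v <- c(meal_v, times)
      }
    }
    list(diary = data.frame(subject_id = subj[i], age_months = age_v,
                            day = day_v, meal_min = meal_v,
                            stringsAsFactors = FALSE),
         truth = data.frame(subject_id = subj[i], age_months = ages,
                            r = r, r_age = r_age, jitter_sd = sd_jit,
                            stringsAsFactors = FALSE))
  })
  diary <- do.call(rbind, lapply(per_subject, `[[`, "diary"))
  truth <- do.call(rbind, lapply(per_subject, `[[`, "truth"))
  rownames(diary) <- rownames(truth) <- NULL
  list(diary = diary, truth = truth)
}

#' Simulate sleep composites and covariates
#'
#' Generates the five sleep composites and the covariate table for every
#' subject-assessment. Each composite follows
#' \code{y = b r_age + c age + u_subject + e}, with \code{b} from
#' \code{effect_sizes} acting on the regularity realized at that assessment,
#' subject random intercept \code{u ~ N(0, sd_intercept^2)} and residual
#' \code{e ~ N(0, sd_resid^2)}. Sex is Bernoulli(0.5) per subject;
#' breastfeeding is 1 for everyone at 3 months and Bernoulli per
#' \code{breastfeeding_prob} later; the parental Structure score is a
#' subject-level Likert-type score correlated with trait regularity at
#' strength \code{structure_cor}.
#'
#' Under \code{mediation_mode != "none"} the designated composite is driven
#' (fully or partially) by the realized microbiota marker instead of by
#' \code{r} directly: pass the per-assessment marker values via
#' \code{mediator} (as [simulate_cohort()] does with the standardized
#' realized Shannon index, itself generated from \code{r} by
#' [simulate_microbiota()]).
#'
#' @param truth Assessment-level truth table from [simulate_diaries()].
#' @param config The same [cohort_config()].
#' @param mediator Data frame \code{subject_id}, \code{age_months},
#'   \code{mediator} with the realized marker driving the designated
#'   composite; required when \code{mediation_mode != "none"}.
#' @return List with \code{sleep} (one row per subject-assessment: covariates
#'   plus the five composites) and \code{truth} (input truth extended with
#'   subject random intercepts).
#' @export
simulate_sleep_and_covariates <- function(truth, config, mediator = NULL) {
  stopifnot(inherits(config, "cohort_config"), is.data.frame(truth),
            all(c("subject_id", "age_months", "r", "r_age") %in%
                  names(truth)))
  if (config$mediation_mode != "none" && is.null(mediator)) {
    stop("mediation_mode '", config$mediation_mode, "' needs the realized ",
         "marker: pass 'mediator' or use simulate_cohort()")
  }
  ages <- config$ages_months
  comps <- names(config$effect_sizes)
  subjects <- unique(truth$subject_id)
  rows <- vector("list", length(subjects))
  u_tab <- numeric(length(subjects))
  med_lookup <- function(s, a) {
    if (is.null(mediator)) return(0)
    v <- mediator$mediator[mediator$subject_id == s &
                             mediator$age_months == a]
    if (!length(v)) 0 else v[1L]
  }
  for (i in seq_along(subjects)) {
    set.seed(subject_seed(config, i, "sleep"))
    sub_tr <- truth[truth$subject_id == subjects[i], , drop = FALSE]
    r <- sub_tr$r[1L]
    u <- stats::rnorm(1, 0, config$sd_intercept)
    u_tab[i] <- u
    sex <- stats::rbinom(1, 1, 0.5)
    ab <- config$r_shape
    mu_r <- ab[1] / sum(ab)
    sd_r <- sqrt(prod(ab) / (sum(ab)^2 * (sum(ab) + 1)))
    struct_z <- config$structure_cor * (r - mu_r) / sd_r +
      sqrt(1 - config$structure_cor^2) * stats::rnorm(1)
    structure_score <- 3 + 0.5 * struct_z
    subj_rows <- lapply(seq_along(ages), function(k) {
      a <- ages[k]
      r_a <- sub_tr$r_age[sub_tr$age_months == a][1L]
      exact_age <- a + stats::rnorm(1, 0, 0.25)
      bf_p <- if (k == 1L) 1 else config$breastfeeding_prob[[as.character(a)]]
      bf <- stats::rbinom(1, 1, bf_p)
      m <- med_lookup(subjects[i], a)
      y <- vapply(comps, function(cm) {
        b <- config$effect_sizes[[cm]]
        base <- config$age_slope * exact_age + u +
          stats::rnorm(1, 0, config$sd_resid)
        if (cm == config$med_composite && config$mediation_mode == "full") {
          base + config$med_b * m
        } else if (cm == config$med_composite &&
                   config$mediation_mode == "partial") {
          base + 0.5 * b * r_a + config$med_b * m
        } else {
          base + b * r_a
        }
      }, numeric(1))
      cbind(data.frame(subject_id = subjects[i], age_months = a,
                       sex = sex, exact_age = exact_age, breastfeeding = bf,
                       structure_score = structure_score,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(y)))
    })
    rows[[i]] <- do.call(rbind, subj_rows)
  }
  sleep <- do.call(rbind, rows)
  rownames(sleep) <- NULL
  truth$intercept <- u_tab[match(truth$subject_id, subjects)]
  list(sleep = sleep, truth = truth)
}

#' Reference genus set of the simulated infant gut community
#'
#' Twenty-two genera across five phyla with two base compositions: an early
#' Bifidobacterium-dominated profile (enterotype A) and a later
#' Bacteroides-dominated profile (enterotype B). Taxon labels carry
#' kingdom/phylum/genus rank annotations
#' (\code{k__...|p__...|g__...}; pipe-separated so labels stay legal newick
#' tip names).
#'
#' @return Data frame with columns \code{taxon}, \code{phylum}, \code{genus},
#'   \code{base_A}, \code{base_B} (each base column sums to 1).
#' @export
taxa_reference <- function() {
  g <- c("Bifidobacterium", "Collinsella", "Eggerthella",
         "Bacteroides", "Prevotella", "Parabacteroides", "Alistipes",
         "Faecalibacterium", "Blautia", "Ruminococcus", "Clostridium",
         "Lactobacillus", "Streptococcus", "Veillonella", "Roseburia",
         "Dorea", "Eubacterium",
         "Escherichia", "Klebsiella", "Enterobacter", "Haemophilus",
         "Akkermansia")
  p <- c(rep("Actinobacteria", 3), rep("Bacteroidetes", 4),
         rep("Firmicutes", 10), rep("Proteobacteria", 4), "Verrucomicrobia")
  base_A <- c(40, 4, 1,   5, 0.5, 1, 0.5,   1, 4, 1, 4, 5, 6, 6, 0.5, 1, 1,
              8, 4, 2, 1.5,   0.5)
  base_B <- c(8, 2, 0.5,   30, 6, 5, 4,   10, 7, 6, 3, 1, 2, 2, 4, 2, 3,
              2, 1, 0.5, 0.5,   1.5)
  data.frame(taxon = sprintf("k__Bacteria|p__%s|g__%s", p, g),
             phylum = p, genus = g,
             base_A = base_A / sum(base_A), base_B = base_B / sum(base_B),
             stringsAsFactors = FALSE)
}

#' Phylum-structured phylogeny over the reference genera
#'
#' Builds a fixed rooted tree with genera grouped under their phylum
#' (within-phylum polytomies), genus tip branches of length 0.2 and phylum
#' stem branches of length 0.8, for weighted UniFrac computation. Phylum
#' clades are joined pairwise through zero-length internal branches so the
#' root is strictly binary (a rooted tree in the \pkg{ape} sense; normalized
#' weighted UniFrac depends on the root position, so the root is fixed here
#' rather than left to downstream tools).
#'
#' @param taxa Data frame as from [taxa_reference()].
#' @return An \code{ape::phylo} tree whose tip labels are the taxon labels.
#' @export
taxa_tree <- function(taxa = taxa_reference()) {
  clades <- vapply(split(taxa$taxon, taxa$phylum), function(tips) {
    if (length(tips) == 1L) return(sprintf("%s:1.0", tips))
    sprintf("(%s):0.8", paste(sprintf("%s:0.2", tips), collapse = ","))
  }, character(1))
  nested <- Reduce(function(a, b) sprintf("(%s,%s):0", a, b), clades)
  ape::read.tree(text = sprintf("%s;", nested))
}

# Dirichlet draws as normalized independent gammas; rows are samples.
rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate stool microbiota count tables
#'
#' Each subject-assessment sample mixes one of two latent enterotype base
#' compositions (Bifidobacterium-rich A vs Bacteroides-rich B, with P(B)
#' rising with age) and draws counts Dirichlet-multinomially. The Dirichlet
#' precision rises with age (\code{concentration_by_age}), producing richer
#' and more even communities, and is additionally modulated by a latent
#' per-assessment mediator \code{m} through \code{exp(1.5 m)}: under
#' \code{mediation_mode "full"} or \code{"partial"},
#' \code{m = med_a r_age + N(0, 0.5)} carries the regularity signal into
#' realized alpha diversity; under \code{"none"}, \code{m ~ N(0, 1)} is
#' independent of regularity (marker variation without mediation).
#'
#' @param truth Assessment-level truth table from [simulate_diaries()].
#' @param config The same [cohort_config()].
#' @return List with \code{counts} (integer matrix, taxa x samples),
#'   \code{meta} (sample_id, subject_id, age_months), \code{tree}
#'   (phylum-structured phylogeny) and \code{truth} (input truth extended
#'   with the latent mediator and enterotype membership).
#' @export
simulate_microbiota <- function(truth, config) {
  stopifnot(inherits(config, "cohort_config"), is.data.frame(truth))
  taxa <- taxa_reference()
  subjects <- unique(truth$subject_id)
  ages <- config$ages_months
  out_counts <- list(); out_meta <- list(); out_truth <- list()
  for (i in seq_along(subjects)) {
    set.seed(subject_seed(config, i, "microbiota"))
    for (a in ages) {
      r <- truth$r_age[truth$subject_id == subjects[i] &
                         truth$age_months == a][1L]
      m <- if (config$mediation_mode == "none") stats::rnorm(1) else
        config$med_a * r + stats::rnorm(1, 0, 0.5)
      # centre the mediator so the precision multiplier averages ~1 and the
      # age-specific baseline concentration keeps its meaning
      m_c <- m - if (config$mediation_mode == "none") 0 else
        config$med_a * config$r_shape[1] / sum(config$r_shape)
      p_b <- config$enterotype_b_prob[[as.character(a)]]
      etype <- if (stats::runif(1) < p_b) "B" else "A"
      base <- if (etype == "A") taxa$base_A else taxa$base_B
      conc <- config$concentration_by_age[[as.character(a)]] * exp(1.5 * m_c)
      prop <- rdirichlet(1, conc * base)[1, ]
      counts <- stats::rmultinom(1, size = config$depth, prob = prop)[, 1]
      sid <- sprintf("%s_m%02d", subjects[i], a)
      out_counts[[sid]] <- counts
      out_meta[[sid]] <- data.frame(sample_id = sid,
                                    subject_id = subjects[i], age_months = a,
                                    stringsAsFactors = FALSE)
      out_truth[[sid]] <- data.frame(sample_id = sid,
                                     subject_id = subjects[i],
                                     age_months = a, mediator = m,
                                     enterotype = etype,
                                     concentration = conc,
                                     stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, out_counts)
  rownames(counts) <- taxa$taxon
  meta <- do.call(rbind, out_meta)
  rownames(meta) <- NULL
  samples <- do.call(rbind, out_truth)
  rownames(samples) <- NULL
  truth <- merge(truth, samples, by = c("subject_id", "age_months"),
                 sort = FALSE)
  list(counts = counts, meta = meta, tree = taxa_tree(taxa), truth = truth)
}

#' Simulate a complete synthetic cohort
#'
#' Runs [simulate_diaries()], [simulate_microbiota()] and
#' [simulate_sleep_and_covariates()] in order and returns all pieces with
#' the accumulated ground truth. Under a mediated configuration the
#' standardized realized Shannon index of the simulated samples is the
#' marker passed into the sleep stage, so the designated composite is
#' generated from the marker an analyst can actually measure.
#'
#' @param config A [cohort_config()].
#' @return List with \code{diary}, \code{sleep}, \code{counts}, \code{meta},
#'   \code{tree}, \code{truth}, \code{config}.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  d <- simulate_diaries(config)
  m <- simulate_microbiota(d$truth, config)
  mediator <- NULL
  if (config$mediation_mode != "none") {
    sh <- alpha_diversity(m$counts)$shannon
    mediator <- data.frame(subject_id = m$meta$subject_id,
                           age_months = m$meta$age_months,
                           mediator = as.numeric(scale(sh)),
                           stringsAsFactors = FALSE)
  }
  s <- simulate_sleep_and_covariates(d$truth, config, mediator = mediator)
  truth <- merge(m$truth,
                 s$truth[, c("subject_id", "age_months", "intercept")],
                 by = c("subject_id", "age_months"), sort = FALSE)
  truth <- truth[order(truth$subject_id, truth$age_months), ]
  rownames(truth) <- NULL
  list(diary = d$diary, sleep = s$sleep, counts = m$counts, meta = m$meta,
       tree = m$tree, truth = truth, config = config)
}
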