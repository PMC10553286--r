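# Gut-microbiota maturation markers: alpha diversity, weighted UniFrac,
# enterotypes (k-medoids + Calinski-Harabasz + prediction strength), a
# random-forest bacterial maturation index, and phylum-level abundances.

#' Alpha diversity per sample
#'
#' Observed species (taxa with count > 0), Shannon entropy (natural log,
#' computed on relative abundances) and the bias-corrected Chao1 estimator
#' \code{S_obs + F1 (F1 - 1) / (2 (F2 + 1))} with \code{F1}/\code{F2} the
#' singleton/doubleton counts (defined even when no doubletons occur).
#'
#' @param counts Non-negative integer matrix, taxa x samples (a vector is
#'   treated as one sample). Every sample must have a positive total.
#' @return Data frame with \code{sample_id}, \code{observed}, \code{shannon},
#'   \code{chao1}.
#' @export
alpha_diversity <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1,
                                             dimnames = list(NULL, "sample1"))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  }
  x <- t(counts)                       # vegan wants samples as rows
  est <- vegan::estimateR(round(x))    # S.obs and bias-corrected S.chao1
  data.frame(sample_id = colnames(counts),
             observed = as.integer(est["S.obs", ]),
             shannon = as.numeric(vegan::diversity(x, index = "shannon")),
             chao1 = as.numeric(est["S.chao1", ]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Normalized weighted UniFrac distances
#'
#' Abundance-weighted, branch-length-weighted distance between communities:
#' \code{sum_l b_l |A_l - B_l| / sum_l b_l (A_l + B_l)} over branches
#' \code{l}, where \code{A_l}, \code{B_l} are the relative abundances
#' descending from branch \code{l}. Zero iff two samples have identical
#' relative composition; 1 for fully disjoint communities.
#'
#' The normalized form depends on the root position, so unrooted trees are
#' rooted deterministically at their first tip rather than left to a random
#' choice downstream.
#'
#' @param counts Taxa x samples count matrix; rownames must match tree tips.
#' @param tree \code{phylo} tree with branch lengths covering every taxon
#'   with a nonzero count.
#' @return A \code{dist} object over samples.
#' @export
weighted_unifrac <- function(counts, tree) {
  present <- rownames(counts)[rowSums(counts) > 0]
  validate_tree(tree, present)
  if (!ape::is.rooted(tree)) {
    tree <- ape::root(tree, outgroup = tree$tip.label[1L],
                      resolve.root = TRUE)
  }
  # resolve polytomies with zero-length edges (value-preserving): the
  # underlying fast UniFrac implementation assumes a binary tree
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  otu <- phyloseq::otu_table(counts, taxa_are_rows = TRUE)
  ps <- phyloseq::phyloseq(otu, phyloseq::phy_tree(tree))
  phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE)
}

# Calinski-Harabasz pseudo-F from a distance matrix and hard labels, using
# the squared-distance decomposition (no coordinates needed):
#   SS_within(C) = sum_{i<j in C} d_ij^2 / |C|,  SS_total analogous.
ch_index <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  k <- length(unique(labels))
  tot <- sum(d^2) / (2 * n)
  w <- sum(vapply(unique(labels), function(cl) {
    idx <- labels == cl
    sum(d[idx, idx]^2) / (2 * sum(idx))
  }, numeric(1)))
  b <- tot - w
  if (w <= .Machine$double.eps) return(Inf)
  (b / (k - 1)) / (w / (n - k))
}

# Tibshirani-Walther prediction strength for k = 2 with one seeded 2-fold
# split, averaged over the two train/test directions. For each test sample
# pair co-clustered in the test clustering, check whether the train-medoid
# assignment also co-clusters them; return the worst cluster's agreement.
prediction_strength_k2 <- function(d, seed) {
  d <- as.matrix(d)
  n <- nrow(d)
  set.seed(seed)
  fold <- sample(rep(1:2, length.out = n))
  ps_dir <- vapply(1:2, function(test_f) {
    test <- which(fold == test_f); train <- which(fold != test_f)
    if (length(test) < 4 || length(train) < 2) return(NA_real_)
    cl_test <- cluster::pam(stats::as.dist(d[test, test]), k = 2,
                            diss = TRUE, cluster.only = TRUE)
    med_train <- cluster::pam(stats::as.dist(d[train, train]), k = 2,
                              diss = TRUE)$id.med
    dm <- d[test, train[med_train], drop = FALSE]
    # break exact ties at chance (seeded); negligible against real distances
    dm <- dm + matrix(stats::runif(length(dm), 0, 1e-9), nrow(dm))
    assigned <- apply(dm, 1, which.min)
    min(vapply(1:2, function(cl) {
      idx <- which(cl_test == cl)
      if (length(idx) < 2) return(1)
      pairs <- utils::combn(idx, 2)
      mean(assigned[pairs[1, ]] == assigned[pairs[2, ]])
    }, numeric(1)))
  }, numeric(1))
  mean(ps_dir, na.rm = TRUE)
}

#' Enterotype samples by 2-cluster k-medoids
#'
#' Partitions samples into two enterotypes by k-medoids (deterministic
#' BUILD+SWAP) on a community distance matrix (typically weighted UniFrac),
#' scores the partition with the Calinski-Harabasz pseudo-F and a seeded
#' 2-fold prediction strength, and labels the cluster with the higher mean
#' Bifidobacterium relative abundance as enterotype A (Bifidobacterium-rich),
#' the other as B (Bacteroides-rich). Partitions with prediction strength
#' below 0.8 (the usual stability threshold) are flagged non-separable.
#'
#' @param d Symmetric distance matrix or \code{dist} over at least 4 samples.
#' @param counts Taxa x samples count matrix used for the A/B labelling; the
#'   Bifidobacterium taxon is found by matching \code{g__Bifidobacterium} (or
#'   the literal genus name) in the rownames.
#' @param seed Seed for the prediction-strength fold split.
#' @return List of class \code{"enterotype"}: \code{assignment} (data frame
#'   sample_id / cluster A|B), \code{ch_index}, \code{prediction_strength},
#'   \code{separable}, \code{medoids}.
#' @export
enterotype <- function(d, counts, seed = 1) {
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-8)) {
    stop("distance matrix must be square and symmetric")
  }
  if (nrow(dm) < 4) stop("enterotyping needs at least 4 samples")
  samples <- rownames(dm)
  if (is.null(samples)) samples <- colnames(counts)
  fit <- cluster::pam(stats::as.dist(dm), k = 2, diss = TRUE)
  lab <- fit$clustering
  bif <- grep("g__Bifidobacterium|^Bifidobacterium$", rownames(counts))
  if (!length(bif)) stop("no Bifidobacterium taxon found for A/B labelling")
  rel_bif <- colSums(counts[bif, samples, drop = FALSE]) /
    colSums(counts[, samples, drop = FALSE])
  mean_bif <- tapply(rel_bif, lab, mean)
  a_cluster <- as.integer(names(which.max(mean_bif)))
  cluster_ab <- ifelse(lab == a_cluster, "A", "B")
  ps <- prediction_strength_k2(dm, seed)
  structure(list(
    assignment = data.frame(sample_id = samples, cluster = cluster_ab,
                            row.names = NULL, stringsAsFactors = FALSE),
    ch_index = ch_index(dm, lab),
    prediction_strength = ps,
    separable = is.finite(ps) && ps >= 0.8,
    medoids = samples[fit$id.med]), class = "enterotype")
}

#' @export
print.enterotype <- function(x, ...) {
  cat(sprintf("enterotypes: %d A (Bifidobacterium-rich), %d B (Bacteroides-rich)\n",
              sum(x$assignment$cluster == "A"),
              sum(x$assignment$cluster == "B")))
  cat(sprintf("Calinski-Harabasz = %.2f, prediction strength = %.2f (%s)\n",
              x$ch_index, x$prediction_strength,
              if (x$separable) "separable" else "non-separable"))
  invisible(x)
}

# Collapse taxa counts to genus level using g__ annotations (taxa without a
# genus annotation keep their full label).
genus_collapse <- function(counts) {
  genus <- sub(".*g__", "g__", rownames(counts))
  rowsum(counts, group = genus)
}

#' Bacterial maturation index by random-forest age regression
#'
#' Regresses chronological age on genus-level relative abundances with a
#' random forest; the microbiota-predicted age of each training sample is its
#' out-of-bag prediction (no leakage), and the maturation index is
#' \code{predicted - actual} age: positive values mark a comparably more
#' mature bacterial profile than expected for the infant's age.
#'
#' @param counts Taxa x samples count matrix.
#' @param ages Numeric vector of chronological ages (months), one per sample,
#'   spanning at least two distinct ages.
#' @param n_trees Number of trees (default 500).
#' @param seed RNG seed; predictions are deterministic given it.
#' @return Data frame with \code{sample_id}, \code{predicted_age},
#'   \code{actual_age}, \code{index}; attribute \code{"oob_r2"} holds the
#'   out-of-bag R-squared.
#' @export
maturation_index <- function(counts, ages, n_trees = 500, seed = 1) {
  if (length(ages) != ncol(counts)) {
    stop("ages must have one entry per sample")
  }
  if (length(unique(ages)) < 2) {
    stop("maturation index needs samples from at least two ages")
  }
  rel <- t(genus_collapse(counts))
  rel <- rel / rowSums(rel)
  colnames(rel) <- make.names(colnames(rel))
  set.seed(seed)
  rf <- suppressWarnings(   # few distinct ages is the expected design
    randomForest::randomForest(x = rel, y = ages, ntree = n_trees))
  pred <- as.numeric(rf$predicted)          # out-of-bag predictions
  sample_id <- colnames(counts) %||% paste0("sample", seq_along(ages))
  out <- data.frame(sample_id = sample_id, predicted_age = pred,
                    actual_age = ages, index = pred - ages,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "oob_r2") <- 1 - sum((pred - ages)^2) / sum((ages - mean(ages))^2)
  out
}

#' Phylum-level relative abundances
#'
#' Sums counts within each phylum (parsed from \code{p__} annotations in the
#' taxon labels; unannotated taxa are routed to \code{"other"} with a
#' warning) and normalizes per sample.
#'
#' @param counts Taxa x samples count matrix with rank-annotated rownames.
#' @return Numeric matrix, phyla x samples, columns summing to 1.
#' @export
phylum_collapse <- function(counts) {
  phylum <- rep("other", nrow(counts))
  has <- grepl("p__", rownames(counts))
  phylum[has] <- sub("^p__", "", regmatches(rownames(counts),
                                            regexpr("p__[A-Za-z0-9_]+",
                                                    rownames(counts))))
  if (any(!has)) {
    warning(sum(!has), " taxa without phylum annotation routed to 'other'")
  }
  agg <- rowsum(counts, group = phylum)
  sweep(agg, 2, colSums(agg), "/")
}

#' Compute all per-sample microbiota markers
#'
#' Joins alpha diversity, the bacterial maturation index, the enterotype
#' assignment and phylum relative abundances into one per-sample marker
#' table, the mediator input of [mediation_screen()].
#'
#' @param counts Taxa x samples count matrix.
#' @param meta Sample metadata with \code{sample_id}, \code{subject_id},
#'   \code{age_months}.
#' @param tree Phylogeny for weighted UniFrac (enterotyping input).
#' @param seed Seed for the forest and the prediction-strength split.
#' @param n_trees Trees for the maturation forest.
#' @return List of class \code{"marker_set"}: \code{markers} (per-sample data
#'   frame), \code{enterotype_fit}, \code{unifrac} (dist).
#' @export
compute_markers <- function(counts, meta, tree, seed = 1, n_trees = 500) {
  stopifnot(all(c("sample_id", "subject_id", "age_months") %in% names(meta)),
            all(meta$sample_id == colnames(counts)))
  div <- alpha_diversity(counts)
  uf <- weighted_unifrac(counts, tree)
  et <- enterotype(uf, counts, seed = seed)
  mat <- maturation_index(counts, meta$age_months, n_trees = n_trees,
                          seed = seed)
  phy <- phylum_collapse(counts)
  markers <- data.frame(meta,
                        observed = div$observed, shannon = div$shannon,
                        chao1 = div$chao1,
                        maturation = mat$index,
                        enterotype = as.integer(et$assignment$cluster == "B"),
                        t(phy), check.names = TRUE,
                        stringsAsFactors = FALSE)
  rownames(markers) <- NULL
  structure(list(markers = markers, enterotype_fit = et, unifrac = uf),
            class = "marker_set")
}
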