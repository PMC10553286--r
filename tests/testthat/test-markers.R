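# Microbiota maturation markers: closed-form diversity values, UniFrac
# against a brute-force branch enumeration, enterotype recovery, the
# random-forest maturation index, phylum collapse.

test_that("alpha diversity matches closed forms", {
  d <- alpha_diversity(c(10, 10, 10, 10))
  expect_equal(d$observed, 4L)
  expect_equal(d$shannon, log(4), tolerance = 1e-10)
  expect_equal(d$chao1, 4)                    # no singletons: chao1 = S_obs

  d2 <- alpha_diversity(c(5, 1, 1))           # F1 = 2, F2 = 0
  expect_equal(d2$observed, 3L)
  expect_equal(d2$chao1, 3 + 2 * 1 / 2)       # bias-corrected formula

  d3 <- alpha_diversity(c(0, 7, 0))
  expect_equal(d3$observed, 1L)
  expect_equal(d3$shannon, 0)

  expect_error(alpha_diversity(c(0, 0)), "all-zero")
  expect_error(alpha_diversity(c(-1, 2)), "non-negative")
})

test_that("diversity is invariant to taxon order; shannon to rescaling", {
  set.seed(4)
  x <- rpois(30, 4)
  x[1] <- max(x[1], 1)
  d <- alpha_diversity(x)
  dp <- alpha_diversity(sample(x))
  expect_equal(d[, -1], dp[, -1])
  expect_equal(alpha_diversity(x * 10)$shannon, d$shannon, tolerance = 1e-10)
  # bounds: shannon <= ln(observed), observed <= chao1
  expect_lte(d$shannon, log(d$observed))
  expect_lte(d$observed, d$chao1)
})

test_that("weighted UniFrac has metric endpoints and matches the oracle", {
  tree <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,(C:0.7,D:0.3):0.2);")
  counts <- cbind(s1 = c(A = 10L, B = 5L, C = 0L, D = 5L),
                  s2 = c(A = 10L, B = 5L, C = 0L, D = 5L),
                  s3 = c(A = 0L, B = 2L, C = 8L, D = 1L))
  uf <- as.matrix(weighted_unifrac(counts, tree))
  expect_equal(uf["s1", "s2"], 0, tolerance = 1e-10)      # identical samples
  expect_equal(uf["s1", "s3"], uf["s3", "s1"])
  expect_equal(uf["s1", "s3"],
               naive_weighted_unifrac(tree, counts[, "s1"], counts[, "s3"]),
               tolerance = 1e-10)

  # star tree, disjoint communities, equal branch lengths -> distance 1
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  dj <- cbind(s1 = c(A = 5L, B = 5L, C = 0L, D = 0L),
              s2 = c(A = 0L, B = 0L, C = 3L, D = 7L))
  expect_equal(as.numeric(weighted_unifrac(dj, star)), 1, tolerance = 1e-10)

  expect_error(weighted_unifrac(rbind(counts, X = 1L), tree),
               "absent from tree tips")
})

test_that("weighted UniFrac behaves as a metric on random communities", {
  cfg <- cohort_config(n_subjects = 4, seed = 19)
  m <- simulate_microbiota(simulate_diaries(cfg)$truth, cfg)
  uf <- as.matrix(weighted_unifrac(m$counts, m$tree))
  expect_equal(uf, t(uf), tolerance = 1e-10)
  expect_true(all(diag(uf) == 0))
  n <- nrow(uf)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(uf[i, j], uf[i, k] + uf[k, j] + 1e-10)
  }
  # cross-check a pair against the brute-force branch enumeration
  expect_equal(uf[1, 5],
               naive_weighted_unifrac(m$tree, m$counts[, 1], m$counts[, 5]),
               tolerance = 1e-10)
})

test_that("enterotyping recovers well-separated blobs and labels A by Bifidobacterium", {
  # two tight synthetic communities: Bifidobacterium-rich vs Bacteroides-rich
  cfg <- cohort_config(n_subjects = 10, seed = 33, depth = 20000,
                       concentration_by_age = c("3" = 500, "6" = 500,
                                                "12" = 500),
                       enterotype_b_prob = c("3" = 0, "6" = 0.5, "12" = 1))
  m <- simulate_microbiota(simulate_diaries(cfg)$truth, cfg)
  uf <- weighted_unifrac(m$counts, m$tree)
  et <- enterotype(uf, m$counts, seed = 1)
  truth_lab <- m$truth$enterotype
  expect_equal(et$assignment$cluster, truth_lab)
  expect_true(et$separable)
  expect_gt(et$prediction_strength, 0.9)
  # CH of the recovered labels beats random relabelings
  d <- as.matrix(uf)
  ch_true <- eatrhythm:::ch_index(d, et$assignment$cluster)
  set.seed(9)
  for (i in 1:20) {
    expect_gt(ch_true, eatrhythm:::ch_index(d, sample(et$assignment$cluster)))
  }
  # invariant to sample order
  perm <- sample(nrow(d))
  et_p <- enterotype(d[perm, perm], m$counts[, perm], seed = 1)
  expect_equal(et_p$assignment$cluster[order(perm)], et$assignment$cluster)
})

test_that("structureless distances are reported non-separable", {
  n <- 12
  d <- matrix(1, n, n) - diag(n)
  rownames(d) <- colnames(d) <- paste0("s", 1:n)
  counts <- matrix(5L, 2, n,
                   dimnames = list(c("g__Bifidobacterium", "g__Bacteroides"),
                                   paste0("s", 1:n)))
  et <- enterotype(d, counts, seed = 1)
  expect_false(et$separable)
  expect_error(enterotype(matrix(c(0, 1, 2, 0), 2, 2), counts[, 1:2]),
               "symmetric|4 samples")
})

test_that("maturation forest finds a monotone age signal and centers OOB indices", {
  set.seed(11)
  n <- 200
  ages <- sample(c(3, 6, 12), n, replace = TRUE)
  # five taxa rise linearly with age, the rest are noise
  signal <- sapply(ages, function(a) a / 12 * (1:5))
  noise <- matrix(rpois(15 * n, 20), 15, n)
  counts <- rbind(matrix(rpois(5 * n, 50 * (signal + 0.5)), 5, n), noise)
  rownames(counts) <- paste0("k__B|p__P|g__G", 1:20)
  mi <- maturation_index(counts, ages, n_trees = 300, seed = 2)
  expect_gt(cor(mi$predicted_age, mi$actual_age), 0.8)
  expect_lt(abs(mean(mi$index)), 0.5)
  expect_identical(maturation_index(counts, ages, n_trees = 300, seed = 2),
                   mi)   # deterministic under seed

  # pure-noise features: no information about age
  counts0 <- matrix(rpois(20 * n, 20), 20, n,
                    dimnames = list(paste0("g__N", 1:20), NULL))
  mi0 <- maturation_index(counts0, ages, n_trees = 300, seed = 2)
  expect_lt(attr(mi0, "oob_r2"), 0.1)
  expect_lt(abs(cor(mi0$index + mi0$actual_age, mi0$actual_age)), 0.15)

  expect_error(maturation_index(counts, rep(3, n)), "two ages")
})

test_that("phylum collapse sums annotated counts and flags unannotated taxa", {
  counts <- matrix(c(30L, 70L), 2, 1,
                   dimnames = list(c("k__B|p__Firmicutes|g__X",
                                     "k__B|p__Bacteroidetes|g__Y"), "s1"))
  ph <- phylum_collapse(counts)
  expect_equal(as.numeric(ph[c("Firmicutes", "Bacteroidetes"), 1]),
               c(0.3, 0.7))
  expect_equal(colSums(ph), c(s1 = 1), tolerance = 1e-9)

  one <- matrix(5L, 3, 1, dimnames = list(paste0("k__B|p__F|g__", 1:3), "s"))
  expect_equal(as.numeric(phylum_collapse(one)), 1)

  unann <- rbind(counts, mystery = 10L)
  expect_warning(ph2 <- phylum_collapse(unann), "other")
  expect_equal(as.numeric(ph2["other", 1]), 10 / 110)
})

test_that("collapsed phyla match the simulator's configured mixture", {
  cfg <- cohort_config(n_subjects = 60, seed = 21, depth = 50000,
                       enterotype_b_prob = c("3" = 0, "6" = 0, "12" = 0))
  m <- simulate_microbiota(simulate_diaries(cfg)$truth, cfg)
  ph <- phylum_collapse(m$counts)
  taxa <- taxa_reference()
  expected <- tapply(taxa$base_A, taxa$phylum, sum)
  got <- rowMeans(ph)[names(expected)]
  expect_lt(max(abs(got - expected)), 0.03)
})

test_that("compute_markers joins all marker families per sample", {
  cfg <- cohort_config(n_subjects = 8, seed = 27)
  m <- simulate_microbiota(simulate_diaries(cfg)$truth, cfg)
  ms <- compute_markers(m$counts, m$meta, m$tree, seed = 3, n_trees = 100)
  expect_equal(nrow(ms$markers), ncol(m$counts))
  expect_true(all(c("observed", "shannon", "chao1", "maturation",
                    "enterotype", "Firmicutes") %in% names(ms$markers)))
  expect_true(all(ms$markers$enterotype %in% 0:1))
})
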