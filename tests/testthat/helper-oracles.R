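# Independent brute-force oracles, deliberately naive implementations kept
# separate from the package's vectorised code paths.

# Circular uniform moving average by explicit index arithmetic: window at t
# covers [t - floor((k-1)/2), t + ceiling((k-1)/2)] modulo length.
naive_sma_once <- function(x, k) {
  E <- length(x)
  lo <- floor((k - 1) / 2); hi <- ceiling((k - 1) / 2)
  vapply(seq_len(E), function(t) {
    idx <- ((t - 1 - lo):(t - 1 + hi)) %% E + 1
    mean(x[idx])
  }, numeric(1))
}

naive_double_sma <- function(x, k) naive_sma_once(naive_sma_once(x, k), k)

naive_cosine <- function(a, b) {
  s <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    s <- s + a[i] * b[i]; na <- na + a[i]^2; nb <- nb + b[i]^2
  }
  s / sqrt(na * nb)
}

# All-pairs ERI recomputed with explicit double loops.
naive_eri <- function(days, k = 4, epoch_minutes = 15) {
  days <- days[vapply(days, function(d) length(d[!is.na(d)]) > 0, logical(1))]
  prof <- lapply(days, function(d) {
    v <- numeric(1440 / epoch_minutes)
    v[unique(floor(d[!is.na(d)] / epoch_minutes)) + 1] <- 1
    naive_double_sma(v, k)
  })
  n <- length(prof)
  sims <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sims <- c(sims, naive_cosine(prof[[i]], prof[[j]]))
  }
  mean(sims)
}

# Weighted UniFrac by explicit branch enumeration on an ape tree.
naive_weighted_unifrac <- function(tree, ca, cb) {
  pa <- ca / sum(ca); pb <- cb / sum(cb)
  ntip <- length(tree$tip.label)
  # tips descending from each edge
  desc_tips <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tree$tip.label[desc_tips(tree$edge[e, 2])]
    A <- sum(pa[tips]); B <- sum(pb[tips])
    bl <- tree$edge.length[e]
    num <- num + bl * abs(A - B)
    den <- den + bl * (A + B)
  }
  num / den
}

# small deterministic diary table for IO tests
write_tiny_diary <- function(path) {
  writeLines(c(
    "subject_id,age_months,date,meal_start",
    "S1,3,2016-05-01,07:30",
    "S1,3,2016-05-01,12:00",
    "S1,3,2016-05-02,07:37",
    "S1,3,2016-05-03,",
    "S2,3,2016-05-01,23:45"), path)
  path
}
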