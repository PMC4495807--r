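# Independent oracles used across the suite.

# brute-force optimal global alignment score over all monotone alignments of
# index sets 1..n and 1..m with gap score zero
brute_force_alignment <- function(zeta) {
  n <- nrow(zeta)
  m <- ncol(zeta)
  best <- list(score = 0, matches = matrix(integer(0), ncol = 2))
  # enumerate all subsets of rows, all equally sized subsets of columns, all
  # order-preserving pairings (which are unique once both subsets are fixed)
  for (k in 0:min(n, m)) {
    if (k == 0) next
    ri <- utils::combn(n, k, simplify = FALSE)
    ci <- utils::combn(m, k, simplify = FALSE)
    for (a in ri) for (b in ci) {
      sc <- sum(zeta[cbind(a, b)])
      if (sc > best$score) best <- list(score = sc, matches = cbind(a, b))
    }
  }
  best
}

# pairwise-definition Fowlkes-Mallows index over all point pairs
fmi_pairs_oracle <- function(truth, clustering) {
  n <- length(truth)
  tp <- fp <- fn <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    conn <- truth[i] == truth[j]
    clus <- clustering[i] == clustering[j]
    if (conn && clus) tp <- tp + 1
    else if (!conn && clus) fp <- fp + 1
    else if (conn && !clus) fn <- fn + 1
  }
  if (tp == 0) return(0)
  sqrt(tp / (tp + fp) * tp / (tp + fn))
}

# direct entropy computation for the normalized variation of information
nvi_entropy_oracle <- function(truth, clustering) {
  n <- length(truth)
  tl <- unique(truth)
  cl <- unique(clustering)
  a <- outer(tl, cl, Vectorize(function(i, j) sum(truth == i & clustering == j)))
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  hp <- h(rowSums(a) / n)
  hc <- h(colSums(a) / n)
  hpc <- 0
  hcp <- 0
  for (i in seq_along(tl)) for (j in seq_along(cl)) {
    if (a[i, j] > 0) {
      hpc <- hpc - a[i, j] / n * log(a[i, j] / sum(a[, j]))
      hcp <- hcp - a[i, j] / n * log(a[i, j] / sum(a[i, ]))
    }
  }
  if (hp != 0) (hpc + hcp) / hp else hc
}

random_partition <- function(n, max_blocks = 4) {
  sample.int(max_blocks, n, replace = TRUE)
}

# small standard config used in most tests (short spectra keep them fast)
test_config <- function(...) {
  ims_config(n_drift = 2500, ...)
}
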