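check_partitions <- function(truth, clustering) {
  if (length(truth) != length(clustering)) {
    stop("partitions must cover the same point set")
  }
  if (!length(truth)) stop("partitions are empty")
}

#' Fowlkes-Mallows index between two partitions
#'
#' Considers all point pairs: a pair is *connected* when both points share a
#' true block and *clustered* when the evaluated clustering puts them
#' together.  With TP (connected and clustered), FP (clustered only) and FN
#' (connected only), the index is the geometric mean of pairwise precision
#' and recall, `sqrt(TP/(TP+FP) * TP/(TP+FN))`, in `[0, 1]`; 1 means perfect
#' agreement.  When TP is zero the index is defined as 0.
#'
#' @param truth Vector of true block labels, one per point.
#' @param clustering Vector of cluster labels over the same points.
#' @return The index, a number in `[0, 1]`.
#' @export
fmi <- function(truth, clustering) {
  check_partitions(truth, clustering)
  a <- table(truth, clustering)
  tp <- sum(choose(a, 2))
  tp_fp <- sum(choose(colSums(a), 2))
  tp_fn <- sum(choose(rowSums(a), 2))
  if (tp == 0) return(0)
  sqrt(tp / tp_fp * tp / tp_fn)
}

#' Normalized variation of information between two partitions
#'
#' Builds the contingency matrix `a[i, j]` (points of true block `i` in
#' cluster `j`) and combines the entropies (natural logarithm, with
#' `0 log 0 := 0`):
#' `NVI = (H(P|C) + H(C|P)) / H(P)` when `H(P) != 0`, otherwise `H(C)`.
#' Zero means perfect agreement.
#'
#' @inheritParams fmi
#' @return A non-negative score.
#' @export
nvi <- function(truth, clustering) {
  check_partitions(truth, clustering)
  a <- table(truth, clustering)
  n <- sum(a)
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  pr <- rowSums(a) / n
  pc <- colSums(a) / n
  h_p <- -sum(xlogx(pr))
  h_c <- -sum(xlogx(pc))
  pij <- a / n
  # H(P|C) = -sum p_ij log(p_ij / p_.j); H(C|P) analogous
  h_p_c <- -sum(ifelse(a > 0, pij * log(sweep(pij, 2L, pc, `/`)), 0))
  h_c_p <- -sum(ifelse(a > 0, pij * log(sweep(pij, 1L, pr, `/`)), 0))
  res <- if (h_p != 0) (h_p_c + h_c_p) / h_p else h_c
  res + 0   # normalise a signed zero
}
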