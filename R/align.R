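#' Log-odds score for matching two 1-D peaks from consecutive spectra
#'
#' Evaluates the earlier peak's density at the new peak's mode and compares
#' it to the density one approximate grid-width standard deviation
#' (`delta = d_grid * c_t_given_d / phi_fwhm`) right of its own mode:
#' `zeta = log(g(m_new) / g(m_old + delta))`.  Positive when the new mode is
#' closer to the old mode than `delta`, negative when farther, `-Inf` when
#' the new mode falls outside the support.
#'
#' @param p_i A row (list or one-row data frame) with fields `mu`, `lambda`,
#'   `shift`, `mode` describing the earlier peak.
#' @param p_j Same, for the later peak (only `mode` is used).
#' @param cfg An [ims_config()].
#' @return The log-odds score (may be `-Inf`).
#' @export
peak_match_score <- function(p_i, p_j, cfg) {
  delta <- cfg$d_grid * cfg$c_t_given_d / phi_fwhm
  num <- dsig(p_j$mode, p_i$mu, p_i$lambda, p_i$shift)
  den <- dsig(p_i$mode + delta, p_i$mu, p_i$lambda, p_i$shift)
  if (num <= 0 || den <= 0) return(-Inf)
  log(num / den)
}

#' Globally align two consecutive spectrum peak lists
#'
#' Needleman-Wunsch dynamic programming over the two mode-sorted peak lists
#' with [peak_match_score()] as the match score and gap score zero:
#' `Z[i,j] = max(Z[i-1,j-1] + zeta, Z[i-1,j], Z[i,j-1])`, `Z[i,0] = Z[0,j] =
#' 0`.  Traceback ties prefer the match, then the gap in the earlier list,
#' then the gap in the later list, making the output deterministic.
#'
#' @param peaks Peak data frame of the earlier spectrum (rows sorted by
#'   `mode`).
#' @param peaks_new Peak data frame of the later spectrum.
#' @param cfg An [ims_config()].
#' @return A list with `matches` (two-column integer matrix of row indices
#'   `i`, `j`), `unmatched_old`, `unmatched_new` (integer vectors) and
#'   `score` (the DP optimum).
#' @export
align_peak_lists <- function(peaks, peaks_new, cfg) {
  n <- nrow(peaks)
  m <- nrow(peaks_new)
  Z <- matrix(0, n + 1L, m + 1L)
  zeta <- matrix(-Inf, max(n, 1L), max(m, 1L))
  if (n && m) {
    delta <- cfg$d_grid * cfg$c_t_given_d / phi_fwhm
    mode_new <- peaks_new$mode
    jj <- seq_len(m)
    for (i in seq_len(n)) {
      num <- dsig(mode_new, peaks$mu[i], peaks$lambda[i], peaks$shift[i])
      den <- dsig(peaks$mode[i] + delta, peaks$mu[i], peaks$lambda[i],
                  peaks$shift[i])
      zi <- ifelse(num > 0 & den > 0, log(num / den), -Inf)
      zi[is.nan(zi)] <- -Inf
      zeta[i, jj] <- zi
      # with gap score zero the row recurrence collapses to a running max
      cand <- pmax(Z[i, jj] + zi, Z[i, jj + 1L])
      cand[is.nan(cand)] <- Z[i, jj + 1L][is.nan(cand)]
      Z[i + 1L, jj + 1L] <- cummax(cand)
    }
  }
  matches <- matrix(integer(0), ncol = 2L,
                    dimnames = list(NULL, c("i", "j")))
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    here <- Z[i + 1L, j + 1L]
    if (is.finite(zeta[i, j]) && here == Z[i, j] + zeta[i, j]) {
      matches <- rbind(c(i, j), matches)
      i <- i - 1L; j <- j - 1L
    } else if (here == Z[i, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(matches = matches,
       unmatched_old = setdiff(seq_len(n), matches[, 1L]),
       unmatched_new = setdiff(seq_len(m), matches[, 2L]),
       score = Z[n + 1L, m + 1L])
}

#' Update the set of open peak chains with a new alignment
#'
#' Matched peaks extend their chains, unmatched new peaks start fresh chains,
#' and chains whose last peak went unmatched are closed and emitted.  The
#' open chains are returned in the row order of the new peak list so that the
#' next alignment can index them directly.
#'
#' @param chains List of open chains; chain `i` ends in row `i` of the
#'   previous peak list.  Each chain is a data frame of 1-D peak rows.
#' @param alignment Result of [align_peak_lists()] between the previous and
#'   the new peak list.
#' @param peaks_new The new spectrum's peak data frame.
#' @return A list with `open` (chains ordered like `peaks_new`) and `closed`
#'   (chains that ended at this retention time).
#' @export
update_chains <- function(chains, alignment, peaks_new) {
  if (length(chains) &&
      length(alignment$unmatched_old) + nrow(alignment$matches) != length(chains)) {
    stop("internal error: chain state inconsistent with alignment")
  }
  m <- nrow(peaks_new)
  open <- vector("list", m)
  if (nrow(alignment$matches)) {
    for (k in seq_len(nrow(alignment$matches))) {
      i <- alignment$matches[k, 1L]
      j <- alignment$matches[k, 2L]
      open[[j]] <- rbind(chains[[i]], peaks_new[j, ])
    }
  }
  for (j in alignment$unmatched_new) {
    open[[j]] <- peaks_new[j, , drop = FALSE]
  }
  closed <- chains[alignment$unmatched_old]
  list(open = open, closed = closed)
}
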