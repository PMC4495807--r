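#' Initialise the peak-location cluster model
#'
#' One cluster per peak: means at the peak locations, spreads at their floors
#' (`t_width` on the IRM axis, `xi(r)/phi` on the retention axis), uniform
#' mixture weights.
#'
#' @param locations Data frame with columns `t` (IRM, V s cm^-2) and `r`
#'   (retention time, s), one row per peak.
#' @param cfg An [ims_config()].
#' @return An object of class `ims_clusters`: a list with `mu_t`, `mu_r`,
#'   `sigma_t`, `sigma_r`, `weight` (per component) and `memberships`
#'   (points x components).
#' @export
init_clusters <- function(locations, cfg) {
  n <- nrow(locations)
  if (n < 1L) stop("at least one peak location is required")
  structure(list(
    mu_t = locations$t,
    mu_r = locations$r,
    sigma_t = rep(cfg$t_width, n),
    sigma_r = ret_width(locations$r, cfg) / phi_fwhm,
    weight = rep(1 / n, n),
    memberships = diag(n)
  ), class = "ims_clusters")
}

# closeness of component j to the components in idx
pair_close <- function(cm, cfg, j, idx) {
  lim <- pmax(cm$mu_r[j], cm$mu_r[idx]) * cfg$r_width_factor +
    cfg$r_width_offset
  abs(cm$mu_t[j] - cm$mu_t[idx]) < cfg$t_width &
    abs(cm$mu_r[j] - cm$mu_r[idx]) < lim
}

# scan all component pairs (ascending j < k) for mergeable centres; merge the
# first hit and restart, until no pair qualifies.  The pairwise closeness
# matrix is maintained incrementally: a merge only changes the surviving
# component's row and column.
merge_pass <- function(cm, cfg) {
  merged_any <- FALSE
  C <- length(cm$weight)
  if (C < 2L) return(list(model = cm, merged = FALSE))
  lim <- outer(cm$mu_r, cm$mu_r, pmax) * cfg$r_width_factor +
    cfg$r_width_offset
  close <- abs(outer(cm$mu_t, cm$mu_t, `-`)) < cfg$t_width &
    abs(outer(cm$mu_r, cm$mu_r, `-`)) < lim
  close[lower.tri(close, diag = TRUE)] <- FALSE
  repeat {
    hits <- which(close)
    if (!length(hits)) break
    # which() walks columns: convert to (row j, col k) and take the first
    # pair in ascending (j, k) order
    jj <- ((hits - 1L) %% C) + 1L
    kk <- ((hits - 1L) %/% C) + 1L
    first <- order(jj, kk)[1L]
    j <- jj[first]
    k <- kk[first]
    keep_pos <- if (cm$weight[j] >= cm$weight[k]) j else k
    cm$mu_t[j] <- cm$mu_t[keep_pos]
    cm$mu_r[j] <- cm$mu_r[keep_pos]
    cm$sigma_t[j] <- cm$sigma_t[keep_pos]
    cm$sigma_r[j] <- cm$sigma_r[keep_pos]
    cm$weight[j] <- cm$weight[j] + cm$weight[k]
    cm$memberships[, j] <- cm$memberships[, j] + cm$memberships[, k]
    sel <- setdiff(seq_len(C), k)
    cm$mu_t <- cm$mu_t[sel]; cm$mu_r <- cm$mu_r[sel]
    cm$sigma_t <- cm$sigma_t[sel]; cm$sigma_r <- cm$sigma_r[sel]
    cm$weight <- cm$weight[sel]
    cm$memberships <- cm$memberships[, sel, drop = FALSE]
    close <- close[-k, -k, drop = FALSE]
    C <- C - 1L
    if (C < 2L) {
      merged_any <- TRUE
      break
    }
    cc <- pair_close(cm, cfg, j, seq_len(C))
    cc[j] <- FALSE
    close[j, ] <- cc & (seq_len(C) > j)
    close[, j] <- cc & (seq_len(C) < j)
    merged_any <- TRUE
  }
  list(model = cm, merged = merged_any)
}

#' Merge clusters with close centres
#'
#' Compares every component pair `j < k` and merges pairs whose centres
#' differ by less than `t_width` in IRM and less than
#' `xi(max(mu_r_j, mu_r_k))` in retention time.  The merged component keeps
#' the position of the heavier partner, sums the mixture weights and the
#' membership columns; the scan restarts after each merge.
#'
#' @param cm An `ims_clusters` model with current memberships.
#' @param cfg An [ims_config()].
#' @return The updated `ims_clusters` model.
#' @export
merge_close <- function(cm, cfg) {
  stopifnot(inherits(cm, "ims_clusters"))
  merge_pass(cm, cfg)$model
}

#' Adaptive EM clustering of peak locations
#'
#' Soft-clusters peak locations from multiple measurements with a mixture of
#' axis-aligned 2-D Gaussians.  The component count starts at the number of
#' points (one cluster per peak, so no background component is needed) and is
#' reduced on the fly by [merge_close()], which runs between the E- and
#' M-steps from the second iteration onward.  Variance floors
#' (`sigma_t >= t_width`, `sigma_r >= xi(mu_r)/phi`) prevent the singleton
#' clusters from collapsing.  The loop ends when an iteration performs no
#' merge and all parameters change by less than `cfg$thresh` (relative), or
#' at `cfg$cluster_max_iter`.
#'
#' @param locations Data frame with columns `t` and `r` (one row per peak;
#'   an optional `measurement` column is carried along but not used).
#' @param cfg An [ims_config()].
#' @return A converged `ims_clusters` model; see [hard_assignment()] for a
#'   partition.
#' @export
cluster_peaks <- function(locations, cfg) {
  n <- nrow(locations)
  if (n == 0L) {
    return(structure(list(mu_t = numeric(0), mu_r = numeric(0),
                          sigma_t = numeric(0), sigma_r = numeric(0),
                          weight = numeric(0),
                          memberships = matrix(0, 0, 0),
                          iterations = 0L, converged = TRUE),
                     class = "ims_clusters"))
  }
  cm <- init_clusters(locations, cfg)
  xt <- locations$t
  xr <- locations$r
  prev <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$cluster_max_iter) {
    iter <- iter + 1L
    C <- length(cm$weight)
    # E-step: log densities of the 2-D Gaussian products
    MT <- matrix(xt, n, C)
    MR <- matrix(xr, n, C)
    logd <- stats::dnorm(MT, matrix(cm$mu_t, n, C, byrow = TRUE),
                         matrix(cm$sigma_t, n, C, byrow = TRUE), log = TRUE) +
      stats::dnorm(MR, matrix(cm$mu_r, n, C, byrow = TRUE),
                   matrix(cm$sigma_r, n, C, byrow = TRUE), log = TRUE)
    logw <- sweep(logd, 2L, log(cm$weight), `+`)
    mx <- apply(logw, 1L, max)
    W <- exp(logw - mx)
    W <- W / rowSums(W)
    cm$memberships <- W
    cm$weight <- colMeans(W)
    # dynamic adjustment (means need one iteration to move first)
    merged <- FALSE
    if (iter >= 2L) {
      mp <- merge_pass(cm, cfg)
      cm <- mp$model
      merged <- mp$merged
      C <- length(cm$weight)
    }
    # M-step with variance floors
    W <- cm$memberships
    cs <- colSums(W)
    ok <- cs > 0
    mu_t <- cm$mu_t; mu_r <- cm$mu_r
    mu_t[ok] <- colSums(W[, ok, drop = FALSE] * xt) / cs[ok]
    mu_r[ok] <- colSums(W[, ok, drop = FALSE] * xr) / cs[ok]
    st <- cm$sigma_t; sr <- cm$sigma_r
    st[ok] <- sqrt(colSums(W[, ok, drop = FALSE] *
                             (matrix(xt, n, sum(ok)) -
                                matrix(mu_t[ok], n, sum(ok), byrow = TRUE))^2) /
                     cs[ok])
    sr[ok] <- sqrt(colSums(W[, ok, drop = FALSE] *
                             (matrix(xr, n, sum(ok)) -
                                matrix(mu_r[ok], n, sum(ok), byrow = TRUE))^2) /
                     cs[ok])
    cm$mu_t <- mu_t
    cm$mu_r <- mu_r
    cm$sigma_t <- pmax(st, cfg$t_width)
    cm$sigma_r <- pmax(sr, ret_width(mu_r, cfg) / phi_fwhm)
    cur <- c(cm$mu_t, cm$mu_r, cm$sigma_t, cm$sigma_r)
    if (!merged && !is.null(prev) && length(prev) == length(cur)) {
      kap <- abs(cur - prev) / pmax(abs(cur), abs(prev))
      kap[cur == 0 & prev == 0] <- 0
      if (all(kap < cfg$thresh)) {
        converged <- TRUE
        break
      }
    }
    prev <- if (merged) NULL else cur
  }
  cm$iterations <- iter
  cm$converged <- converged
  cm
}

#' Hard cluster assignment from a soft clustering
#'
#' Assigns each point to the component with the largest membership weight;
#' ties go to the lower component index.
#'
#' @param cm A converged `ims_clusters` model.
#' @return Integer vector of cluster labels, one per point.
#' @export
hard_assignment <- function(cm) {
  stopifnot(inherits(cm, "ims_clusters"))
  if (!nrow(cm$memberships)) return(integer(0))
  max.col(cm$memberships, ties.method = "first")
}

#' k-means++ seeding for the baseline comparator
#'
#' Standard D^2-weighted seeding used to give [stats::kmeans()] good starting
#' centres when it serves as an evaluation baseline against
#' [cluster_peaks()].
#'
#' @param x Numeric matrix of points (rows).
#' @param k Number of centres.
#' @return A `k x ncol(x)` matrix of starting centres.
#' @export
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  if (k > n) stop("k must not exceed the number of points")
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}
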