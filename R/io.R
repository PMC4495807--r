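#' Write an IM spectrum-chromatogram to CSV
#'
#' Plain-text matrix dialect: the first line holds a label and the drift
#' axis in ms; each following line holds the spectrum's retention time in
#' seconds and its intensities, comma-separated.
#'
#' @param imsc An `imsc` list (see [simulate_imsc()] or [read_imsc()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imsc <- function(imsc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("retention_s", sprintf("%.17g", imsc$drift)),
                   collapse = ","), con)
  # 17 significant digits round-trip doubles exactly: reading the file back
  # reproduces the matrix bit for bit
  body <- cbind(imsc$retention, imsc$matrix)
  lines <- apply(body, 1L, function(row) paste(sprintf("%.17g", row),
                                               collapse = ","))
  writeLines(lines, con)
  invisible(path)
}

#' Read an IM spectrum-chromatogram from CSV
#'
#' Parses the dialect written by [write_imsc()], validates that the matrix
#' is rectangular and both axes strictly increasing and equidistant, and
#' attaches the IRM axis `c_t_given_d * drift`.
#'
#' @param path Input path.
#' @param cfg An [ims_config()] providing the drift-to-IRM conversion.
#' @param average Optional drift-axis averaging factor (see
#'   [average_drift()]).
#' @return An `imsc` list.
#' @export
read_imsc <- function(path, cfg = ims_config(), average = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("format error: no spectra in ", path)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  drift <- suppressWarnings(as.numeric(header[-1L]))
  if (anyNA(drift)) stop("format error: non-numeric drift axis header")
  nfield <- lengths(strsplit(lines[-1L], ",", fixed = TRUE))
  bad <- which(nfield != length(drift) + 1L)
  if (length(bad)) {
    stop("format error: row ", bad[1L] + 1L, " has ", nfield[bad[1L]],
         " fields, expected ", length(drift) + 1L)
  }
  body <- matrix(scan(text = lines[-1L], sep = ",", quiet = TRUE),
                 nrow = length(lines) - 1L, byrow = TRUE)
  retention <- body[, 1L]
  S <- body[, -1L, drop = FALSE]
  check_axis <- function(x, what) {
    if (length(x) >= 2L) {
      dx <- diff(x)
      if (any(dx <= 0)) stop("format error: ", what, " axis not strictly increasing")
      if (max(dx) - min(dx) > 1e-6 * mean(dx)) {
        stop("format error: ", what, " axis not equidistant")
      }
    }
  }
  check_axis(drift, "drift")
  check_axis(retention, "retention")
  imsc <- structure(list(matrix = S, retention = retention, drift = drift,
                         irm = cfg$c_t_given_d * drift, truth = NULL,
                         cfg = cfg),
                    class = "imsc")
  if (average > 1) imsc <- average_drift(imsc, average)
  imsc
}

#' Average an IMSC along the drift axis
#'
#' Replaces every block of `k` consecutive drift samples by its mean (a
#' common preprocessing step; `k = 5` turns 12 500 samples into 2 500).
#' Trailing samples that do not fill a block are dropped.
#'
#' @param imsc An `imsc` list.
#' @param k Block size.
#' @return The reduced `imsc`.
#' @export
average_drift <- function(imsc, k) {
  k <- as.integer(k)
  if (k < 2L) return(imsc)
  n <- ncol(imsc$matrix)
  m <- (n %/% k) * k
  grp <- rep(seq_len(m %/% k), each = k)
  avg <- function(v) tapply(v[seq_len(m)], grp, mean)
  S <- t(apply(imsc$matrix, 1L, avg))
  imsc$matrix <- matrix(S, nrow = nrow(imsc$matrix))
  imsc$drift <- as.numeric(avg(imsc$drift))
  imsc$irm <- as.numeric(avg(imsc$irm))
  imsc
}

#' Stream the spectra of an IMSC one at a time
#'
#' Returns a generator function that yields one [ims_spectrum()] per call,
#' in retention order, and `NULL` when exhausted — the shape of input the
#' online pipeline consumes (no look-ahead beyond the current spectrum).
#'
#' @param source An `imsc` list or a path readable by [read_imsc()].
#' @param cfg An [ims_config()] (used when `source` is a path).
#' @return A zero-argument function.
#' @export
stream_spectra <- function(source, cfg = ims_config()) {
  imsc <- if (is.character(source)) read_imsc(source, cfg) else source
  stopifnot(inherits(imsc, "imsc"))
  if (is.unsorted(imsc$retention, strictly = TRUE)) {
    stop("spectra out of retention order")
  }
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > nrow(imsc$matrix)) return(NULL)
    ims_spectrum(imsc$matrix[i, ], imsc$irm, imsc$retention[i])
  }
}

#' Run the full online peak-extraction pipeline
#'
#' Processes each spectrum as it arrives: EM denoising and baseline
#' correction, tailing estimation and subtraction, reduction to a 1-D peak
#' list, alignment against the previous spectrum's list and chain
#' bookkeeping; every chain that closes is immediately converted to 2-D peak
#' models.  The spread of a RIP-only spectrum, needed to initialise the
#' tailing fit, is calibrated from the first `cfg$calib_spectra` spectra.
#' Open chains are flushed when the stream ends.  The pipeline is
#' deterministic: identical input yields identical output, and streaming a
#' measurement gives the same table as passing it whole.
#'
#' @param source An `imsc` list, a path, or a generator as returned by
#'   [stream_spectra()].
#' @param cfg An [ims_config()].
#' @return A list with `peaks` (accepted 2-D peak data frame), `n_spectra`,
#'   `n_chains` (closed chains seen) and `sigma_n` (last noise estimate).
#' @export
run_online <- function(source, cfg = ims_config()) {
  nxt <- if (is.function(source)) source else stream_spectra(source, cfg)
  chains <- list()
  prev_peaks <- NULL
  tables <- list()
  n_spectra <- 0L
  n_chains <- 0L
  rip_sigmas <- numeric(0)
  sigma_n <- NA_real_
  emit <- function(chain, sn) {
    pk <- chain_to_peaks(chain, sn, cfg)
    if (nrow(pk)) tables[[length(tables) + 1L]] <<- pk
  }
  prev_nm <- NULL
  prev_tailing <- NULL
  repeat {
    spec <- nxt()
    if (is.null(spec)) break
    n_spectra <- n_spectra + 1L
    # consecutive spectra differ little: warm-starting the mixture and the
    # tailing from the previous spectrum keeps the per-spectrum work low
    nm <- suppressWarnings(denoise_spectrum(spec, cfg, init = prev_nm))
    prev_nm <- nm
    sigma_n <- nm$sigma_n
    corrected <- correct_spectrum(spec, nm, cfg)
    if (n_spectra <= cfg$calib_spectra) {
      sdv <- spectrum_axis_sd(corrected)
      if (is.finite(sdv) && sdv > 0) rip_sigmas <- c(rip_sigmas, sdv)
    }
    rip_sigma <- if (length(rip_sigmas)) mean(rip_sigmas) else NA_real_
    red <- suppressWarnings(
      reduce_spectrum(corrected, nm, cfg, rip_sigma = rip_sigma,
                      tailing_start = prev_tailing))
    prev_tailing <- red$tailing
    peaks <- red$peaks
    if (is.null(prev_peaks)) {
      chains <- lapply(seq_len(nrow(peaks)),
                       function(j) peaks[j, , drop = FALSE])
    } else {
      al <- align_peak_lists(prev_peaks, peaks, cfg)
      upd <- update_chains(chains, al, peaks)
      chains <- upd$open
      n_chains <- n_chains + length(upd$closed)
      for (ch in upd$closed) emit(ch, sigma_n)
    }
    prev_peaks <- peaks
  }
  n_chains <- n_chains + length(chains)
  for (ch in chains) emit(ch, sigma_n)
  peaks <- if (length(tables)) do.call(rbind, tables) else
    chain_to_peaks(data.frame(r = numeric(0), mode = numeric(0),
                              mean = numeric(0), sigma = numeric(0),
                              mu = numeric(0), lambda = numeric(0),
                              shift = numeric(0), v = numeric(0),
                              height = numeric(0)),
                   1, cfg)
  rownames(peaks) <- NULL
  list(peaks = peaks, n_spectra = n_spectra, n_chains = n_chains,
       sigma_n = sigma_n)
}
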