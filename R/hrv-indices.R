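#' Locally detrend the valid NN intervals
#'
#' Subtracts a centered moving average computed over a time window so that
#' baseline drift and state transitions do not inflate the fluctuation
#' amplitude. At the edges the window shrinks to the available data.
#'
#' @param x an `nn_series`.
#' @param window_s averaging window, seconds (default 60).
#' @return list with `time_s` and `resid_ms` for the valid intervals.
#' @export
detrend_nn <- function(x, window_s = 60) {
  keep <- x$valid
  t <- x$time_s[keep]
  v <- x$nn_ms[keep]
  if (length(v) < 2) stop("need at least 2 valid intervals")
  half <- window_s / 2
  cs <- c(0, cumsum(v))
  lo <- findInterval(t - half, t, left.open = TRUE) + 1L
  hi <- findInterval(t + half, t)
  m <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  list(time_s = t, resid_ms = v - m)
}

#' Fluctuation amplitude (AMP)
#'
#' The 20-95 inter-quantile distance of the detrended NN series, in ms.
#' Quantiles use the linear-interpolation convention (R type 7).
#'
#' @param detrended numeric residuals in ms (see [detrend_nn()]), or an
#'   `nn_series` which is detrended first with `window_s`.
#' @param window_s detrending window when an `nn_series` is given.
#' @return AMP in ms, or `NA` with a `reason` attribute for fewer than 20
#'   values.
#' @export
amp <- function(detrended, window_s = 60) {
  if (inherits(detrended, "nn_series")) {
    detrended <- detrend_nn(detrended, window_s)$resid_ms
  }
  detrended <- detrended[is.finite(detrended)]
  if (length(detrended) < 20) {
    return(structure(NA_real_, reason = "fewer than 20 values"))
  }
  q <- stats::quantile(detrended, c(0.20, 0.95), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Skewness of the instantaneous heart rate
#'
#' Sample skewness `g1 = m3 / m2^(3/2)` (bias-uncorrected moment form) of
#' the bpm series of the valid beats. Decelerations drag the heart rate
#' down asymmetrically and push the skewness negative; accelerations push
#' it positive, so the sign summarises AC/DC pattern formation.
#'
#' @param hr data frame with a `bpm` column, or an `nn_series`.
#' @return dimensionless skewness; `NA` with a `reason` attribute for fewer
#'   than 3 values or zero variance.
#' @export
hr_skewness <- function(hr) {
  if (inherits(hr, "nn_series")) hr <- instantaneous_hr(hr)
  v <- hr$bpm[is.finite(hr$bpm)]
  if (length(v) < 3) return(structure(NA_real_, reason = "fewer than 3 values"))
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 <= 0) return(structure(NA_real_, reason = "zero variance"))
  mean((v - m)^3) / m2^1.5
}

#' pNN5: percentage of adjacent NN differences exceeding 5 ms
#'
#' Counts pairs of array-adjacent valid intervals; a difference of exactly
#' 5 ms is not counted (the threshold is strict). Pairs spanning an invalid
#' interval are excluded.
#'
#' @param x an `nn_series`.
#' @param threshold_ms strict difference threshold, default 5 ms.
#' @return percentage in `[0, 100]`, or `NA` with a `reason` attribute when
#'   no valid pair exists.
#' @export
pnn5 <- function(x, threshold_ms = 5) {
  n <- length(x$nn_ms)
  if (n < 2) return(structure(NA_real_, reason = "fewer than 2 intervals"))
  pair <- x$valid[-n] & x$valid[-1]
  if (!any(pair)) return(structure(NA_real_, reason = "no valid adjacent pairs"))
  d <- abs(diff(x$nn_ms))[pair]
  100 * mean(d > threshold_ms)
}

# Welch-style averaged modified periodogram with a Hann taper. Returns a
# one-sided PSD; power in a band is the sum of psd * df over the band.
.welch_psd <- function(z, fs, seg_len, overlap = 0.5) {
  n <- length(z)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  scale <- fs * sum(w^2)
  acc <- numeric(floor(seg_len / 2) + 1L)
  for (s in starts) {
    seg <- z[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    p <- Mod(X[seq_along(acc)])^2 / scale
    p[-c(1L, length(acc))] <- 2 * p[-c(1L, length(acc))]
    acc <- acc + p
  }
  psd <- acc / length(starts)
  list(freq = (seq_along(acc) - 1L) * fs / seg_len, psd = psd,
       df = fs / seg_len)
}

# Cubic-spline resampling of the valid-beat tachogram onto an even grid.
.resample_tachogram <- function(x, fs = 4) {
  keep <- x$valid
  t <- x$time_s[keep]
  v <- x$nn_ms[keep]
  grid <- seq(t[1], t[length(t)], by = 1 / fs)
  stats::spline(t, v, xout = grid, method = "fmm")$y
}

#' ln VLF/LF band-power ratio
#'
#' Ratio of very-low-frequency (0.02-0.08 Hz) to low-frequency (0.08-0.2 Hz)
#' band power of the NN tachogram, on a natural-log scale. The irregular
#' tachogram is cubic-spline resampled to `fs` Hz and the spectrum is a
#' Welch-type average of Hann-tapered, mean-removed periodograms
#' (segment length `seg_s` seconds, 50% overlap).
#'
#' @param x an `nn_series` spanning at least 150 s (three cycles of the
#'   lowest band edge).
#' @param fs resampling rate, Hz (default 4).
#' @param seg_s Welch segment length, seconds (default 150).
#' @param vlf,lf band edges in Hz.
#' @return `ln(P_vlf / P_lf)`; `NA` with a `reason` attribute when the
#'   series is too short or the LF power vanishes.
#' @export
vlf_lf <- function(x, fs = 4, seg_s = 150, vlf = c(0.02, 0.08),
                   lf = c(0.08, 0.2)) {
  keep <- x$valid
  if (sum(keep) < 8 || diff(range(x$time_s[keep])) < 150) {
    return(structure(NA_real_, reason = "shorter than 150 s"))
  }
  z <- .resample_tachogram(x, fs)
  sp <- .welch_psd(z, fs, seg_len = round(seg_s * fs))
  p_vlf <- sum(sp$psd[sp$freq >= vlf[1] & sp$freq <= vlf[2]]) * sp$df
  p_lf <- sum(sp$psd[sp$freq > lf[1] & sp$freq <= lf[2]]) * sp$df
  if (p_lf <= 0) return(structure(NA_real_, reason = "zero LF power"))
  log(p_vlf / p_lf)
}

#' Coarse-grained lag-1 auto mutual information (gMSE3)
#'
#' Complexity of the beat-interval series at coarse-graining level 3,
#' following the multiscale convention: (1) replace the valid NN series by
#' non-overlapping means of 3 consecutive intervals; (2) estimate the auto
#' mutual information at lag 1 of the coarse-grained series with an
#' equiprobable (rank-based) binning estimator using
#' `B = floor(sqrt(M / 5))` bins, where `M` is the number of lagged pairs.
#' Values are reported in nats. Estimator settings are recorded in the
#' result's attributes for auditability; rank-based binning makes the
#' estimate invariant under strictly monotone transformations of the
#' intervals.
#'
#' @param x an `nn_series`, or a numeric vector of interval values.
#' @param scale coarse-graining level (default 3).
#' @param lag mutual-information lag on the coarse series (default 1).
#' @param bins number of marginal bins; default `floor(sqrt(M / 5))`,
#'   at least 2.
#' @param min_n minimum number of valid intervals (default 300; the
#'   pattern-segmentation variants relax this to 120 for 3-min windows).
#' @return mutual information in nats (non-negative by construction of the
#'   plug-in estimate), or `NA` with a `reason` attribute when too short.
#' @export
gmse3 <- function(x, scale = 3, lag = 1, bins = NULL, min_n = 300) {
  v <- if (inherits(x, "nn_series")) x$nn_ms[x$valid] else x[is.finite(x)]
  if (length(v) < min_n) {
    return(structure(NA_real_, reason = sprintf("fewer than %d valid intervals", min_n)))
  }
  K <- floor(length(v) / scale)
  cg <- colMeans(matrix(v[seq_len(K * scale)], nrow = scale))
  M <- K - lag
  B <- if (is.null(bins)) max(2L, floor(sqrt(M / 5))) else as.integer(bins)
  # equiprobable bins via empirical quantiles (type 1 keeps exact order stats)
  edges <- stats::quantile(cg, probs = seq_len(B - 1) / B, type = 1, names = FALSE)
  idx <- findInterval(cg, unique(edges), left.open = TRUE) + 1L
  nb <- max(idx)
  joint <- table(factor(idx[seq_len(M)], levels = seq_len(nb)),
                 factor(idx[seq_len(M) + lag], levels = seq_len(nb)))
  p <- joint / M
  pi_ <- rowSums(p); pj_ <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(pi_, pj_)[nz]))
  structure(max(mi, 0),
            settings = list(scale = scale, lag = lag, bins = B,
                            estimator = "equiprobable_binning", units = "nats"))
}

#' Compute the five fABAS indices for one segment
#'
#' AMP, skewness of the instantaneous heart rate, pNN5, ln VLF/LF and gMSE3
#' for a segment's NN series. Indices that cannot be computed are reported
#' as `NA` with a reason code.
#'
#' @param x an `nn_series` covering one segment.
#' @param label segment label recorded in the result (e.g. `"full30"`,
#'   `"quiet"`, `"active"`).
#' @param detrend_window_s AMP detrending window (default 60 s).
#' @param gmse_min_n minimum intervals for gMSE3 (default 300).
#' @return list of class `index_vector`: `amp_ms`, `skewness`,
#'   `pnn5_percent`, `ln_vlf_lf`, `gmse3`, `n_beats`, `segment_label`,
#'   `reasons` (named character vector for missing entries).
#' @export
compute_indices <- function(x, label = "full30", detrend_window_s = 60,
                            gmse_min_n = 300) {
  vals <- list(
    amp_ms = tryCatch(amp(x, detrend_window_s), error = function(e)
      structure(NA_real_, reason = conditionMessage(e))),
    skewness = tryCatch(hr_skewness(x), error = function(e)
      structure(NA_real_, reason = conditionMessage(e))),
    pnn5_percent = pnn5(x),
    ln_vlf_lf = vlf_lf(x),
    gmse3 = gmse3(x, min_n = gmse_min_n)
  )
  reasons <- vapply(vals, function(v) {
    r <- attr(v, "reason"); if (is.null(r) || !is.na(v)) NA_character_ else r
  }, character(1))
  out <- lapply(vals, function(v) as.numeric(v))
  out$n_beats <- sum(x$valid)
  out$segment_label <- label
  out$reasons <- reasons[!is.na(reasons)]
  structure(out, class = "index_vector")
}

#' @export
print.index_vector <- function(x, ...) {
  cat(sprintf("<index_vector '%s'> n_beats = %d\n", x$segment_label, x$n_beats))
  cat(sprintf("  AMP %.2f ms | skewness %.3f | pNN5 %.1f%% | lnVLF/LF %.3f | gMSE3 %.4f\n",
              x$amp_ms, x$skewness, x$pnn5_percent, x$ln_vlf_lf, x$gmse3))
  if (length(x$reasons)) {
    cat("  missing:", paste(names(x$reasons), x$reasons, sep = ": ", collapse = "; "), "\n")
  }
  invisible(x)
}
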