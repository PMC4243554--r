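#' Estimate the fetal heart rate baseline from an epoch series
#'
#' A smooth, slowly varying bpm reference that is insensitive to
#' accelerations and decelerations. The published Dawes-Redman baseline
#' algorithm is proprietary; this implementation is an iterated trimmed
#' low-pass: convert epochs to bpm, take a centered moving median over
#' `window_s`, exclude points deviating more than `exclude_bpm` from the
#' current baseline, refit the median on the remainder, and repeat until
#' the baseline stabilises or `max_iter` passes. The method tag is recorded
#' so results stay auditable when a different estimator is plugged in.
#'
#' @param epochs an `epoch_series`.
#' @param window_s moving-median window, seconds (default 180).
#' @param exclude_bpm trimming threshold in bpm (default 10).
#' @param max_iter maximum refinement passes (default 5).
#' @param tol_bpm convergence tolerance on the maximal baseline change.
#' @return list of class `baseline_series`: `values` (bpm per epoch),
#'   `method`, `converged`.
#' @export
estimate_baseline <- function(epochs, window_s = 180, exclude_bpm = 10,
                              max_iter = 5, tol_bpm = 0.1) {
  if (duration_s(epochs) < window_s) stop("need at least ", window_s, " s of epochs")
  bpm <- 60000 / epochs$values
  k <- round(window_s / epochs$epoch_s)
  if (k %% 2 == 0) k <- k + 1
  roll_med <- function(v) {
    out <- zoo::rollapply(zoo::zoo(v), width = k,
                          FUN = function(z) stats::median(z, na.rm = TRUE),
                          align = "center", partial = TRUE)
    as.numeric(out)
  }
  fill <- function(b) {
    # bridge stretches where every window point was trimmed/artifact
    if (all(is.na(b))) stop("baseline undefined: no usable epochs")
    idx <- seq_along(b)
    ok <- is.finite(b)
    stats::approx(idx[ok], b[ok], xout = idx, rule = 2)$y
  }
  base <- fill(roll_med(bpm))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    keep <- bpm
    keep[!is.finite(bpm) | abs(bpm - base) > exclude_bpm] <- NA_real_
    new <- fill(roll_med(keep))
    if (max(abs(new - base)) < tol_bpm) { base <- new; converged <- TRUE; break }
    base <- new
  }
  if (!converged) warning("baseline refinement did not converge; returning last iterate")
  structure(list(values = base, method = "iterated_trimmed_moving_median",
                 converged = converged),
            class = "baseline_series")
}

#' Floating baseline of an instantaneous heart rate series
#'
#' Operationalises the visually determined floating baseline used for
#' behavioral-state classification as a 3-minute centered moving median of
#' the bpm series with one trimming pass: samples deviating more than
#' `exclude_bpm` from the first-pass median (i.e. inside AC/DC complexes)
#' are excluded and the median refitted, so dense accelerations do not
#' drag the baseline up. The irregularly sampled beat series is
#' nearest-neighbour resampled to a 1 s grid for the median, then mapped
#' back to beat times.
#'
#' @param hr data frame with `time_s`, `bpm` (see [instantaneous_hr()]).
#' @param window_s moving window in seconds (default 180).
#' @param exclude_bpm trimming threshold, bpm (default 10).
#' @return numeric vector of baseline bpm, one per row of `hr`.
#' @export
floating_baseline <- function(hr, window_s = 180, exclude_bpm = 10) {
  span <- diff(range(hr$time_s))
  if (span < window_s) stop("need at least ", window_s, " s of heart rate")
  grid <- seq(min(hr$time_s), max(hr$time_s), by = 1)
  g <- stats::approx(hr$time_s, hr$bpm, xout = grid, method = "constant",
                     rule = 2)$y
  k <- min(window_s + 1, length(g))
  if (k %% 2 == 0) k <- k - 1
  med <- stats::runmed(g, k, endrule = "median")
  keep <- g
  keep[abs(g - med) > exclude_bpm] <- NA_real_
  med2 <- as.numeric(zoo::rollapply(zoo::zoo(keep), width = k,
                                    FUN = function(z) stats::median(z, na.rm = TRUE),
                                    align = "center", partial = TRUE))
  bad <- !is.finite(med2)
  med2[bad] <- med[bad]
  stats::approx(grid, med2, xout = hr$time_s, rule = 2)$y
}
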