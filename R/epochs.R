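#' Integrate an NN series into fixed CTG-compatible epochs
#'
#' Clinical CTG devices integrate beat intervals over 3.75 s epochs (16 per
#' minute); STV/LTV and the Dawes-Redman criteria are defined on this grid.
#' The epoch value is the time-weighted mean of the valid NN intervals
#' overlapping the epoch window; the artifact fraction is the share of the
#' epoch not covered by valid intervals.
#'
#' @param x an `nn_series`.
#' @param epoch_s epoch duration in seconds (default 3.75).
#' @return An object of class `epoch_series`: list with `values` (ms, `NA`
#'   where the whole epoch is artifact), `artifact_fraction`, `epoch_s`,
#'   `n_epochs` and `time_s` (epoch start times).
#' @export
epoch_series <- function(x, epoch_s = 3.75) {
  dur <- attr(x, "duration_s")
  if (dur < epoch_s) stop("recording shorter than one epoch")
  n_epochs <- floor(dur / epoch_s + 1e-9)
  t0 <- x$time_s
  t1 <- x$time_s + x$nn_ms / 1000
  values <- numeric(n_epochs)
  artf <- numeric(n_epochs)
  starts <- (seq_len(n_epochs) - 1) * epoch_s
  # candidate intervals per epoch located by onset index
  lo_idx <- findInterval(starts, t1, left.open = FALSE) # last interval ending <= start
  for (j in seq_len(n_epochs)) {
    a <- starts[j]; b <- a + epoch_s
    i <- max(1L, lo_idx[j])
    idx <- i:length(t0)
    idx <- idx[t0[idx] < b & t1[idx] > a]
    if (length(idx) == 0L) { values[j] <- NA_real_; artf[j] <- 1; next }
    ov <- pmin(t1[idx], b) - pmax(t0[idx], a)
    v <- x$valid[idx]
    covered <- sum(ov[v])
    artf[j] <- 1 - covered / epoch_s
    values[j] <- if (covered > 0) sum(x$nn_ms[idx][v] * ov[v]) / covered else NA_real_
  }
  structure(list(values = values, artifact_fraction = pmin(pmax(artf, 0), 1),
                 epoch_s = epoch_s, n_epochs = n_epochs, time_s = starts),
            class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> %d epochs of %.2f s, mean NN %.1f ms\n",
              x$n_epochs, x$epoch_s, mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Partition an epoch series into 1-minute sections and mark analyzability
#'
#' A minute (16 consecutive 3.75 s epochs) is analyzable iff it overlaps no
#' large deceleration and its mean artifact fraction does not exceed
#' `max_artifact`. Following the smallest Dawes-Redman lost-beats bound, a
#' "large" deceleration is one with more than `large_dc_lost` lost beats.
#'
#' @param epochs an `epoch_series`.
#' @param dc_events an `event_list` (from [detect_events()], `ctg_dawes`
#'   rules); may be `NULL` for none.
#' @param max_artifact maximum mean artifact fraction (default 0.5).
#' @param large_dc_lost lost-beats bound defining a large DC (default 20).
#' @return data frame of class `minute_sections` with one row per complete
#'   minute: `minute`, `start_s`, `end_s`, `analyzable`, `minute_range_ms`
#'   (filled by [ltv()]).
#' @export
mark_analyzable <- function(epochs, dc_events = NULL, max_artifact = 0.5,
                            large_dc_lost = 20) {
  per_min <- round(60 / epochs$epoch_s)
  n_min <- floor(epochs$n_epochs / per_min)
  if (n_min < 1) stop("epoch series shorter than one minute")
  start_s <- (seq_len(n_min) - 1) * 60
  end_s <- start_s + 60
  af <- vapply(seq_len(n_min), function(m) {
    mean(epochs$artifact_fraction[((m - 1) * per_min + 1):(m * per_min)])
  }, numeric(1))
  analyzable <- af <= max_artifact
  if (!is.null(dc_events) && nrow(dc_events) > 0) {
    dc <- dc_events[dc_events$kind == "DC" & dc_events$lost_beats > large_dc_lost, ,
                    drop = FALSE]
    if (nrow(dc) > 0) {
      for (k in seq_len(nrow(dc))) {
        hit <- start_s < dc$onset_s[k] + dc$duration_s[k] & end_s > dc$onset_s[k]
        analyzable[hit] <- FALSE
      }
    }
  }
  structure(data.frame(minute = seq_len(n_min), start_s = start_s, end_s = end_s,
                       analyzable = analyzable, minute_range_ms = NA_real_),
            class = c("minute_sections", "data.frame"))
}

#' Short-term variability (STV)
#'
#' Mean absolute difference between consecutive epoch values (15 pairs per
#' minute), averaged within each analyzable minute and then across
#' analyzable minutes. Pairs involving a fully-artifact epoch are skipped.
#'
#' @param epochs an `epoch_series`.
#' @param minutes minute sections from [mark_analyzable()].
#' @return STV in ms; `NA` with attribute `reason` when no minute is
#'   analyzable.
#' @export
stv <- function(epochs, minutes) {
  per_min <- round(60 / epochs$epoch_s)
  vals <- lapply(which(minutes$analyzable), function(m) {
    v <- epochs$values[((m - 1) * per_min + 1):(m * per_min)]
    d <- abs(diff(v))
    mean(d, na.rm = TRUE)
  })
  vals <- unlist(vals)
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) {
    return(structure(NA_real_, reason = "no analyzable minutes"))
  }
  mean(vals)
}

#' Long-term variability (LTV)
#'
#' Per analyzable minute, the fluctuation range of the epoch values about
#' the baseline: the maximal deviation above the baseline plus the maximal
#' deviation below it (each clamped at zero), computed on the interval scale
#' in ms after converting the baseline from bpm. The recording LTV is the
#' mean range across analyzable minutes.
#'
#' @param epochs an `epoch_series`.
#' @param minutes minute sections from [mark_analyzable()].
#' @param baseline a `baseline_series` (bpm, per epoch) from
#'   [estimate_baseline()].
#' @return list with `ltv_ms` (`NA` with a `reason` attribute when no minute
#'   is analyzable) and `minutes`, the input with `minute_range_ms` filled
#'   for every complete minute.
#' @export
ltv <- function(epochs, minutes, baseline) {
  per_min <- round(60 / epochs$epoch_s)
  base_ms <- 60000 / baseline$values
  rng <- vapply(seq_len(nrow(minutes)), function(m) {
    idx <- ((m - 1) * per_min + 1):(m * per_min)
    dev <- epochs$values[idx] - base_ms[idx]
    dev <- dev[is.finite(dev)]
    if (length(dev) == 0) return(NA_real_)
    max(c(dev, 0)) + max(c(-dev, 0))
  }, numeric(1))
  minutes$minute_range_ms <- rng
  ok <- minutes$analyzable & is.finite(rng)
  val <- if (any(ok)) mean(rng[ok]) else structure(NA_real_, reason = "no analyzable minutes")
  list(ltv_ms = val, minutes = minutes)
}
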