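#' Construct a validated beat-to-beat (NN) interval series
#'
#' The universal input object of the package: a sequence of normal-to-normal
#' beat intervals in milliseconds together with the onset time of each beat,
#' a per-interval validity flag, and recording metadata. Intervals that
#' violate basic physiology (non-positive length) or whose onset times are
#' inconsistent with the stated interval are flagged invalid, never removed:
#' downstream artifact rules (e.g. the 50%-artifact exclusion of analyzable
#' minutes, the signal-loss criterion) need the artifact fraction.
#'
#' @param time_s numeric, beat onset times in seconds from recording start,
#'   strictly increasing.
#' @param nn_ms numeric, NN intervals in milliseconds, one per beat onset.
#' @param valid logical, per-interval validity flag. Defaults to all `TRUE`;
#'   rows with non-positive `nn_ms` are flagged invalid with a warning.
#' @param recording_id character scalar identifier.
#' @param wga gestational age in completed weeks, in `[21, 40]`, or `NA`.
#' @param movement_count optional non-negative integer, number of fetal
#'   movements observed during the recording.
#' @param check_times if `TRUE` (default), verify that within every maximal
#'   run of valid intervals `time_s[i+1] - time_s[i]` equals `nn_ms[i]/1000`
#'   to within 1 ms, flagging offenders invalid.
#' @return An object of class `nn_series`: a list with elements `time_s`,
#'   `nn_ms`, `valid`, `recording_id`, `wga`, `movement_count` and an
#'   attribute `duration_s` (end of the last interval).
#' @seealso [read_nn_csv()], [instantaneous_hr()], [extract_segment()]
#' @export
nn_series <- function(time_s, nn_ms, valid = NULL, recording_id = "rec",
                      wga = NA_real_, movement_count = NA_integer_,
                      check_times = TRUE) {
  n <- length(nn_ms)
  if (n == 0L) stop("empty interval series")
  if (length(time_s) != n) stop("time_s and nn_ms must have equal length")
  if (is.null(valid)) valid <- rep(TRUE, n)
  valid <- as.logical(valid) & !is.na(nn_ms)
  if (any(diff(time_s) <= 0)) {
    stop("beat times not strictly increasing; first offending row: ",
         which(diff(time_s) <= 0)[1] + 1L)
  }
  bad <- valid & (is.na(nn_ms) | nn_ms <= 0)
  if (any(bad)) {
    warning(sum(bad), " interval(s) with non-positive length flagged invalid")
    valid[bad] <- FALSE
  }
  if (check_times && n > 1L) {
    # onset spacing must match the stated interval inside valid runs (1 ms slack)
    run <- valid[-n] & valid[-1]
    mism <- run & abs(diff(time_s) - nn_ms[-n] / 1000) > 1e-3 + 1e-9
    if (any(mism)) {
      warning(sum(mism), " interval(s) inconsistent with beat times flagged invalid")
      valid[which(mism)] <- FALSE
    }
  }
  if (!is.na(wga) && (wga < 21 || wga > 40)) {
    stop("wga must lie in [21, 40] weeks, got ", wga)
  }
  x <- list(time_s = as.numeric(time_s), nn_ms = as.numeric(nn_ms),
            valid = valid, recording_id = as.character(recording_id),
            wga = wga, movement_count = movement_count)
  attr(x, "duration_s") <- time_s[n] + ifelse(valid[n], nn_ms[n] / 1000, 0)
  class(x) <- "nn_series"
  x
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("<nn_series '%s'> %d intervals, %.1f s, %.1f%% invalid, wga = %s\n",
              x$recording_id, length(x$nn_ms), attr(x, "duration_s"),
              100 * mean(!x$valid),
              ifelse(is.na(x$wga), "NA", format(x$wga))))
  invisible(x)
}

#' @export
length.nn_series <- function(x) length(x$nn_ms)

#' Duration of a series, segment or epoch grid in seconds
#' @param x an `nn_series` or `epoch_series`.
#' @return numeric scalar, seconds.
#' @export
duration_s <- function(x) {
  if (inherits(x, "epoch_series")) return(x$n_epochs * x$epoch_s)
  attr(x, "duration_s")
}

#' Read an NN-interval series from a delimited text file
#'
#' The default dialect is comma-separated with a header line
#' `time_s,nn_ms,valid`; the `valid` column is optional. Invalid rows are
#' flagged, not dropped, and the flagged count is reported via `message()`.
#'
#' @param path file path.
#' @param dialect list with elements `sep` (default `","`), `header`
#'   (default `TRUE`) and `cols`, a character vector naming the time,
#'   interval and (optional) validity columns in order.
#' @param ... metadata passed on to [nn_series()] (`recording_id`, `wga`,
#'   `movement_count`).
#' @return An `nn_series`.
#' @export
read_nn_csv <- function(path, dialect = list(), ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::modifyList(list(sep = ",", header = TRUE,
                              cols = c("time_s", "nn_ms", "valid")), dialect)
  df <- utils::read.table(path, sep = d$sep, header = d$header,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty file: ", path)
  if (!d$header) names(df) <- d$cols[seq_len(ncol(df))]
  need <- d$cols[1:2]
  if (!all(need %in% names(df))) {
    stop("missing required columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  valid <- if (length(d$cols) >= 3 && d$cols[3] %in% names(df)) {
    as.logical(df[[d$cols[3]]])
  } else NULL
  x <- nn_series(df[[need[1]]], df[[need[2]]], valid = valid, ...)
  nflag <- sum(!x$valid)
  if (nflag > 0) message(nflag, " interval(s) flagged invalid in ", basename(path))
  x
}

#' Write an NN-interval series to CSV
#'
#' Inverse of [read_nn_csv()] under the default dialect; the round trip is
#' lossless for times, intervals and validity flags.
#'
#' @param x an `nn_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nn_csv <- function(x, path) {
  df <- data.frame(time_s = x$time_s, nn_ms = x$nn_ms,
                   valid = as.integer(x$valid))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Instantaneous heart rate of the valid beats
#'
#' One value per valid interval, `60000 / nn_ms`, in beats per minute;
#' invalid intervals are omitted.
#'
#' @param x an `nn_series`.
#' @return data frame with columns `time_s` and `bpm`.
#' @export
instantaneous_hr <- function(x) {
  keep <- x$valid
  if (!any(keep)) stop("no valid beats")
  data.frame(time_s = x$time_s[keep], bpm = 60000 / x$nn_ms[keep])
}

#' Describe an analysis segment
#'
#' Segments use the half-open convention `[start, end)`; a beat belongs to a
#' segment iff its onset time falls inside. State segments are 600 s, full
#' recordings 1800 s (checked with a configurable tolerance).
#'
#' @param start,end segment bounds in seconds.
#' @param label one of `"full30"`, `"quiet"` (HRP I), `"active"` (HRP II),
#'   `"awake"` (HRP III), `"unclassified"`.
#' @param tol_s tolerance on the expected duration check, seconds.
#' @return list of class `segment_spec`.
#' @export
segment_spec <- function(start, end, label = "unclassified", tol_s = 1) {
  label <- match.arg(label, c("full30", "quiet", "active", "awake", "unclassified"))
  if (end <= start) stop("segment end must exceed start")
  expect <- switch(label, full30 = 1800, quiet = , active = , awake = 600, NA)
  if (!is.na(expect) && abs((end - start) - expect) > tol_s) {
    stop(sprintf("segment labelled '%s' must span %g s, got %g s",
                 label, expect, end - start))
  }
  structure(list(start = start, end = end, label = label),
            class = "segment_spec")
}

#' Extract a time segment from a series
#'
#' Retains intervals whose onset lies in `[start, end)` and re-references
#' times to the segment start.
#'
#' @param x an `nn_series`.
#' @param spec a [segment_spec()], or a numeric `c(start, end)`.
#' @return An `nn_series` covering the segment.
#' @export
extract_segment <- function(x, spec) {
  if (is.numeric(spec)) spec <- list(start = spec[1], end = spec[2], label = "unclassified")
  dur <- attr(x, "duration_s")
  if (spec$start < 0 || spec$start >= dur) {
    stop(sprintf("segment [%g, %g) outside recording of %g s", spec$start, spec$end, dur))
  }
  keep <- x$time_s >= spec$start & x$time_s < spec$end
  if (!any(keep)) stop("segment contains no beats")
  out <- nn_series(x$time_s[keep] - spec$start, x$nn_ms[keep],
                   valid = x$valid[keep], recording_id = x$recording_id,
                   wga = x$wga, movement_count = x$movement_count,
                   check_times = FALSE)
  attr(out, "segment_label") <- spec$label
  out
}
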