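#' Acceleration / deceleration detection rule sets
#'
#' Three rule sets are used in different parts of the methodology:
#' \describe{
#'   \item{`ctg_dawes`}{CTG definitions. AC: heart rate more than 10 bpm
#'     above baseline for more than 15 s. DC: below baseline for more than
#'     30 s with a deviation above 20 bpm, or for more than 60 s with a
#'     deviation above 10 bpm.}
#'   \item{`state_classification`}{AC for behavioral-state rules: more than
#'     15 bpm above baseline for more than 15 s. DC as `ctg_dawes`.}
#'   \item{`pattern_10bpm`}{any excursion beyond 10 bpm from baseline, in
#'     either direction, with no duration minimum; used by the quiet-sleep
#'     pattern segmentation.}
#' }
#' @name event_rules
NULL

.event_rules <- list(
  ctg_dawes = list(ac_gate = 10, ac_min_dur = 15, dc_gate = 10,
                   dc_qualify = function(dur, depth) {
                     (dur > 30 & depth > 20) | (dur > 60 & depth > 10)
                   }),
  state_classification = list(ac_gate = 15, ac_min_dur = 15, dc_gate = 10,
                              dc_qualify = function(dur, depth) {
                                (dur > 30 & depth > 20) | (dur > 60 & depth > 10)
                              }),
  pattern_10bpm = list(ac_gate = 10, ac_min_dur = 0, dc_gate = 10,
                       dc_qualify = function(dur, depth) depth > 10)
)

.empty_events <- function(rule_set) {
  structure(data.frame(kind = character(), onset_s = numeric(),
                       duration_s = numeric(), peak_deviation_bpm = numeric(),
                       lost_beats = numeric()),
            rule_set = rule_set, class = c("event_list", "data.frame"))
}

# run finder on a (possibly irregular) sampled deviation series; dt gives the
# duration each sample represents. Candidate runs of the same kind separated
# by a gap shorter than merge_gap_s are merged before the duration/deviation
# gates are applied: a brief return toward baseline does not terminate an
# excursion. Lost beats = time integral of the bpm deficit below baseline
# over the event, divided by 60 s/min.
.detect_runs <- function(time_s, dev, dt, rule_set, merge_gap_s = 5) {
  rule <- .event_rules[[rule_set]]
  out <- list()
  scan <- function(mask, kind) {
    mask[is.na(mask)] <- FALSE
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ki <- which(r$values)
    if (length(ki) == 0) return(invisible())
    spans <- cbind(starts[ki], ends[ki])
    merged <- spans[1, , drop = FALSE]
    if (nrow(spans) > 1) {
      for (k in 2:nrow(spans)) {
        gap_idx <- (merged[nrow(merged), 2] + 1L):(spans[k, 1] - 1L)
        if (sum(dt[gap_idx]) < merge_gap_s) {
          merged[nrow(merged), 2] <- spans[k, 2]
        } else merged <- rbind(merged, spans[k, ])
      }
    }
    for (k in seq_len(nrow(merged))) {
      idx <- merged[k, 1]:merged[k, 2]
      dur <- sum(dt[idx])
      depth <- max(abs(dev[idx]), na.rm = TRUE)  # artifact samples carry NA
      keep <- if (kind == "AC") dur > rule$ac_min_dur else rule$dc_qualify(dur, depth)
      if (!keep) next
      excur <- if (kind == "DC") pmax(-dev[idx], 0) else pmax(dev[idx], 0)
      excur[is.na(excur)] <- 0
      lost <- if (kind == "DC") sum(excur * dt[idx]) / 60 else NA_real_
      out[[length(out) + 1L]] <<- data.frame(
        kind = kind, onset_s = time_s[idx[1]], duration_s = dur,
        peak_deviation_bpm = depth, lost_beats = lost)
    }
  }
  scan(dev > rule$ac_gate, "AC")
  scan(dev < -rule$dc_gate, "DC")
  if (length(out) == 0) return(.empty_events(rule_set))
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, rule_set = rule_set, class = c("event_list", "data.frame"))
}

#' Detect accelerations and decelerations against a baseline
#'
#' Contiguous runs of the heart rate deviation beyond the rule set's gate
#' become candidate events; a candidate qualifies by the rule set's
#' duration/deviation thresholds (see [event_rules]). For decelerations the
#' lost-beats measure is the time integral of the bpm deficit below the
#' baseline over the event, in beats.
#'
#' @param x an `epoch_series`, or a data frame with `time_s` and `bpm`
#'   (e.g. from [instantaneous_hr()]).
#' @param baseline a `baseline_series` (for epochs) or a numeric bpm vector
#'   aligned with `x`.
#' @param rule_set one of `"ctg_dawes"`, `"state_classification"`,
#'   `"pattern_10bpm"`.
#' @return data frame of class `event_list` with columns `kind`, `onset_s`,
#'   `duration_s`, `peak_deviation_bpm`, `lost_beats`, and attribute
#'   `rule_set`.
#' @export
detect_events <- function(x, baseline,
                          rule_set = c("ctg_dawes", "state_classification",
                                       "pattern_10bpm")) {
  rule_set <- match.arg(rule_set)
  if (inherits(x, "epoch_series")) {
    b <- if (inherits(baseline, "baseline_series")) baseline$values else baseline
    hr <- 60000 / x$values
    dev <- hr - b
    dt <- rep(x$epoch_s, x$n_epochs)
    return(.detect_runs(x$time_s, dev, dt, rule_set))
  }
  b <- if (inherits(baseline, "baseline_series")) baseline$values else baseline
  dev <- x$bpm - b
  # beat-level series carry white interval jitter that fragments excursion
  # runs; a short median filter (~2 s) restores the trace a clinician reads
  if (length(dev) >= 5) dev <- stats::runmed(dev, 5, endrule = "median")
  dt <- diff(c(x$time_s, x$time_s[length(x$time_s)] +
                 stats::median(diff(x$time_s))))
  .detect_runs(x$time_s, dev, dt, rule_set)
}
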