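#' Classify a 10-minute window into a heart rate pattern (HRP)
#'
#' Transparent rule engine operationalising the written behavioral-state
#' criteria; the reference standard is an expert consensus, so every
#' evidence number is exported and a manual annotation can overrule the
#' classifier (see [select_segments()]).
#'
#' Rules, evaluated on the deviation of the instantaneous heart rate from
#' the floating baseline with samples inside AC/DC events excluded:
#' \itemize{
#'   \item HRP I (quiet sleep): floating-baseline drift below 10 bpm per
#'     3 min, oscillation bandwidth below +/-5 bpm, at most 2 AC
#'     (>15 bpm over >15 s), baseline never above 160 bpm.
#'   \item HRP II (active sleep): bandwidth above +/-5 bpm, at least 3 AC,
#'     heart rate above 160 bpm only inside AC.
#'   \item HRP III (active awakeness): more than `tachy_min_s` seconds
#'     above 160 bpm outside AC (long-lasting, frequently fused AC).
#' }
#' Bandwidth is half the 2.5th-97.5th percentile span of the deviation
#' (robust to isolated spikes), measured outside AC/DC complexes: every
#' excursion beyond 10 bpm (any duration) is masked together with a
#' `pad_s` shoulder on each side, mirroring how a clinician reads the
#' oscillation band between complexes. The rules are evaluated as
#' exclusive hits: exactly one rule firing gives its label, anything else
#' is unclassified. The HRP II and III tachycardia gates are complementary
#' at `tachy_min_s`: brief crossings of 160 bpm leave a window in HRP II,
#' sustained ones make it HRP III.
#'
#' @param hr data frame `time_s`, `bpm` covering exactly the window.
#' @param baseline floating-baseline bpm aligned with `hr` (see
#'   [floating_baseline()]).
#' @param events `event_list` under `state_classification` rules for this
#'   window (used for the AC count).
#' @param window_s expected window length, default 600 s (checked against
#'   the data span with 10% slack).
#' @param tachy_min_s threshold on time above 160 bpm outside AC separating
#'   HRP II from HRP III, seconds (default 60).
#' @param pad_s shoulder padding around masked excursions, seconds
#'   (default 10).
#' @return list of class `hrp_classification`: `label` (one of `HRP_I`,
#'   `HRP_II`, `HRP_III`, `unclassified`) and `evidence` (drift, bandwidth,
#'   AC count, time above 160 bpm, max baseline).
#' @export
classify_hrp <- function(hr, baseline, events, window_s = 600,
                         tachy_min_s = 60, pad_s = 10) {
  span <- diff(range(hr$time_s))
  if (abs(span - window_s) > 0.1 * window_s) {
    stop(sprintf("window spans %.0f s; expected %.0f s", span, window_s))
  }
  dt <- diff(c(hr$time_s, hr$time_s[nrow(hr)] + stats::median(diff(hr$time_s))))
  # the written rules describe the smoothed trace a clinician reads, so the
  # bandwidth and tachycardia checks use a ~2 s median-filtered heart rate
  bpm_s <- if (nrow(hr) >= 5) stats::runmed(hr$bpm, 5, endrule = "median") else hr$bpm
  dev <- bpm_s - baseline
  span_mask <- function(onsets, durs, pad) {
    m <- rep(FALSE, nrow(hr))
    for (k in seq_along(onsets)) {
      m <- m | (hr$time_s >= onsets[k] - pad & hr$time_s < onsets[k] + durs[k] + pad)
    }
    m
  }
  in_ac <- span_mask(events$onset_s, events$duration_s, 0)
  in_excl <- span_mask(events$onset_s, events$duration_s, pad_s)
  exc <- .detect_runs(hr$time_s, dev, dt, "pattern_10bpm")
  in_excl <- in_excl | span_mask(exc$onset_s, exc$duration_s, pad_s)
  q <- stats::quantile(dev[!in_excl], c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  bandwidth <- (q[2] - q[1]) / 2
  # worst-case baseline excursion over any 3-minute lag
  grid <- seq(min(hr$time_s), max(hr$time_s), by = 1)
  bg <- stats::approx(hr$time_s, baseline, xout = grid, rule = 2)$y
  drift <- if (length(bg) > 180) max(abs(bg[-(1:180)] - bg[seq_len(length(bg) - 180)])) else 0
  n_ac <- sum(events$kind == "AC")
  t_above <- sum(dt[bpm_s > 160 & !in_ac])
  ev <- list(baseline_drift_bpm_per_3min = drift, bandwidth_bpm = bandwidth,
             n_ac = n_ac, time_above_160_s = t_above,
             baseline_max_bpm = max(baseline))
  hit_i <- drift < 10 && bandwidth < 5 && n_ac <= 2 && max(baseline) <= 160 &&
    t_above <= tachy_min_s
  hit_iii <- t_above > tachy_min_s
  hit_ii <- bandwidth > 5 && n_ac >= 3 && t_above <= tachy_min_s
  hits <- c(HRP_I = hit_i, HRP_III = hit_iii, HRP_II = hit_ii)
  label <- if (sum(hits) == 1) names(hits)[hits] else "unclassified"
  structure(list(label = label, evidence = ev), class = "hrp_classification")
}

#' Select quiet- and active-sleep analysis segments from a recording
#'
#' Slides a 10-minute window over the recording in 1-minute steps,
#' classifies each window with [classify_hrp()], and keeps at most one
#' segment per state: for HRP I the window with the smallest oscillation
#' bandwidth, for HRP II the one with the largest (ties go to the earliest
#' window). A manual annotation list, when supplied, bypasses the
#' classifier entirely.
#'
#' @param x an `nn_series` (typically 30 min).
#' @param step_s window step, seconds (default 60).
#' @param annotations optional list of `list(start_s, end_s, label)` with
#'   labels `"quiet"`/`"active"` that overrides classification.
#' @return list with `segments` (named list `quiet`/`active` of
#'   [segment_spec()]s, either may be absent) and `windows` (data frame of
#'   all window classifications with evidence).
#' @export
select_segments <- function(x, step_s = 60, annotations = NULL) {
  if (!is.null(annotations)) {
    segs <- list()
    for (a in annotations) {
      lab <- match.arg(a$label, c("quiet", "active"))
      segs[[lab]] <- segment_spec(a$start_s, a$end_s, lab)
    }
    return(list(segments = segs, windows = NULL))
  }
  hr <- instantaneous_hr(x)
  base <- floating_baseline(hr)
  events <- detect_events(hr, base, "state_classification")
  dur <- attr(x, "duration_s")
  starts <- seq(0, dur - 600 + step_s / 2, by = step_s)
  rows <- lapply(starts, function(s) {
    w <- hr$time_s >= s & hr$time_s < s + 600
    ew <- events[events$onset_s < s + 600 &
                   events$onset_s + events$duration_s > s, , drop = FALSE]
    cl <- classify_hrp(hr[w, , drop = FALSE], base[w], ew)
    data.frame(start_s = s, end_s = s + 600, label = cl$label,
               bandwidth_bpm = cl$evidence$bandwidth_bpm,
               drift_bpm = cl$evidence$baseline_drift_bpm_per_3min,
               n_ac = cl$evidence$n_ac,
               time_above_160_s = cl$evidence$time_above_160_s)
  })
  windows <- do.call(rbind, rows)
  segs <- list()
  qi <- which(windows$label == "HRP_I")
  if (length(qi)) {
    best <- qi[which.min(windows$bandwidth_bpm[qi])]
    segs$quiet <- segment_spec(windows$start_s[best], windows$end_s[best], "quiet")
  }
  ai <- which(windows$label == "HRP_II")
  if (length(ai)) {
    best <- ai[which.max(windows$bandwidth_bpm[ai])]
    segs$active <- segment_spec(windows$start_s[best], windows$end_s[best], "active")
  }
  list(segments = segs, windows = windows)
}
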