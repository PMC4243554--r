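#' End-to-end analysis of one recording
#'
#' Runs the full methodology on a single NN-interval series: epoching,
#' baseline estimation, CTG-rule AC/DC detection, STV/LTV, the
#' Dawes-Redman verdict (when the gestational age is at least 26 weeks),
#' behavioral-state segment selection, the five indices on the full
#' recording and on each selected segment, the pattern-segmented variants
#' for the quiet segment, and optionally a predicted age and normogram
#' z-score.
#'
#' @param series an `nn_series`.
#' @param refs `ltv_reference` for the criteria (`NULL` to skip the
#'   reference-dependent ones).
#' @param model optional `fabas_model` used to score the recording.
#' @param normogram optional `fabas_normogram` for the z-score.
#' @param annotations optional manual state annotation (see
#'   [select_segments()]).
#' @return nested list of class `fabas_result` with elements `recording`,
#'   `ctg` (stv/ltv/events/verdict), `segments`, `indices`,
#'   `pattern_segmented`, `score`.
#' @export
analyze_recording <- function(series, refs = fabas_reference(), model = NULL,
                              normogram = NULL, annotations = NULL) {
  epochs <- epoch_series(series)
  baseline <- estimate_baseline(epochs)
  events <- detect_events(epochs, baseline, "ctg_dawes")
  minutes <- mark_analyzable(epochs, events)
  lt <- ltv(epochs, minutes, baseline)
  minutes <- lt$minutes
  verdict <- if (!is.na(series$wga) && series$wga >= 26) {
    evaluate_dawes_redman(series, epochs, baseline, events, episodes = NULL,
                          wga = series$wga,
                          movement_count = series$movement_count,
                          refs = refs, minutes = minutes)
  } else NULL
  sel <- select_segments(series, annotations = annotations)
  indices <- list(full30 = compute_indices(series, "full30"))
  pattern <- NULL
  for (lab in names(sel$segments)) {
    seg <- extract_segment(series, sel$segments[[lab]])
    indices[[lab]] <- compute_indices(seg, lab)
    if (lab == "quiet") {
      ws <- flag_windows(build_windows(), instantaneous_hr(seg))
      pattern <- list(windows = ws,
                      woDC = segmented_indices(seg, ws, "woDC"),
                      basic = segmented_indices(seg, ws, "basic"))
    }
  }
  score <- NULL
  if (!is.null(model)) {
    est <- predict(model, indices$full30)
    score <- list(predicted_wga = as.numeric(est),
                  family = model$family,
                  z = if (!is.null(normogram) && is.finite(est))
                    as.numeric(score_deviation(est, series$wga, normogram))
                  else NA_real_)
  }
  structure(list(
    recording = list(id = series$recording_id, wga = series$wga,
                     duration_s = attr(series, "duration_s"),
                     n_beats = length(series$nn_ms),
                     signal_loss = sum(series$nn_ms[!series$valid]) / 1000 /
                       attr(series, "duration_s")),
    ctg = list(stv_ms = as.numeric(stv(epochs, minutes)),
               ltv_ms = as.numeric(lt$ltv_ms),
               n_ac = sum(events$kind == "AC"),
               n_dc = sum(events$kind == "DC"),
               dawes_redman = if (is.null(verdict)) "not applicable below 26 weeks"
               else verdict),
    segments = sel$segments,
    indices = indices,
    pattern_segmented = pattern,
    score = score), class = "fabas_result")
}

#' Serialise an analysis result (or any package object) to JSON
#'
#' @param x a `fabas_result`, verdict, model or normogram.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(.unclass_deep(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, na = "null")
  invisible(path)
}

.unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    return(lapply(unclass(x), .unclass_deep))
  }
  if (is.data.frame(x)) return(as.data.frame(unclass(x)))
  x
}
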