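#' Configuration for the synthetic fetal recording generator
#'
#' The generator is a test fixture, not a physiological model: an AR(1)
#' process plus two band-limited sinusoids and gamma-like AC/DC bumps is
#' the minimal heart rate process that exposes all five maturation indices'
#' sensitivities (fluctuation amplitude via the modulation depth, pNN5 via
#' fast beat-to-beat jitter, VLF/LF via the band amplitudes, gMSE3 via the
#' AR coefficient, skewness via AC/DC asymmetry). Maturation maps are
#' smooth and monotone over 21-40 weeks so parameter-recovery tests have a
#' defined direction.
#'
#' @param wga gestational age in weeks (21-40).
#' @param duration_s recording length, seconds (default 1800).
#' @param seed integer seed fixing the full sample path.
#' @param ... overrides of the defaults listed below.
#' @return list of class `generator_config` with elements:
#' \describe{
#'   \item{baseline_bpm_range}{baseline heart rate at 21 and 40 weeks
#'     (default 150 down to 135 bpm).}
#'   \item{quiet_sd_bpm_range}{marginal SD of the AR(1) modulation in quiet
#'     sleep at 21/40 weeks (default 1.0 to 1.7 bpm).}
#'   \item{active_sd_mult}{active-sleep multiplier on the AR SD (3.0).}
#'   \item{ar_phi_range}{AR(1) coefficient at 21/40 weeks (0.62 to 0.95),
#'     the complexity proxy.}
#'   \item{jitter_ms_range}{SD of white beat-to-beat interval jitter at
#'     21/40 weeks (1.5 to 4 ms), the vagal/pNN5 proxy.}
#'   \item{vlf_amp_bpm, lf_amp_bpm}{amplitudes of the 0.05 and 0.15 Hz
#'     sinusoids per state (quiet 1.0/0.8 bpm at 40 weeks, active 3.0/2.5).}
#'   \item{sin_age_gain}{scale the quiet-sleep sinusoid amplitudes by
#'     `0.6 + 0.8 * a` with `a` the age fraction (default `TRUE`): the
#'     quiet-sleep modulation depth matures, while active-sleep
#'     fluctuations are large at all ages.}
#'   \item{ac_rate_per_10min, dc_rate_per_10min}{event rates per state
#'     (AC: quiet 1, active 3.5, so that any 10-min active window holds at
#'     least 3; DC: 1 in both states).}
#'   \item{ac_amp_bpm, ac_dur_s, dc_amp_bpm, dc_dur_s}{event shapes per
#'     state (AC: quiet 20 bpm/30 s, active 28 bpm/25 s; DC: 15 bpm/30 s).}
#'   \item{ac_age_gain}{multiplier on AC amplitude, `0.9 + 0.2 * a` with
#'     `a` the age fraction, part of the pattern-formation trend.}
#'   \item{dc_age_decline}{multiplier on DC amplitude, `1.2 - 0.4 * a`
#'     (default `TRUE`): decelerations are deeper in the premature fetus
#'     and decline with maturation, part of the skewness trend.}
#'   \item{poisson_events}{draw event counts from a Poisson law instead of
#'     the deterministic rounded rate (default `FALSE`: counts and spacing
#'     are regular with jitter, which keeps planted states at stable rule
#'     margins).}
#'   \item{variability_scale}{overall modulation-depth multiplier applied
#'     to the AR SD, sinusoid amplitudes and jitter (default 1).}
#'   \item{artifact_fraction}{share of recording time flagged invalid
#'     (default 0.02).}
#'   \item{schedule}{data frame `state`, `start`, `end`; default quiet
#'     `[0, 900)` then active `[900, 1800)`, truncated/recycled to the
#'     duration.}
#'   \item{individual_sd}{log-normal SD of per-recording multipliers on the
#'     maturation maps (0.08).}
#'   \item{baseline_offset_sd}{SD of the per-recording baseline heart rate
#'     offset, bpm (default 2).}
#'   \item{fs}{internal heart rate grid, Hz (4).}
#' }
#' @export
generator_config <- function(wga, duration_s = 1800, seed = 1, ...) {
  if (wga < 21 || wga > 40) stop("wga must be in [21, 40]")
  cfg <- list(
    wga = wga, duration_s = duration_s, seed = seed,
    baseline_bpm_range = c(150, 135),
    quiet_sd_bpm_range = c(0.9, 1.4),
    active_sd_mult = 3.0,
    ar_phi_range = c(0.62, 0.95),
    jitter_ms_range = c(1.5, 4.0),
    vlf_amp_bpm = c(quiet = 1.0, active = 3.0),
    lf_amp_bpm = c(quiet = 0.8, active = 2.5),
    ac_rate_per_10min = c(quiet = 1, active = 3.5),
    dc_rate_per_10min = c(quiet = 1, active = 1),
    ac_amp_bpm = c(quiet = 20, active = 28),
    ac_dur_s = c(quiet = 30, active = 25),
    dc_amp_bpm = c(quiet = 15, active = 15),
    dc_dur_s = c(quiet = 30, active = 30),
    ac_age_gain = TRUE,
    dc_age_decline = TRUE,
    sin_age_gain = TRUE,
    poisson_events = FALSE,
    variability_scale = 1,
    artifact_fraction = 0.02,
    schedule = NULL,
    individual_sd = 0.08,
    baseline_offset_sd = 2,
    fs = 4
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  if (is.null(cfg$schedule)) {
    # alternate 900 s quiet/active blocks up to the duration
    starts <- seq(0, duration_s - 1e-9, by = 900)
    cfg$schedule <- data.frame(
      state = rep(c("quiet", "active"), length.out = length(starts)),
      start = starts, end = pmin(starts + 900, duration_s))
  }
  if (max(cfg$schedule$end) < duration_s || min(cfg$schedule$start) > 0) {
    stop("schedule does not cover the recording duration")
  }
  structure(cfg, class = "generator_config")
}

# flat-topped bump for AC/DC excursions: quarter-sine ramps over the first
# and last 30% of the duration, full amplitude on the middle 40%
.bump <- function(t_grid, onset, dur, amp) {
  s <- (t_grid - onset) / dur
  out <- numeric(length(t_grid))
  ramp_in <- s > 0 & s < 0.3
  flat <- s >= 0.3 & s <= 0.7
  ramp_out <- s > 0.7 & s < 1
  out[ramp_in] <- amp * sin(pi * s[ramp_in] / 0.6)
  out[flat] <- amp
  out[ramp_out] <- amp * sin(pi * (1 - s[ramp_out]) / 0.6)
  out
}

#' Generate a seeded synthetic fetal NN-interval recording
#'
#' Builds the heart rate process on a 4 Hz grid (state-dependent AR(1)
#' modulation, 0.05/0.15 Hz sinusoids, AC/DC bumps, flagged artifact
#' spans), then derives beat times by stepping through the instantaneous
#' rate and adds white interval jitter. Deterministic given the seed.
#'
#' @param cfg a [generator_config()].
#' @return list with `series` (an `nn_series`) and `truth` (list of class
#'   `ground_truth`: `schedule`, `events` data frame with kind/state/onset/
#'   duration/amplitude, `artifact_spans`, `params`).
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  a <- (cfg$wga - 21) / 19
  lerp <- function(r) r[1] + a * (r[2] - r[1])
  ind <- exp(stats::rnorm(3, 0, cfg$individual_sd)) # per-recording multipliers
  base_bpm <- lerp(cfg$baseline_bpm_range) +
    stats::rnorm(1, 0, cfg$baseline_offset_sd)
  sd_quiet <- lerp(cfg$quiet_sd_bpm_range) * ind[1] * cfg$variability_scale
  phi <- min(0.98, lerp(cfg$ar_phi_range) * ind[2]^0.25)
  jitter <- lerp(cfg$jitter_ms_range) * ind[3] * cfg$variability_scale
  ac_gain <- if (isTRUE(cfg$ac_age_gain)) 0.9 + 0.2 * a else 1
  sin_gain <- if (isTRUE(cfg$sin_age_gain)) 0.6 + 0.8 * a else 1
  dc_gain <- if (isTRUE(cfg$dc_age_decline)) 1.2 - 0.4 * a else 1

  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  t_grid <- (seq_len(n) - 1) / fs
  sched <- cfg$schedule
  state <- character(n)
  for (k in seq_len(nrow(sched))) {
    state[t_grid >= sched$start[k] & t_grid < sched$end[k]] <- sched$state[k]
  }
  sd_marg <- ifelse(state == "active", sd_quiet * cfg$active_sd_mult, sd_quiet)
  innov <- stats::rnorm(n) * sd_marg * sqrt(1 - phi^2)
  ar <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                 init = stats::rnorm(1) * sd_marg[1]))
  ph <- stats::runif(2, 0, 2 * pi)
  vlf_a <- ifelse(state == "active", cfg$vlf_amp_bpm[["active"]],
                  cfg$vlf_amp_bpm[["quiet"]] * sin_gain) * cfg$variability_scale
  lf_a <- ifelse(state == "active", cfg$lf_amp_bpm[["active"]],
                 cfg$lf_amp_bpm[["quiet"]] * sin_gain) * cfg$variability_scale
  hr <- base_bpm + ar + vlf_a * sin(2 * pi * 0.05 * t_grid + ph[1]) +
    lf_a * sin(2 * pi * 0.15 * t_grid + ph[2])

  events <- list()
  n_events <- function(rate, len) {
    if (isTRUE(cfg$poisson_events)) stats::rpois(1, rate * len / 600) else
      round(rate * len / 600)
  }
  add_events <- function(kind, m, amp, dur, block, shift = 0) {
    len <- block$end - block$start
    if (m < 1) return(invisible())
    # evenly spaced centers with slight jitter; DC centers are offset to
    # interleave between ACs so opposite-sign bumps never cancel
    centers <- block$start +
      ((seq_len(m) - 0.5) * len / m + shift) %% len +
      stats::runif(m, -0.01, 0.01) * len / m
    for (ctr in centers) {
      onset <- max(block$start, min(ctr - dur / 2, block$end - dur))
      amp_k <- amp * stats::runif(1, 0.95, 1.05)
      events[[length(events) + 1L]] <<- data.frame(
        kind = kind, state = block$state, onset_s = onset, duration_s = dur,
        amplitude_bpm = amp_k)
    }
  }
  for (k in seq_len(nrow(sched))) {
    blk <- sched[k, ]
    st <- blk$state
    len <- blk$end - blk$start
    m_ac <- n_events(cfg$ac_rate_per_10min[[st]], len)
    m_dc <- n_events(cfg$dc_rate_per_10min[[st]], len)
    add_events("AC", m_ac, cfg$ac_amp_bpm[[st]] * ac_gain, cfg$ac_dur_s[[st]], blk)
    add_events("DC", m_dc, cfg$dc_amp_bpm[[st]] * dc_gain, cfg$dc_dur_s[[st]], blk,
               shift = if (m_ac > 0) len / (2 * m_ac) else 0)
  }
  truth_events <- if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(), state = character(), onset_s = numeric(),
               duration_s = numeric(), amplitude_bpm = numeric())
  if (nrow(truth_events)) {
    truth_events <- truth_events[order(truth_events$onset_s), ]
    rownames(truth_events) <- NULL
    for (k in seq_len(nrow(truth_events))) {
      sgn <- if (truth_events$kind[k] == "AC") 1 else -1
      hr <- hr + sgn * .bump(t_grid, truth_events$onset_s[k],
                             truth_events$duration_s[k],
                             truth_events$amplitude_bpm[k])
    }
  }
  hr <- pmax(hr, 60)

  spans <- list()
  if (cfg$artifact_fraction > 0) {
    total <- cfg$artifact_fraction * cfg$duration_s
    acc <- 0
    while (acc < total) {
      len <- stats::runif(1, 5, 15)
      s0 <- stats::runif(1, 0, cfg$duration_s - len)
      spans[[length(spans) + 1L]] <- c(s0, s0 + len)
      acc <- acc + len
    }
  }

  # beat times by stepping through the instantaneous rate
  cap <- ceiling(cfg$duration_s / 0.25)
  bt <- numeric(cap); nn <- numeric(cap)
  jit <- stats::rnorm(cap) * jitter
  t <- 0; i <- 0L
  repeat {
    idx <- min(n, floor(t * fs) + 1L)
    nn_i <- max(250, 60000 / hr[idx] + jit[i + 1L])
    if (t + nn_i / 1000 > cfg$duration_s + 1e-9) break
    i <- i + 1L
    bt[i] <- t; nn[i] <- nn_i
    t <- t + nn_i / 1000
  }
  bt <- bt[seq_len(i)]; nn <- nn[seq_len(i)]
  valid <- rep(TRUE, i)
  for (sp in spans) valid[bt >= sp[1] & bt < sp[2]] <- FALSE

  series <- nn_series(bt, nn, valid = valid,
                      recording_id = sprintf("sim_wga%g_seed%d", cfg$wga, cfg$seed),
                      wga = cfg$wga, check_times = FALSE)
  truth <- structure(list(schedule = sched, events = truth_events,
                          artifact_spans = spans,
                          params = list(baseline_bpm = base_bpm,
                                        sd_quiet_bpm = sd_quiet, phi = phi,
                                        jitter_ms = jitter, ac_gain = ac_gain)),
                     class = "ground_truth")
  list(series = series, truth = truth)
}

#' Generate a seeded synthetic cohort
#'
#' Ages are drawn uniformly over the integer weeks of `age_range`;
#' per-recording seeds derive deterministically from the master seed.
#'
#' @param n number of recordings.
#' @param age_range integer week range (default `c(21, 40)`).
#' @param seed master seed.
#' @param ... config overrides passed to every [generator_config()].
#' @return list with `recordings` (list of [generate_recording()] outputs)
#'   and `table` (data frame `recording_id`, `wga`, `seed`).
#' @export
generate_cohort <- function(n, age_range = c(21, 40), seed = 1, ...) {
  stopifnot(n >= 1)
  set.seed(seed)
  ages <- sample(seq(age_range[1], age_range[2]), n, replace = TRUE)
  seeds <- sample.int(2^31 - 2, n)
  recordings <- lapply(seq_len(n), function(i) {
    generate_recording(generator_config(wga = ages[i], seed = seeds[i], ...))
  })
  tab <- data.frame(
    recording_id = vapply(recordings, function(r) r$series$recording_id, character(1)),
    wga = ages, seed = seeds)
  list(recordings = recordings, table = tab)
}

#' Feature table of fABAS indices for a cohort
#'
#' Computes the five indices on each recording's full extent (and, when
#' requested, on classified quiet/active segments plus the pattern-
#' segmented quiet-sleep variants) into the row-per-recording table
#' consumed by [stepwise_fit()].
#'
#' @param cohort output of [generate_cohort()], or a list of `nn_series`.
#' @param segments also classify states and add per-state and
#'   pattern-segmented columns (slower; default `FALSE`).
#' @return data frame with `wga` and index columns (`amp_ms`, `skewness`,
#'   `pnn5_percent`, `ln_vlf_lf`, `gmse3`, plus `*_quiet`, `*_active`,
#'   `gmse3_wodc`, `gmse3_basic`, ... when `segments = TRUE`).
#' @export
cohort_features <- function(cohort, segments = FALSE) {
  recs <- if (!is.null(cohort$recordings)) {
    lapply(cohort$recordings, `[[`, "series")
  } else cohort
  rows <- lapply(recs, function(s) {
    iv <- compute_indices(s, "full30")
    row <- data.frame(recording_id = s$recording_id, wga = s$wga,
                      amp_ms = iv$amp_ms, skewness = iv$skewness,
                      pnn5_percent = iv$pnn5_percent, ln_vlf_lf = iv$ln_vlf_lf,
                      gmse3 = iv$gmse3)
    if (segments) {
      sel <- select_segments(s)
      for (lab in c("quiet", "active")) {
        cols <- paste0(c("skewness_", "pnn5_", "gmse3_", "amp_", "lnvlflf_"), lab)
        if (!is.null(sel$segments[[lab]])) {
          seg <- extract_segment(s, sel$segments[[lab]])
          ivs <- compute_indices(seg, lab)
          row[cols] <- c(ivs$skewness, ivs$pnn5_percent, ivs$gmse3,
                         ivs$amp_ms, ivs$ln_vlf_lf)
        } else row[cols] <- NA_real_
      }
      if (!is.null(sel$segments$quiet)) {
        seg <- extract_segment(s, sel$segments$quiet)
        ws <- flag_windows(build_windows(), instantaneous_hr(seg))
        for (m in c("woDC", "basic")) {
          si <- segmented_indices(seg, ws, m)
          suff <- if (m == "woDC") "wodc" else "basic"
          row[paste0(c("skewness_", "pnn5_", "gmse3_", "lnvlflf_"), suff)] <-
            c(as.numeric(si$skewness), as.numeric(si$pnn5_percent),
              as.numeric(si$gmse3), as.numeric(si$ln_vlf_lf))
        }
      } else {
        row[c(outer(c("skewness_", "pnn5_", "gmse3_", "lnvlflf_"),
                    c("wodc", "basic"), paste0))] <- NA_real_
      }
    }
    row
  })
  do.call(rbind, rows)
}
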