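# Beat-level fixture builders used across the suite. All fixtures are
# deterministic functions of their arguments; no files are read.

# Step through an instantaneous-rate/interval recipe to produce beat times.
# nn_fun(t) must return the interval (ms) for a beat starting at time t.
build_series <- function(duration_s, nn_fun, wga = 30, movement_count = 10L,
                         invalid_spans = list(), recording_id = "fixture") {
  cap <- ceiling(duration_s / 0.25)
  bt <- numeric(cap); nn <- numeric(cap)
  t <- 0; i <- 0L
  repeat {
    nn_i <- nn_fun(t)
    if (t + nn_i / 1000 > duration_s + 1e-9) break
    i <- i + 1L
    bt[i] <- t; nn[i] <- nn_i
    t <- t + nn_i / 1000
  }
  bt <- bt[seq_len(i)]; nn <- nn[seq_len(i)]
  valid <- rep(TRUE, i)
  for (sp in invalid_spans) valid[bt >= sp[1] & bt < sp[2]] <- FALSE
  nn_series(bt, nn, valid = valid, recording_id = recording_id, wga = wga,
            movement_count = movement_count, check_times = FALSE)
}

# fixed per-minute epoch pattern (16 epochs); zero mean, range 2 units,
# energy spread over many harmonics of the 1-minute period
.dr_pattern <- c(0, 1, -1, 0.5, -0.5, 1, -1, 0, 0.8, -0.8, 0.3, -0.3,
                 1, -1, 0.6, -0.6)

# low-STV / high-LTV construction: a minute-aligned triangle (slope
# 2.5 ms per epoch, period 2 min) keeps every minute monotone with a
# 37.5 ms range while consecutive-epoch differences stay at 2.5 ms; a
# small 0.05 Hz tone dilutes the triangle's harmonic comb so the
# sinusoidal-rhythm check stays quiet
.sweep_offset <- function(t) {
  k <- floor(t / 3.75)
  p <- k %% 32
  tri <- ifelse(p < 16, -20 + 2.5 * p, -20 + 2.5 * (32 - p))
  tri + 2.0 * sin(2 * pi * 0.05 * t)
}

# Synthetic 30-min CTG-style recording for the normality criteria.
# Baseline hr0 with a deterministic minute-periodic interval pattern
# (pattern_amp ms) giving controlled STV and minute ranges, optional
# accelerations/decelerations (bpm bumps), an optional pure sinusoidal
# interval modulation, or a slow +/-2.5 ms-per-epoch sweep.
make_dr_recording <- function(wga = 30, movement_count = 10L, hr0 = 140,
                              pattern_amp = 20,
                              acs = list(c(300, 40, 22), c(780, 40, 22), c(1260, 40, 22)),
                              dcs = list(),
                              sinus_amp_ms = 0, sinus_freq = 0.06,
                              slow_sweep = FALSE,
                              invalid_spans = list()) {
  epoch_offset <- function(t) {
    if (slow_sweep) return(.sweep_offset(t))
    k <- floor(t / 3.75)
    pattern_amp * .dr_pattern[(k %% 16) + 1]
  }
  nn_fun <- function(t) {
    hr <- hr0
    for (e in acs) hr <- hr + .bump_at(t, e[1], e[2], e[3])
    for (e in dcs) hr <- hr - .bump_at(t, e[1], e[2], e[3])
    60000 / hr + epoch_offset(t) +
      if (sinus_amp_ms > 0) sinus_amp_ms * sin(2 * pi * sinus_freq * t) else 0
  }
  build_series(1800, nn_fun, wga = wga, movement_count = movement_count,
               invalid_spans = invalid_spans, recording_id = "dr_fixture")
}

# scalar version of the generator's flat-topped bump
.bump_at <- function(t, onset, dur, amp) {
  s <- (t - onset) / dur
  if (s <= 0 || s >= 1) return(0)
  if (s < 0.3) return(amp * sin(pi * s / 0.6))
  if (s <= 0.7) return(amp)
  amp * sin(pi * (1 - s) / 0.6)
}

# constant-interval series helper
constant_series <- function(nn_ms = 500, duration_s = 600, ...) {
  build_series(duration_s, function(t) nn_ms, ...)
}

# nn_series directly from an interval vector (times derived from intervals)
series_from_nn <- function(nn_ms, ...) {
  nn_series(c(0, cumsum(nn_ms[-length(nn_ms)] / 1000)), nn_ms,
            check_times = FALSE, ...)
}
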