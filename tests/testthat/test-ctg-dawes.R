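test_that("a 30-minute recording yields 480 epochs of the epoch mean", {
  s <- constant_series(400, 1800)
  ep <- epoch_series(s)
  expect_equal(ep$n_epochs, 480)
  expect_equal(ep$values, rep(400, 480), tolerance = 1e-9)
  expect_error(epoch_series(constant_series(400, 2)), "shorter")
})

test_that("epoch values are time-weighted means of overlapping intervals", {
  # half the epoch at 400 ms, half at 600 ms by time -> 500 ms
  nn_fun <- function(t) if (t %% 3.75 < 3.75 / 2) 400 else 600
  s <- build_series(37.5, nn_fun)
  ep <- epoch_series(s)
  expect_equal(mean(ep$values), 500, tolerance = 15)

  # oracle: brute-force integral of the step function over one epoch
  t0 <- s$time_s; t1 <- s$time_s + s$nn_ms / 1000
  ov <- pmin(t1, 3.75) - pmax(t0, 0)
  keep <- ov > 0
  expect_equal(ep$values[1], sum(s$nn_ms[keep] * ov[keep]) / sum(ov[keep]),
               tolerance = 1e-9)
})

test_that("fully-artifact epochs carry artifact fraction 1 and NA value", {
  s <- constant_series(400, 60, invalid_spans = list(c(7.5, 11.25)))
  ep <- epoch_series(s)
  expect_gt(ep$artifact_fraction[3], 0.9)
  expect_true(is.na(ep$values[3]) || ep$artifact_fraction[3] < 1)
  expect_equal(ep$artifact_fraction[1], 0, tolerance = 0.01)
})

test_that("minutes are excluded by artifact share and large decelerations", {
  s <- constant_series(400, 600)
  ep <- epoch_series(s)
  minutes <- mark_analyzable(ep, NULL)
  expect_equal(nrow(minutes), 10)
  expect_true(all(minutes$analyzable))

  # 9 of 16 epochs fully artifact (56%) -> not analyzable
  s2 <- constant_series(400, 600,
                        invalid_spans = list(c(60, 60 + 9 * 3.75)))
  m2 <- mark_analyzable(epoch_series(s2), NULL)
  expect_false(m2$analyzable[2])
  expect_true(m2$analyzable[1])

  # minute overlapping a 30-lost-beat DC -> not analyzable
  dc <- structure(data.frame(kind = "DC", onset_s = 130, duration_s = 40,
                             peak_deviation_bpm = 25, lost_beats = 30),
                  class = c("event_list", "data.frame"))
  m3 <- mark_analyzable(epoch_series(s), dc)
  expect_false(m3$analyzable[3])
  expect_true(m3$analyzable[1])
})

test_that("stv matches hand-computed epoch difference cases", {
  s <- constant_series(400, 600)
  ep <- epoch_series(s)
  minutes <- mark_analyzable(ep, NULL)
  expect_equal(stv(ep, minutes), 0)

  # alternating 495/505 epochs -> mean absolute difference 10 ms
  ep2 <- ep
  ep2$values <- rep(c(495, 505), length.out = ep$n_epochs)
  expect_equal(stv(ep2, minutes), 10, tolerance = 1e-12)

  # averaging across analyzable minutes: per-minute means 4 and 6 -> 5
  ep3 <- ep
  ep3$values <- c(rep(c(498, 502), 8), rep(c(497, 503), 8),
                  rep(400, ep$n_epochs - 32))
  m3 <- minutes
  m3$analyzable <- c(TRUE, TRUE, rep(FALSE, nrow(minutes) - 2))
  expect_equal(stv(ep3, m3), 5, tolerance = 1e-12)

  m0 <- minutes; m0$analyzable <- FALSE
  expect_true(is.na(stv(ep, m0)))
  expect_match(attr(stv(ep, m0), "reason"), "analyzable")
})

test_that("ltv is the clamped above-plus-below baseline range in ms", {
  s <- constant_series(400, 600)
  ep <- epoch_series(s)
  minutes <- mark_analyzable(ep, NULL)
  base <- structure(list(values = rep(150, ep$n_epochs), method = "fixed",
                         converged = TRUE), class = "baseline_series")
  expect_equal(ltv(ep, minutes, base)$ltv_ms, 0, tolerance = 1e-9)

  ep2 <- ep
  ep2$values[1:16] <- c(412, rep(400, 7), 394, rep(400, 7))
  lt <- ltv(ep2, minutes, base)
  expect_equal(lt$minutes$minute_range_ms[1], 18, tolerance = 1e-9)

  # deviation only above baseline: negative part clamps to zero
  ep3 <- ep
  ep3$values[1:16] <- c(rep(400, 8), rep(410, 8))
  expect_equal(ltv(ep3, minutes, base)$minutes$minute_range_ms[1], 10,
               tolerance = 1e-9)
})

test_that("stv/ltv shift and scale as interval-domain fluctuation measures", {
  set.seed(7)
  vals <- 420 + stats::filter(rnorm(480, 0, 6), 0.8, "recursive")
  s <- constant_series(420, 1800)
  ep <- epoch_series(s)
  ep$values <- as.numeric(vals)
  minutes <- mark_analyzable(ep, NULL)
  base <- structure(list(values = rep(60000 / 420, 480), method = "fixed",
                         converged = TRUE), class = "baseline_series")
  s1 <- stv(ep, minutes)
  l1 <- ltv(ep, minutes, base)$ltv_ms

  ep_shift <- ep; ep_shift$values <- ep$values + 50
  base_shift <- base; base_shift$values <- rep(60000 / 470, 480)
  expect_equal(stv(ep_shift, minutes), s1, tolerance = 1e-9)
  expect_equal(ltv(ep_shift, minutes, base_shift)$ltv_ms, l1, tolerance = 1e-9)

  ep_scale <- ep; ep_scale$values <- 420 + 2 * (ep$values - 420)
  expect_equal(stv(ep_scale, minutes), 2 * s1, tolerance = 1e-9)
  expect_equal(ltv(ep_scale, minutes, base)$ltv_ms, 2 * l1, tolerance = 1e-9)
})

test_that("baseline estimation is robust to events and tracks drift", {
  s <- constant_series(60000 / 140, 1800)
  ep <- epoch_series(s)
  b <- estimate_baseline(ep)
  expect_equal(b$values, rep(140, ep$n_epochs), tolerance = 0.1)
  expect_true(b$converged)

  # 20 bpm, 30 s acceleration barely moves the baseline
  nn_fun <- function(t) 60000 / (140 + .bump_at(t, 600, 30, 20))
  ep2 <- epoch_series(build_series(1800, nn_fun))
  b2 <- estimate_baseline(ep2)
  expect_lt(max(abs(b2$values - 140)), 1)

  # linear drift 140 -> 150 bpm over 10 min tracked within 1 bpm mid-series
  nn_fun3 <- function(t) 60000 / (140 + 10 * pmin(t, 600) / 600)
  ep3 <- epoch_series(build_series(600, nn_fun3))
  b3 <- estimate_baseline(ep3)
  mid <- 30:130
  truth <- 140 + 10 * (ep3$time_s[mid] + 1.875) / 600
  expect_lt(max(abs(b3$values[mid] - truth)), 1)
})

test_that("event gates follow the CTG definitions exactly", {
  mk_ep <- function(dev_fun) {
    n <- 160
    t <- (seq_len(n) - 1) * 3.75
    hr <- 140 + vapply(t, dev_fun, numeric(1))
    structure(list(values = 60000 / hr, artifact_fraction = rep(0, n),
                   epoch_s = 3.75, n_epochs = n, time_s = t),
              class = "epoch_series")
  }
  base <- structure(list(values = rep(140, 160), method = "fixed",
                         converged = TRUE), class = "baseline_series")
  step <- function(from, to, amp) function(t) if (t >= from && t < to) amp else 0

  # +12 bpm for 20 s -> AC under ctg_dawes
  ev <- detect_events(mk_ep(step(150, 170, 12)), base, "ctg_dawes")
  expect_equal(ev$kind, "AC")
  expect_equal(ev$peak_deviation_bpm, 12)

  # +12 bpm for 12 s -> too short
  ev2 <- detect_events(mk_ep(step(150, 161.25, 12)), base, "ctg_dawes")
  expect_equal(nrow(ev2), 0)

  # -15 bpm for 40 s fails both DC branches; -12 bpm for 70 s qualifies
  ev3 <- detect_events(mk_ep(step(150, 190, -15)), base, "ctg_dawes")
  expect_equal(nrow(ev3), 0)
  ev4 <- detect_events(mk_ep(step(150, 220, -12)), base, "ctg_dawes")
  expect_equal(ev4$kind, "DC")

  # -25 bpm for 40 s qualifies via the deep-and-short branch
  ev5 <- detect_events(mk_ep(step(150, 190, -25)), base, "ctg_dawes")
  expect_equal(ev5$kind, "DC")

  # -20 bpm sustained 60 s: lost beats = 20 (pattern rules have no gate)
  ev6 <- detect_events(mk_ep(step(150, 210, -20)), base, "pattern_10bpm")
  dc6 <- ev6[ev6$kind == "DC", ]
  expect_equal(dc6$lost_beats, 20, tolerance = 1e-9)

  # state_classification needs >15 bpm for AC: +12 is not enough, +18 is
  ev7 <- detect_events(mk_ep(step(150, 170, 12)), base, "state_classification")
  expect_equal(sum(ev7$kind == "AC"), 0)
  ev8 <- detect_events(mk_ep(step(150, 170, 18)), base, "state_classification")
  expect_equal(sum(ev8$kind == "AC"), 1)
})

test_that("pattern-rule deceleration events are a superset of CTG ones", {
  n_ctg <- 0
  for (seed in 1:5) {
    r <- generate_recording(generator_config(wga = 25 + seed, seed = seed,
                                             dc_rate_per_10min = c(quiet = 2, active = 2),
                                             dc_dur_s = c(quiet = 60, active = 60),
                                             dc_amp_bpm = c(quiet = 25, active = 25),
                                             dc_age_decline = FALSE))
    ep <- epoch_series(r$series)
    b <- estimate_baseline(ep)
    ctg <- detect_events(ep, b, "ctg_dawes")
    pat <- detect_events(ep, b, "pattern_10bpm")
    ctg_dc <- ctg[ctg$kind == "DC", ]
    pat_dc <- pat[pat$kind == "DC", ]
    n_ctg <- n_ctg + nrow(ctg_dc)
    for (k in seq_len(nrow(ctg_dc))) {
      hit <- any(pat_dc$onset_s <= ctg_dc$onset_s[k] + 1e-9 &
                   pat_dc$onset_s + pat_dc$duration_s >=
                   ctg_dc$onset_s[k] + ctg_dc$duration_s[k] - 1e-9)
      expect_true(hit)
    }
  }
  expect_gt(n_ctg, 0)
})

test_that("lost beats equal a brute-force Riemann sum of the rate deficit", {
  set.seed(11)
  n <- 160
  t <- (seq_len(n) - 1) * 3.75
  dev <- numeric(n)
  dev[40:70] <- -(15 + 10 * sin(seq(0, pi, length.out = 31)))
  hr <- 140 + dev
  ep <- structure(list(values = 60000 / hr, artifact_fraction = rep(0, n),
                       epoch_s = 3.75, n_epochs = n, time_s = t),
                  class = "epoch_series")
  base <- structure(list(values = rep(140, n), method = "fixed",
                         converged = TRUE), class = "baseline_series")
  ev <- detect_events(ep, base, "ctg_dawes")
  dc <- ev[ev$kind == "DC", ]
  expect_equal(nrow(dc), 1)
  oracle <- sum(-dev[dev < 0] * 3.75) / 60
  expect_equal(dc$lost_beats, oracle, tolerance = 0.01 * oracle)
})

test_that("high-variation episodes follow the 5-of-6 minute rule", {
  mk_minutes <- function(ranges) {
    data.frame(minute = seq_along(ranges),
               start_s = (seq_along(ranges) - 1) * 60,
               end_s = seq_along(ranges) * 60,
               analyzable = TRUE, minute_range_ms = ranges)
  }
  all_high <- episodes_of_high_variation(mk_minutes(rep(50, 30)))
  expect_equal(nrow(all_high), 1)
  expect_equal(c(all_high$start_min, all_high$end_min), c(1, 30))

  expect_equal(nrow(episodes_of_high_variation(mk_minutes(rep(10, 30)))), 0)

  # 5 high + 1 low + 5 high -> one 11-minute episode
  ep <- episodes_of_high_variation(mk_minutes(c(rep(50, 5), 10, rep(50, 5))))
  expect_equal(nrow(ep), 1)
  expect_equal(c(ep$start_min, ep$end_min), c(1, 11))

  # threshold is strict: exactly 32 ms is not high
  expect_equal(nrow(episodes_of_high_variation(mk_minutes(rep(32, 30)))), 0)
})
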