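test_that("detrending removes slow structure and keeps fast structure", {
  s <- constant_series(500, 600)
  d <- detrend_nn(s)
  expect_equal(d$resid_ms, rep(0, length(d$resid_ms)), tolerance = 1e-9)

  # linear ramp: residuals vanish away from the edges
  s2 <- build_series(600, function(t) 400 + 0.1 * t)
  d2 <- detrend_nn(s2)
  core <- d2$time_s > 60 & d2$time_s < 540
  expect_lt(max(abs(d2$resid_ms[core])), 0.5)

  # slow sinusoid (period 600 s >> 60 s window) removed within 5% amplitude
  s3 <- build_series(1200, function(t) 450 + 30 * sin(2 * pi * t / 600))
  d3 <- detrend_nn(s3)
  core3 <- d3$time_s > 60 & d3$time_s < 1140
  expect_lt(max(abs(d3$resid_ms[core3])), 0.05 * 30)
})

test_that("amp is the 20-95 inter-quantile distance with oracle agreement", {
  expect_equal(amp(rep(0, 100)), 0)
  v <- seq(-50, 50, length.out = 1000)
  a <- amp(v)
  expect_equal(a, unname(quantile(v, 0.95) - quantile(v, 0.20)),
               tolerance = 1e-12)
  expect_equal(a, 75, tolerance = 0.2)
  expect_equal(amp(v + 1000), a, tolerance = 1e-9)
  expect_true(is.na(amp(rnorm(10))))
})

test_that("skewness follows the moment formula and flips with sign", {
  sym <- data.frame(bpm = rep(c(-1, 0, 1), 50) + 140)
  expect_equal(hr_skewness(sym), 0, tolerance = 1e-12)

  set.seed(3)
  v <- 140 + rnorm(500)
  v[sample(500, 25)] <- v[sample(500, 25)] - 25  # planted decelerations
  sk <- hr_skewness(data.frame(bpm = v))
  expect_lt(sk, 0)
  m <- mean(v)
  oracle <- mean((v - m)^3) / mean((v - m)^2)^1.5
  expect_equal(sk, oracle, tolerance = 1e-12)
  expect_equal(hr_skewness(data.frame(bpm = 2 * m - v)), -sk, tolerance = 1e-9)

  expect_true(is.na(hr_skewness(data.frame(bpm = rep(140, 10)))))
})

test_that("pnn5 uses a strict 5 ms threshold and skips invalid pairs", {
  expect_equal(pnn5(constant_series(500, 60)), 0)

  s <- series_from_nn(c(500, 510, 515, 515))  # diffs 10, 5, 0
  expect_equal(pnn5(s), 100 / 3, tolerance = 1e-9)

  # every difference 6 ms -> 100%
  expect_equal(pnn5(series_from_nn(500 + cumsum(rep(6, 21)) - 6)), 100)

  # invalidating a middle interval removes both adjacent pairs
  s3 <- series_from_nn(c(500, 510, 520, 530))
  expect_equal(pnn5(s3), 100)
  s3$valid[2] <- FALSE
  expect_equal(pnn5(s3), 100)  # one remaining pair (520,530)
  s4 <- series_from_nn(c(500, 510, 500))
  s4$valid[2] <- FALSE
  expect_true(is.na(pnn5(s4)))
})

test_that("spectral ratio separates VLF- from LF-dominated modulation", {
  mk <- function(freq, amp) {
    build_series(600, function(t) 430 + amp * sin(2 * pi * freq * t))
  }
  expect_gt(vlf_lf(mk(0.05, 10)), 1)
  expect_lt(vlf_lf(mk(0.15, 10)), -1)

  equal <- build_series(600, function(t) {
    430 + 10 * sin(2 * pi * 0.05 * t) + 10 * sin(2 * pi * 0.15 * t)
  })
  expect_lt(abs(vlf_lf(equal)), 0.1)

  expect_true(is.na(vlf_lf(constant_series(430, 100))))
})

test_that("coarse-graining and binning of the complexity index behave", {
  expect_equal(floor(10 / 3), 3)  # documented convention
  s <- series_from_nn(rnorm(10, 500, 5))
  g <- gmse3(s, min_n = 5)
  expect_true(is.finite(g))

  # too-short input is missing with a reason
  expect_true(is.na(gmse3(series_from_nn(rnorm(100, 500, 5)))))
  expect_match(attr(gmse3(series_from_nn(rnorm(100, 500, 5))), "reason"), "300")

  # plug-in mutual information is non-negative
  set.seed(5)
  for (k in 1:10) {
    expect_gte(gmse3(rnorm(600, 500, 5), min_n = 300), 0)
  }
})

test_that("ar(1) dependence raises the complexity index above its shuffle", {
  set.seed(21)
  wins <- vapply(1:40, function(k) {
    x <- 500 + as.numeric(stats::filter(rnorm(1000, 0, 5), 0.9, "recursive"))
    gmse3(x, min_n = 300) > gmse3(sample(x), min_n = 300)
  }, logical(1))
  expect_gte(mean(wins), 0.99)
})

test_that("rank binning makes the complexity index monotone-invariant", {
  set.seed(8)
  x <- 500 + as.numeric(stats::filter(rnorm(900, 0, 5), 0.8, "recursive"))
  # at coarse scale 1 the estimator sees the transformed values directly
  g1 <- gmse3(x, scale = 1, min_n = 300)
  expect_equal(gmse3(exp(x / 100), scale = 1, min_n = 300), g1,
               tolerance = 1e-12)
  expect_equal(gmse3(x^3, scale = 1, min_n = 300), g1, tolerance = 1e-12)
  # coarse-graining commutes with affine maps, so scale 3 is affine-invariant
  g3 <- gmse3(x, min_n = 300)
  expect_equal(gmse3(3 * x + 100, min_n = 300), g3, tolerance = 1e-12)
})

test_that("time reversal leaves the indices unchanged", {
  set.seed(13)
  nn <- 450 + as.numeric(stats::filter(rnorm(900, 0, 6), 0.7, "recursive"))
  s <- series_from_nn(nn)
  s_rev <- series_from_nn(rev(nn))
  expect_equal(pnn5(s_rev), pnn5(s), tolerance = 1e-12)
  expect_equal(amp(detrend_nn(s_rev)$resid_ms), amp(detrend_nn(s)$resid_ms),
               tolerance = 0.2)
  expect_equal(hr_skewness(s_rev), hr_skewness(s), tolerance = 1e-12)
  expect_equal(gmse3(s_rev, min_n = 300), gmse3(s, min_n = 300),
               tolerance = 1e-12)
})

test_that("index vectors populate, record reasons, and are deterministic", {
  s <- constant_series(430, 600)
  iv <- compute_indices(s, gmse_min_n = 120)
  expect_equal(iv$amp_ms, 0)
  expect_equal(iv$pnn5_percent, 0)
  expect_true(is.na(iv$skewness))
  expect_match(iv$reasons[["skewness"]], "variance")

  r <- generate_recording(generator_config(wga = 30, seed = 5))
  q <- extract_segment(r$series, c(0, 600))
  iv2 <- compute_indices(q, "quiet", gmse_min_n = 120)
  expect_true(all(is.finite(c(iv2$amp_ms, iv2$skewness, iv2$pnn5_percent,
                              iv2$ln_vlf_lf, iv2$gmse3))))
  iv3 <- compute_indices(q, "quiet", gmse_min_n = 120)
  expect_identical(iv2[1:5], iv3[1:5])
})
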