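test_that("case weights equalise the age distribution", {
  expect_equal(case_weights(c(25, 26, 27, 28)), rep(1, 4))
  expect_equal(case_weights(c(30, 30, 31)), c(0.75, 0.75, 1.5))
  w1 <- case_weights(c(30, 30, 31))
  w2 <- case_weights(rep(c(30, 30, 31), 2))
  expect_equal(w2, rep(w1, 2))
  expect_equal(mean(case_weights(sample(21:40, 200, TRUE))), 1)
  expect_error(case_weights(numeric(0)), "empty")
})

test_that("stepwise selection recovers a planted linear model", {
  set.seed(101)
  n <- 400
  df <- data.frame(x1 = rnorm(n))
  for (k in 2:6) df[[paste0("x", k)]] <- rnorm(n)
  df$wga <- 30 + 2 * df$x1 + rnorm(n, 0, 0.5)
  m <- stepwise_fit(df, paste0("x", 1:6), weights = rep(1, n))
  expect_true("x1" %in% m$predictors)
  fit <- attr(m, "fit")
  se <- summary(fit)$coefficients["x1", "Std. Error"]
  expect_lt(abs(coef(fit)[["x1"]] - 2), 1.96 * se)
  # pure-noise candidates stay out (jointly unlikely to all enter)
  expect_lt(length(m$predictors), 4)
})

test_that("quadratic terms capture a planted parabola", {
  set.seed(77)
  n <- 300
  df <- data.frame(x1 = rnorm(n, 2, 1))
  df$wga <- 30 + 1.5 * (df$x1 - 2)^2 + rnorm(n, 0, 0.5)
  mq <- stepwise_fit(df, "x1", weights = rep(1, n), quadratic = TRUE)
  expect_true("x1_sq" %in% mq$predictors)
  ml <- stepwise_fit(df, "x1", weights = rep(1, n), quadratic = FALSE)
  expect_gt(mq$adjusted_r2, ml$adjusted_r2)
})

test_that("stepwise selection reaches a fixed point", {
  set.seed(5)
  co <- generate_cohort(50, seed = 5)
  ft <- cohort_features(co)
  cand <- c("amp_ms", "skewness", "pnn5_percent", "ln_vlf_lf", "gmse3")
  m1 <- stepwise_fit(ft, cand)
  # refitting on the same data with the selected set reproduces the model
  m2 <- stepwise_fit(ft, m1$predictors)
  expect_setequal(m2$predictors, m1$predictors)
  expect_equal(m2$adjusted_r2, m1$adjusted_r2, tolerance = 1e-9)
})

test_that("constant candidates are excluded and pure noise gives intercept", {
  set.seed(9)
  df <- data.frame(wga = rnorm(50, 30), xc = 1, xn = rnorm(50))
  expect_warning(m <- stepwise_fit(df, c("xc", "xn"), weights = rep(1, 50)),
                 "constant")
  expect_false("xc" %in% m$predictors)
})

test_that("prediction reproduces training fit and flags missing inputs", {
  set.seed(31)
  co <- generate_cohort(40, seed = 31)
  ft <- cohort_features(co)
  cand <- c("amp_ms", "skewness", "pnn5_percent", "ln_vlf_lf", "gmse3")
  w <- case_weights(ft$wga)
  m <- stepwise_fit(ft, cand, weights = w)
  pred <- predict(m, ft)
  expect_equal(sum(w * (ft$wga - pred)) / sum(w), 0, tolerance = 1e-8)

  one <- as.list(ft[1, ])
  one[[m$predictors[1]]] <- NULL
  p <- predict(m, one)
  expect_true(is.na(p))
  expect_match(attr(p, "reason"), "missing predictor")

  m0 <- stepwise_fit(data.frame(wga = rnorm(30, 30), x = rnorm(30)), "x",
                     weights = rep(1, 30), p_enter = 1e-9, p_remove = 2e-9)
  expect_true(m0$intercept_only)
  expect_equal(predict(m0, list(x = 1)), unname(m0$coefficients[1]))
})

test_that("quadratic centering is applied at prediction time", {
  set.seed(55)
  df <- data.frame(x1 = rnorm(200, 3))
  df$wga <- 28 + (df$x1 - 3)^2 + rnorm(200, 0, 0.3)
  m <- stepwise_fit(df, "x1", weights = rep(1, 200), quadratic = TRUE)
  pred <- predict(m, df)
  expect_equal(unname(cor(pred, df$wga)), 1, tolerance = 0.05)
})

test_that("the stepwise model is at least as good as its univariate parts", {
  co <- generate_cohort(60, seed = 13)
  ft <- cohort_features(co)
  cand <- c("amp_ms", "skewness", "pnn5_percent", "ln_vlf_lf", "gmse3")
  w <- case_weights(ft$wga)
  m <- stepwise_fit(ft, cand, weights = w)
  for (p in m$predictors) {
    mu <- stepwise_fit(ft, p, weights = w, p_enter = 0.9999, p_remove = 1)
    expect_gte(m$adjusted_r2, mu$adjusted_r2 - 1e-9)
  }
})

test_that("normogram bins merge the sparse edges and standardise scores", {
  suppressWarnings(nm <- build_normogram(scores = c(28, 32), ages = c(30, 30.5)))
  expect_equal(nm$mean, 30)
  expect_equal(nm$sd, sd(c(28, 32)))

  ages <- c(23, 25, 30, 38, 39)
  suppressWarnings(nm2 <- build_normogram(ages, ages))
  expect_equal(nm2$bin_lo[1], 21)
  expect_equal(nm2$bin_hi[1], 24)
  expect_true(any(nm2$bin_lo == 37 & nm2$bin_hi == 40))
  expect_equal(nm2$n[nm2$bin_lo == 37], 2)

  set.seed(3)
  sc <- rnorm(40, 30, 2)
  suppressWarnings(nm3 <- build_normogram(sc, rep(30, 40)))
  expect_equal(score_deviation(nm3$mean[1], 30, nm3), 0)
  expect_equal(score_deviation(nm3$mean[1] + nm3$sd[1], 30, nm3), 1)
  # affine rescaling of all scores leaves z untouched
  suppressWarnings(nm4 <- build_normogram(3 * sc + 7, rep(30, 40)))
  expect_equal(score_deviation(3 * sc[1] + 7, 30, nm4),
               score_deviation(sc[1], 30, nm3), tolerance = 1e-9)
  expect_error(score_deviation(30, 20.5, nm3), "no normogram bin")
})
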