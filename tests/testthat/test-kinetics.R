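# Segmented regression, PRESS, model selection and the growth-model
# predictions.

test_that("noiseless piecewise data is recovered exactly", {
  bl <- biphasic_line()
  f <- fit_piecewise_linear(bl$t, bl$y, 2)
  expect_equal(f$sse, 0, tolerance = 1e-12)
  expect_equal(f$slopes, c(88, 19), tolerance = 1e-9)
  expect_equal(f$breakpoints, 13.5, tolerance = 1e-9)

  # collinear data: slope exact, R2 = 1; a second segment is degenerate
  t <- seq(0, 30, by = 3)
  y <- 0.01 + 0.056 * t
  f1 <- fit_piecewise_linear(t, y, 1)
  expect_equal(f1$slopes, 56, tolerance = 1e-9)
  expect_equal(f1$r2, 1)
  f2 <- fit_piecewise_linear(t, y, 2)
  expect_equal(f2$sse, 0, tolerance = 1e-12)
  expect_equal(f2$slopes[1], f2$slopes[2], tolerance = 1e-6)
})

test_that("slope units round-trip between um/min and nm/min exactly", {
  t <- seq(0, 30, by = 3)
  f <- fit_piecewise_linear(t, 0.056 * t, 1)
  expect_equal(f$slopes[1] / 1000, 0.056, tolerance = 1e-9)
})

test_that("too few points is rejected with an informative error", {
  expect_error(fit_piecewise_linear(1:5, rnorm(5), 2), "at least 6")
  expect_error(fit_piecewise_linear(1:8, rnorm(8), 3), "at least 9")
})

test_that("adjusted R2 follows the penalised formula with p = 2k", {
  set.seed(1)
  t <- seq(0, 42, by = 3)
  y <- 0.05 * t + rnorm(length(t), 0, 0.05)
  f1 <- fit_piecewise_linear(t, y, 1)
  n <- length(t)
  expect_equal(adjusted_r2(f1), 1 - (1 - f1$r2) * (n - 1) / (n - 2 - 1))
  f2 <- fit_piecewise_linear(t, y, 2)
  expect_equal(adjusted_r2(f2), 1 - (1 - f2$r2) * (n - 1) / (n - 4 - 1))
  expect_equal(adjusted_r2(fit_piecewise_linear(t, 0.05 * t, 1)), 1)
  # a segment that buys almost no SSE drops the adjusted R2
  expect_lt(adjusted_r2(f2) - adjusted_r2(f1), 0.05)
  expect_error(adjusted_r2(fit_piecewise_linear(1:3, c(1, 2, 3.1), 1)),
               "undefined")
})

test_that("PRESS matches an independent leave-one-out oracle", {
  set.seed(7)
  t <- seq(0, 42, by = 3)
  y <- 0.056 * t + rnorm(length(t), 0, 0.1)
  naive <- function(tt, yy, k) {
    tot <- 0
    for (i in seq_along(tt)) {
      t2 <- tt[-i]; y2 <- yy[-i]
      best <- Inf; bb <- NULL
      if (k == 1) {
        cf <- stats::lm.fit(cbind(1, t2), y2)$coefficients
        pred <- cf[1] + cf[2] * tt[i]
      } else {
        n <- length(t2)
        mids <- (t2[-n] + t2[-1]) / 2
        cand <- mids[seq_along(mids) >= 3 & (n - seq_along(mids)) >= 3]
        for (b in cand) {
          X <- cbind(1, t2, pmax(t2 - b, 0))
          s <- sum(stats::lm.fit(X, y2)$residuals^2)
          if (s < best - 1e-12) { best <- s; bb <- b }
        }
        X <- cbind(1, t2, pmax(t2 - bb, 0))
        cf <- stats::lm.fit(X, y2)$coefficients
        pred <- cf[1] + cf[2] * tt[i] + cf[3] * max(tt[i] - bb, 0)
      }
      tot <- tot + (yy[i] - unname(pred))^2
    }
    tot
  }
  expect_equal(as.numeric(press_statistic(t, y, 1)), naive(t, y, 1))
  expect_equal(as.numeric(press_statistic(t, y, 2)), naive(t, y, 2))
})

test_that("PRESS behaves: zero on collinear data, dominates SSE, ranks models", {
  t <- seq(0, 30, by = 3)
  expect_equal(as.numeric(press_statistic(t, 0.056 * t, 1)), 0,
               tolerance = 1e-18)
  bl <- biphasic_line()
  expect_gt(as.numeric(press_statistic(bl$t, bl$y, 1)),
            as.numeric(press_statistic(bl$t, bl$y, 2)))
  set.seed(11)
  for (rep in 1:8) {
    tt <- seq(0, 3 * (sample(9:16, 1) - 1), by = 3)
    yy <- cumsum(runif(length(tt), 0, 0.2)) + rnorm(length(tt), 0, 0.05)
    for (k in 1:2) {
      f <- fit_piecewise_linear(tt, yy, k)
      expect_gte(as.numeric(press_statistic(tt, yy, k)), f$sse - 1e-10)
    }
  }
})

test_that("exhaustive scan equals the brute-force oracle on random data", {
  set.seed(42)
  for (rep in 1:12) {
    n <- sample(9:18, 1)
    tt <- sort(sample(seq(0, 90, 3), n))
    yy <- cumsum(runif(n, 0, 0.2))
    for (k in 2:3) {
      if (n < 3 * k) next
      f <- fit_piecewise_linear(tt, yy, k)
      expect_equal(f$sse, oracle_best_sse(tt, yy, k),
                   tolerance = 1e-7, ignore_attr = TRUE)
    }
  }
})

test_that("SSE is non-increasing in the number of segments", {
  set.seed(5)
  for (rep in 1:6) {
    tt <- seq(0, 42, by = 3)
    yy <- cumsum(runif(length(tt), 0, 0.15))
    sses <- vapply(1:3, function(k)
      fit_piecewise_linear(tt, yy, k)$sse, numeric(1))
    expect_true(all(diff(sses) <= 1e-10))
  }
})

test_that("model selection labels clean mono- and biphasic growth correctly", {
  t <- seq(0, 30, by = 3)
  kin1 <- fit_sc_kinetics(t, 0.056 * t)
  expect_equal(kin1$best$n_segments, 1L)
  expect_equal(kin1$phasic, "monophasic")

  bl <- biphasic_line()
  kin2 <- fit_sc_kinetics(bl$t, bl$y)
  expect_equal(kin2$best$n_segments, 2L)
  expect_equal(kin2$phasic, "biphasic")
  expect_equal(kin2$initial_rate, 88, tolerance = 1e-6)
  expect_equal(kin2$second_rate, 19, tolerance = 1e-6)
  # phase-1 share of final length for this geometry
  expect_equal(kin2$phase1_length_fraction,
               (88 * 13.5) / (88 * 13.5 + 19 * (42 - 13.5)),
               tolerance = 1e-6)
})

test_that("selection is robust to noise on monophasic growth", {
  n_mono <- 0
  for (s in 1:200) {
    tr <- simulate_trajectory(kinetic_model("x", phases = list(c(56, 42))),
                              3, noise_sd = 0.1, seed = s)
    if (fit_sc_kinetics(tr)$phasic == "monophasic") n_mono <- n_mono + 1
  }
  expect_gte(n_mono / 200, 0.9)
})

test_that("biphasic slope recovery is accurate across a synthetic cohort", {
  # population truth: rates N(88, 42^2) then N(19, 12^2), sigma 0.05 um
  co <- simulate_assembly_cohort(n = 60, mono_fraction = 0, seed = 19)
  fits <- fit_cohort(co, "assembly")
  bi <- fits$phasic == "biphasic"
  err1 <- abs(fits$initial_rate[bi] - co$truth$rate1[bi]) /
    co$truth$rate1[bi]
  expect_lt(mean(err1), 0.15)
})

test_that("logarithmic fits rank below segmented fits on biphasic data", {
  t <- seq(3, 45, by = 3)
  y_log <- 0.2 + 0.5 * log(t)
  expect_equal(fit_log_model(t, y_log), 1, tolerance = 1e-9)
  bl <- biphasic_line()
  kin <- fit_sc_kinetics(bl$t, bl$y)
  expect_gt(max(kin$candidates$adj_r2), fit_log_model(bl$t, bl$y))
  expect_equal(fit_log_model(t, rep(1.5, length(t))), 0)
})

test_that("bidirectional growth predicts a 50% second-phase rate", {
  p <- bidirectional_prediction(0.3)
  expect_equal(p$rate_ratio, 0.5)
  expect_equal(bidirectional_prediction(0.12)$rate_ratio, 0.5)
  # observed second/initial ratio from the fitted population means sits
  # well below the equal-tip-rate prediction
  expect_equal(19 / 88, 0.2159, tolerance = 1e-3)
  expect_lt(19 / 88, 0.5)
  # metacentric chromosome: no second phase at all
  expect_equal(bidirectional_prediction(0.5)$phase2_time_fraction, 0)
  expect_error(bidirectional_prediction(0.6))
  expect_error(bidirectional_prediction(0))
})

test_that("disassembly rate extraction treats a slow lead-in as lag", {
  # -5 nm/min lag for 12.75 min, then -66 nm/min (kink on a midpoint)
  t <- seq(0, 40.5, by = 1.5)
  bp <- 12.75
  y <- ifelse(t <= bp, 2 - 0.005 * t, 2 - 0.005 * bp - 0.066 * (t - bp))
  kin <- fit_sc_kinetics(t, y)
  dr <- disassembly_rate(kin)
  expect_true(dr$has_lag)
  expect_equal(dr$rate, -66, tolerance = 1e-6)
  expect_equal(dr$lag_rate, -5, tolerance = 1e-6)
})

test_that("sc_segfit methods are coherent", {
  bl <- biphasic_line()
  kin <- fit_sc_kinetics(bl$t, bl$y)
  expect_equal(predict(kin, bl$t), fitted(kin))
  expect_equal(residuals(kin), bl$y - fitted(kin))
  cf <- coef(kin)
  expect_named(cf, c("intercept_um", "slope1_nm_min", "slope2_nm_min",
                     "breakpoint1_min"))
  expect_output(print(kin), "biphasic")
  expect_output(print(summary(kin)), "PRESS")
})
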