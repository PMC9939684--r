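# Zip1-profile alignment, onset thresholds, event classification,
# accumulation rates and size classes.

test_that("depletion time interpolates to 10% of the per-cell maximum", {
  # triangular profile: peak 100 at 10 h, zero at 14 h -> 10% at 13.6 h
  p <- data.frame(time_h = 0:14,
                  fi = c(seq(0, 100, length.out = 11),
                         seq(75, 0, length.out = 4)))
  expect_equal(detect_depletion_time(p), 13.6)

  rising <- data.frame(time_h = 0:10, fi = seq(0, 50, length.out = 11))
  d <- detect_depletion_time(rising)
  expect_true(is.na(d))
  expect_equal(attr(d, "flag"), "no_depletion")

  # a sample exactly at 10% of the maximum: that sample's time
  exact <- data.frame(time_h = c(0, 1, 2, 3), fi = c(0, 100, 50, 10))
  expect_equal(detect_depletion_time(exact), 3)
})

test_that("profile alignment is idempotent and shift-invariant", {
  p1 <- simulate_zip1_profile(genotype = "zip3d", sampling_interval = 0.5)
  same <- align_and_average(list(p1, p1))
  expect_equal(same$mean_fi,
               align_and_average(list(p1))$mean_fi)

  p2 <- p1; p2$time_h <- p2$time_h + 2       # same cell, shifted clock
  ali <- align_and_average(list(p1, p2))
  expect_equal(ali$n_cells, rep(2L, nrow(ali)))
  expect_equal(ali$mean_fi, align_and_average(list(p1))$mean_fi)
})

test_that("an aligned zip3-deletion cohort recovers the plateau duration", {
  profiles <- lapply(1:13, function(i) {
    p <- simulate_zip1_profile(genotype = "zip3d", sampling_interval = 0.5,
                               noise_sd = 10, seed = i)
    p$time_h <- p$time_h + stats::runif(1, 0, 4)  # asynchronous cells
    p
  })
  ali <- align_and_average(profiles)
  plateau <- ali$relative_time_h[ali$mean_fi >= 0.95 * max(ali$mean_fi)]
  expect_equal(diff(range(plateau)), 6.3, tolerance = 0.2 * 6.3)
})

test_that("onset threshold is the mean FI at first SC appearance", {
  profiles <- lapply(1:10, function(i)
    simulate_zip1_profile(genotype = "zip3d", sampling_interval = 0.1,
                          seed = i))
  thr <- detect_onset_threshold(profiles)
  expect_equal(as.numeric(thr), 310, tolerance = 0.01 * 310)

  # cells with no SC are excluded and counted
  none <- simulate_zip1_profile(zip1_model(0, 0, 0, 1, 1))
  thr2 <- detect_onset_threshold(c(profiles, list(none)))
  expect_equal(attr(thr2, "n_excluded"), 1L)
  expect_error(detect_onset_threshold(list(none)), "no cell")
})

test_that("events are classified by Zip1 context at disappearance", {
  shrink <- function(fi_path) {
    t <- seq(0, 60, by = 5)
    len <- pmax(1.5 - 0.03 * t, 0)
    data.frame(time_min = t, length_um = len,
               zip1_fi = fi_path(length(t)))
  }
  abortive <- shrink(function(n) rep(424, n))
  ev_a <- classify_event(abortive)
  expect_equal(ev_a$event_type, "abortive_disassembly")
  expect_gte(ev_a$fi_at_disappearance_fraction, 0.75)

  final <- shrink(function(n) seq(424, 40, length.out = n))
  expect_equal(classify_event(final)$event_type, "final_disassembly")

  growing <- data.frame(time_min = seq(0, 30, 3),
                        length_um = seq(0, 30, 3) * 0.06,
                        zip1_fi = 400)
  ev_g <- classify_event(growing)
  expect_equal(ev_g$event_type, "assembly")
  expect_equal(ev_g$rate_nm_min, 60, tolerance = 1e-6)
})

test_that("classification is deterministic and order-independent", {
  co <- simulate_event_cohort(5, 5, 5, seed = 6)
  ev1 <- classify_events(co$trajectories)
  perm <- sample(length(co$trajectories))
  ev2 <- classify_events(co$trajectories[perm])
  expect_equal(ev1$event_type[perm], ev2$event_type)
  expect_equal(ev1$rate_nm_min[perm], ev2$rate_nm_min)
})

test_that("accumulation rate follows the first-attainment rule", {
  expect_equal(accumulation_rate(c(0, 1, 2, 3, 3), 0:4), 1.0)
  expect_equal(accumulation_rate(c(0, 0, 1, 1, 1), 0:4), 1.0)
  no_sc <- accumulation_rate(c(0, 0, 0), 0:2)
  expect_true(is.na(no_sc))
  expect_equal(attr(no_sc, "flag"), "no_sc")
})

test_that("size classes are half-open at 0.5 and 1.5 um and sum to one", {
  ev <- data.frame(event_type = "abortive_disassembly",
                   size_class = c("small", "small", "medium", "large"))
  h <- size_class_histogram(ev)
  expect_equal(h$small + h$medium + h$large, 1, tolerance = 1e-12)
  expect_equal(h$small, 0.5)

  # boundary values: 0.5 um is medium, 1.5 um is large
  traj <- function(maxlen) data.frame(time_min = seq(0, 30, 3),
                                      length_um = seq(0, maxlen,
                                                      length.out = 11),
                                      zip1_fi = 400)
  expect_equal(classify_event(traj(0.5))$size_class, "medium")
  expect_equal(classify_event(traj(1.5))$size_class, "large")
  expect_equal(classify_event(traj(0.49))$size_class, "small")

  all_small <- data.frame(event_type = "assembly",
                          size_class = rep("small", 7))
  expect_equal(size_class_histogram(all_small)$small, 1)
})

test_that("a cohort drawn 88% small recovers its composition", {
  set.seed(21)
  n <- 200
  small <- runif(n) < 0.88
  ev <- data.frame(event_type = "abortive_disassembly",
                   size_class = ifelse(small, "small",
                                       sample(c("medium", "large"),
                                              n, replace = TRUE)))
  h <- size_class_histogram(ev)
  expect_equal(h$small, 0.88, tolerance = 3 * sqrt(0.88 * 0.12 / n) / 0.88)
})
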