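# Ground-truth generators: kinetic programs, trajectories, Zip1 profiles,
# scenes and motion tracks.

test_that("noiseless monophasic trajectory lies exactly on its line", {
  m <- kinetic_model("sc1", phases = list(c(56, 30)))
  tr <- simulate_trajectory(m, 3, noise_sd = 0)
  expect_equal(nrow(tr), 11L)
  expect_equal(diff(tr$length_um), rep(56 * 3 / 1000, 10))
  expect_equal(tr$length_um[1], 0)
})

test_that("biphasic programs respect a configured phase-1 length fraction", {
  L <- 2.4; f <- 0.59
  m <- kinetic_model("sc1",
                     phases = list(c(88, f * L * 1000 / 88),
                                   c(19, (1 - f) * L * 1000 / 19)))
  k <- sckinetics:::model_knots(m)
  expect_equal(k$length[2] / k$length[3], f, tolerance = 1e-12)
})

test_that("infeasible kinetic programs are rejected", {
  expect_error(kinetic_model("x", phases = list(c(-5, 10))), "> 0")
  expect_error(kinetic_model("x", phases = list(c(50, 10)),
                             disassembly_phases = list(c(5, 10))), "< 0")
  # disassembling more than was assembled implies negative length
  expect_error(kinetic_model("x", phases = list(c(50, 10)),
                             disassembly_phases = list(c(-50, 20))),
               "negative length")
})

test_that("generators are deterministic under a fixed seed", {
  m <- kinetic_model("sc1", phases = list(c(56, 30)))
  a <- simulate_trajectory(m, 3, noise_sd = 0.05, seed = 11)
  b <- simulate_trajectory(m, 3, noise_sd = 0.05, seed = 11)
  expect_identical(a$length_um, b$length_um)
  expect_false(identical(
    simulate_trajectory(m, 3, noise_sd = 0.05, seed = 12)$length_um,
    a$length_um))

  c1 <- simulate_assembly_cohort(n = 6, seed = 4)
  c2 <- simulate_assembly_cohort(n = 6, seed = 4)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$trajectories[[3]]$length_um,
                   c2$trajectories[[3]]$length_um)

  t1 <- simulate_motion_track(seed = 5)
  t2 <- simulate_motion_track(seed = 5)
  expect_identical(t1$positions, t2$positions)
})

test_that("trajectory noise is truncated at zero length", {
  m <- kinetic_model("sc1", phases = list(c(5, 60)))
  tr <- simulate_trajectory(m, 3, noise_sd = 0.3, seed = 2)
  expect_true(all(tr$length_um >= 0))
})

test_that("Zip1 presets reproduce the genotype plateau and decline times", {
  wt <- zip1_preset("WT")
  kz <- sckinetics:::zip1_knots(wt)
  expect_equal(kz$time[3] - kz$time[2], 1.5)   # plateau duration, h
  expect_equal(kz$time[4] - kz$time[3], 1.0)   # decline, h
  expect_equal(wt$plateau_level, 740)

  z3 <- zip1_preset("zip3d")
  kz3 <- sckinetics:::zip1_knots(z3)
  expect_equal(kz3$time[3] - kz3$time[2], 6.3)
  expect_equal(kz3$time[4] - kz3$time[3], 3.0)
  expect_equal(z3$plateau_level, 424)
  # reduced Zip1 abundance: 57% of wild type
  expect_equal(round(100 * z3$plateau_level / wt$plateau_level), 57)
})

test_that("Zip1 profiles rise, plateau, decline, and flag synapsis onset", {
  p <- simulate_zip1_profile(genotype = "WT", sampling_interval = 0.25)
  expect_true(all(p$fi >= 0))
  expect_equal(max(p$fi), 740)
  expect_equal(p$fi[nrow(p)], 0)
  on <- attr(p, "first_sc_time")
  expect_equal(p$fi[which(p$time_h == on)] >= 380, TRUE)
  expect_true(all(p$fi[p$time_h < on] < 380))

  flat <- simulate_zip1_profile(zip1_model(0, 0, 0, 1, 1))
  expect_true(all(flat$fi == 0))
  expect_true(is.na(attr(flat, "first_sc_time")))
})

test_that("scenes keep polyline arc length locked to the kinetic truth", {
  m <- kinetic_model("sc1", phases = list(c(70, 30)))
  sc <- build_scene(m, timepoints = seq(0, 30, by = 5), geometry_seed = 2)
  expect_equal(sc$truth$polyline_length_um, sc$truth$true_length_um,
               tolerance = 0.03)
  # every polyline point inside the nucleus sphere
  for (frame in sc$sc) {
    for (s in frame) {
      expect_true(all(sqrt(rowSums(s$points^2)) <= sc$nucleus_radius + 1e-9))
    }
  }
})

test_that("scene geometry guards: overlong SCs rejected, zero length allowed", {
  too_long <- kinetic_model("big", phases = list(c(100, 35)))  # 3.5 um
  expect_error(build_scene(too_long, timepoints = 0), "exceeds")
  # 3.0 um < pi * radius: accepted
  ok <- kinetic_model("chr4", phases = list(c(100, 30)))
  expect_s3_class(build_scene(ok, timepoints = 30, geometry_seed = 1),
                  "nucleus_scene")
  empty <- build_scene(kinetic_model("zero", phases = list(c(50, 1e-9))),
                       timepoints = 0, geometry_seed = 1)
  expect_length(empty$sc[[1]], 0L)
})

test_that("equal arm fractions finish both arms simultaneously", {
  m <- kinetic_model("sym", phases = list(c(100, 20)))
  sc <- build_scene(m, timepoints = c(10, 20), arm_fraction = 0.5,
                    geometry_seed = 3)
  # at completion the sub-polyline is centred on the nucleation point:
  # both arms have consumed equal arc length at every time
  tr <- sc$truth
  expect_equal(tr$polyline_length_um, tr$true_length_um, tolerance = 0.03)
})

test_that("motion tracks stay in the nucleus and span the observed speeds", {
  tk <- simulate_motion_track(duration = 300, interval = 5,
                              speed_means = c(0.3, 0.8), weight = 0.5,
                              seed = 8)
  expect_true(all(sqrt(rowSums(tk$positions^2)) <= tk$nucleus_radius + 1e-9))
  sp <- track_speeds(tk)
  expect_length(sp, 60L)
  expect_gt(max(sp), 0.6)
  expect_lt(min(sp), 0.4)
  still <- simulate_motion_track(speed_means = c(0, 0),
                                 speed_sds = c(0, 0), seed = 1)
  expect_equal(max(abs(diff(still$positions))), 0)
})
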