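# Rendering, segmentation, tracing, projections and trace linking.

straight2 <- local({
  render_phantom(cbind(0, 0, seq(-1, 1, by = 0.05)))
})

test_that("noiseless rendering conserves scene intensity", {
  # diffuse pool alone: the PSF convolution redistributes but does not
  # create or destroy intensity (filament brightness is PSF-calibrated,
  # so conservation is checked against the analytic pool total)
  ph <- phantom_scene(matrix(numeric(0), 0, 3), nucleus_radius = 1)
  st <- render_timelapse(ph, photon_scale = Inf, read_noise_sd = 0,
                         margin = 0.8)
  st0 <- render_timelapse(ph, photon_scale = Inf, read_noise_sd = 0,
                          margin = 0.8, psf_sigma = c(1e-9, 1e-9))
  expect_equal(sum(st), sum(st0), tolerance = 0.01)
  expect_gt(sum(st), 0)

  # with a filament: the deposited line integral scales with the arc
  # length, and blurring conserves it
  ph1 <- phantom_scene(cbind(0, 0, seq(-0.8, 0.8, by = 0.05)),
                       nucleus_radius = 1)
  st1 <- render_timelapse(ph1, photon_scale = Inf, read_noise_sd = 0,
                          margin = 0.8)
  ph2 <- phantom_scene(cbind(0, 0, seq(-0.4, 0.4, by = 0.05)),
                       nucleus_radius = 1)
  st2 <- render_timelapse(ph2, photon_scale = Inf, read_noise_sd = 0,
                          margin = 0.8)
  sc_mass1 <- sum(st1) - sum(st)
  sc_mass2 <- sum(st2) - sum(st)
  expect_equal(sc_mass1 / sc_mass2, 2, tolerance = 0.02)
})

test_that("rendering is deterministic and rejects bad photon scales", {
  ph <- phantom_scene(cbind(0, 0, seq(-0.5, 0.5, by = 0.05)))
  a <- render_timelapse(ph, photon_scale = 30, read_noise_sd = 0.5, seed = 7)
  b <- render_timelapse(ph, photon_scale = 30, read_noise_sd = 0.5, seed = 7)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_error(render_timelapse(ph, photon_scale = 0), "positive")
  expect_true(all(a >= 0))
})

test_that("max and sum projections behave like their definitions", {
  vol <- array(2, c(4, 5, 6))
  pr <- project_max_sum(vol)
  expect_equal(pr$max, matrix(2, 5, 6))
  expect_equal(pr$sum, matrix(8, 5, 6))
  one <- array(0, c(4, 5, 6)); one[2, 3, 4] <- 9
  pr1 <- project_max_sum(one)
  expect_equal(sum(pr1$max > 0), 1L)
  expect_equal(sum(pr1$sum > 0), 1L)
  vol2 <- stack_frame(straight2, 1)
  expect_equal(sum(project_max_sum(vol2)$sum), sum(vol2))
})

test_that("nucleus segmentation recovers volume and total fluorescence", {
  vol <- stack_frame(straight2, 1)
  nuc <- segment_nucleus(vol)
  expect_false(nuc$empty)
  true_vol <- 4 / 3 * pi * 1.3^3
  expect_lt(abs(nuc$volume_um3 - true_vol) / true_vol, 0.15)
  # background-subtracted total FI conserves the scene integral
  expect_equal(nuc$total_fi, sum(vol), tolerance = 0.05)

  zero <- segment_nucleus(array(0, c(8, 16, 16)))
  expect_true(zero$empty)
  expect_equal(zero$total_fi, 0)
})

test_that("SC voxel segmentation finds filaments and nothing else", {
  # scene with diffuse pool only
  ph <- phantom_scene(matrix(numeric(0), 0, 3), nucleus_radius = 1)
  st <- render_timelapse(ph, photon_scale = Inf)
  vol <- stack_frame(st, 1)
  nuc <- segment_nucleus(vol)
  expect_equal(sum(segment_sc_voxels(vol, nuc$mask)), 0L)

  vol2 <- stack_frame(straight2, 1)
  nuc2 <- segment_nucleus(vol2)
  m <- segment_sc_voxels(vol2, nuc2$mask)
  expect_equal(max(sckinetics:::label_components(m)), 1L)

  # two parallel filaments 0.6 um apart -> two components
  pts <- rbind(cbind(0, -0.3, seq(-0.8, 0.8, by = 0.05)),
               cbind(0, 0.3, seq(-0.8, 0.8, by = 0.05)))
  ph2 <- phantom_scene(cbind(0, -0.3, seq(-0.8, 0.8, by = 0.05)),
                       nucleus_radius = 1.2)
  ph2$sc[[1]][[2]] <- list(sc_id = "b",
                           points = cbind(0, 0.3,
                                          seq(-0.8, 0.8, by = 0.05)))
  st2 <- render_timelapse(ph2, photon_scale = Inf)
  v2 <- stack_frame(st2, 1)
  n2 <- segment_nucleus(v2)
  m2 <- segment_sc_voxels(v2, n2$mask)
  expect_equal(max(sckinetics:::label_components(m2)), 2L)
})

test_that("phantom filaments are traced to their analytic lengths", {
  expect_equal(measure_phantom_length(straight2), 2.0, tolerance = 0.1)
  th <- seq(0, pi, length.out = 60)
  semi <- render_phantom(cbind(0, sin(th), cos(th)))
  expect_equal(measure_phantom_length(semi), pi, tolerance = 0.1 * pi)
})

test_that("measured length is invariant to rotation about z", {
  base <- measure_phantom_length(straight2)
  u <- seq(-1, 1, by = 0.05) / sqrt(2)
  rot <- render_phantom(cbind(0, u, u))
  expect_equal(measure_phantom_length(rot), base, tolerance = 0.05 * base)
})

test_that("arc length dominates end-to-end distance for every trace", {
  th <- seq(0, pi, length.out = 60)
  semi <- render_phantom(cbind(0, sin(th), cos(th)))
  vol <- stack_frame(semi, 1)
  nuc <- segment_nucleus(vol)
  tr <- trace_sc_polylines(segment_sc_voxels(vol, nuc$mask), vol,
                           attr(semi, "voxel_size"))[[1]]
  ends <- sqrt(sum((tr$points[1, ] - tr$points[nrow(tr$points), ])^2))
  expect_gte(tr$length_um + 1e-9, ends)
  # a semicircle's arc is much longer than its chord
  expect_gt(tr$length_um, 1.3 * ends)
})

test_that("tiny components are reported as sub-resolution foci", {
  mask <- array(FALSE, c(6, 10, 10))
  mask[3, 5, 5:6] <- TRUE
  vol <- array(0, c(6, 10, 10)); vol[mask] <- 10
  tr <- trace_sc_polylines(mask, vol, c(0.2, 0.1, 0.1))
  expect_length(tr, 1L)
  expect_true(tr[[1]]$sub_resolution)
  expect_equal(tr[[1]]$length_um, 0.1)
})

test_that("trace linking matches identities and reports disappearance", {
  mk <- function(z, len) {
    structure(list(points = cbind(z, 0, c(0, len)), length_um = len,
                   mean_intensity = 1, n_voxels = 10,
                   sub_resolution = FALSE), class = "sc_trace")
  }
  a <- list(mk(0, 1), mk(0.8, 2))
  expect_equal(link_traces(a, a)$match, c(1L, 2L))
  expect_length(link_traces(a, a)$disappeared, 0L)

  grown <- list(mk(0, 1.2), mk(0.8, 2))   # first grew by 0.2 um
  expect_equal(link_traces(a, grown)$match, c(1L, 2L))

  expect_equal(link_traces(a, list(mk(0.8, 2)))$disappeared, 1L)
  expect_true(is.na(link_traces(list(), list(mk(0, 1)))$match))
})

test_that("a full time course recovers the growth trajectory", {
  m <- kinetic_model("sc1", phases = list(c(70, 30)))
  sc <- build_scene(m, timepoints = seq(0, 30, by = 3), geometry_seed = 4)
  st <- render_timelapse(sc, photon_scale = 20, read_noise_sd = 0.3,
                         seed = 9)
  res <- measure_timecourse(st)
  expect_equal(res$measurements$n_scs[1], 0L)
  expect_true(all(res$measurements$n_scs[-1] == 1L))
  expect_length(res$trajectories, 1L)
  tr <- res$trajectories[[1]]
  truth <- sc$truth$true_length_um[match(tr$time_min, sc$truth$time_min)]
  ok <- truth >= 0.5     # above the diffraction floor
  rel_rms <- sqrt(mean((tr$length_um - truth)[ok]^2)) / mean(truth[ok])
  expect_lt(rel_rms, 0.15)
  # nuclear FI context travels with the trajectory
  expect_true(all(tr$zip1_fi > 0))

  empty <- render_timelapse(build_scene(list(), timepoints = c(0, 3),
                                        geometry_seed = 1),
                            photon_scale = Inf)
  res0 <- measure_timecourse(empty)
  expect_true(all(res0$measurements$n_scs == 0L))
})

test_that("stacks survive a TIFF round trip", {
  ph <- phantom_scene(cbind(0, 0, seq(-0.5, 0.5, by = 0.05)))
  st <- render_timelapse(ph, photon_scale = 40, seed = 2)
  f <- file.path(withr::local_tempdir(), "stack.tif")
  write_stack_tiff(st, f)
  back <- read_stack_tiff(f)
  expect_equal(dim(back), dim(st))
  expect_equal(as.numeric(back), as.numeric(st), tolerance = 1e-6)
  expect_equal(attr(back, "voxel_size"), attr(st, "voxel_size"))
})
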