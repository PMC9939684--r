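# shared fixtures: small rendered phantoms are built once per test run

# exact biphasic trajectory with its breakpoint on a candidate midpoint
biphasic_line <- function(r1 = 88, r2 = 19, bp = 13.5, t_end = 42, dt = 3) {
  t <- seq(0, t_end, by = dt)
  y <- ifelse(t <= bp, r1 / 1000 * t,
              r1 / 1000 * bp + r2 / 1000 * (t - bp))
  list(t = t, y = y)
}

# brute-force segmented-fit oracle: exhaustive lm over all admissible
# breakpoint combinations (independent of the package's scan)
oracle_best_sse <- function(tt, yy, k) {
  if (k == 1) return(sum(stats::lm.fit(cbind(1, tt), yy)$residuals^2))
  n <- length(tt)
  mids <- (tt[-n] + tt[-1]) / 2
  cand <- mids[seq_along(mids) >= 3 & (n - seq_along(mids)) >= 3]
  best <- Inf
  combs <- if (k == 2) matrix(cand, ncol = 1) else {
    if (length(cand) < 2) return(Inf)
    t(utils::combn(cand, 2))
  }
  for (r in seq_len(nrow(combs))) {
    b <- combs[r, ]
    if (k == 3 && sum(tt >= b[1] & tt <= b[2]) < 3) next
    X <- cbind(1, tt)
    for (bi in b) X <- cbind(X, pmax(tt - bi, 0))
    best <- min(best, sum(stats::lm.fit(X, yy)$residuals^2))
  }
  best
}

render_phantom <- function(pts, nucleus_radius = 1.3, photon_scale = Inf,
                           read_noise_sd = 0, seed = 3) {
  ph <- phantom_scene(pts, nucleus_radius = nucleus_radius)
  render_timelapse(ph, photon_scale = photon_scale,
                   read_noise_sd = read_noise_sd, seed = seed)
}

measure_phantom_length <- function(stack) {
  vol <- stack_frame(stack, 1)
  nuc <- segment_nucleus(vol)
  scm <- segment_sc_voxels(vol, nuc$mask)
  tr <- trace_sc_polylines(scm, vol, attr(stack, "voxel_size"))
  expect_length(tr, 1L)
  tr[[1]]$length_um
}
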