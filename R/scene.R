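# Nucleus scene construction: SC polylines inside a spherical nucleus,
# and telomere-led motion tracks.

#' Simulate a telomere-led chromosome motion track
#'
#' A tracked SC end performs a random walk inside the nucleus whose
#' per-step speed is drawn from a two-component mixture (the low- and
#' high-velocity behaviour of telomere-led prophase movements), with
#' positions reflected at the nuclear boundary.
#'
#' @param duration seconds of tracking (default 300).
#' @param interval seconds between frames (default 5).
#' @param speed_means `c(low, high)` mixture means in um/s (default
#'   0.3, 0.8).
#' @param weight probability of the high-velocity component per step
#'   (default 0.5).
#' @param speed_sds `c(low, high)` component SDs in um/s.
#' @param nucleus_radius um (default 1).
#' @param seed integer seed.
#' @return object of class `"motion_track"`: list with `times` (s),
#'   `positions` (n x 3 um), `labels` (true component per step, 1 = low,
#'   2 = high), `interval`.
#' @export
simulate_motion_track <- function(duration = 300, interval = 5,
                                  speed_means = c(0.3, 0.8),
                                  weight = 0.5,
                                  speed_sds = c(0.05, 0.1),
                                  nucleus_radius = 1, seed = 1) {
  if (interval <= 0 || duration < interval) {
    stop("need duration >= interval > 0")
  }
  with_seed(seed, {
    n_steps <- floor(duration / interval)
    times <- seq(0, by = interval, length.out = n_steps + 1L)
    pos <- matrix(0, n_steps + 1L, 3)
    pos[1, ] <- random_point_in_sphere(0.5 * nucleus_radius)
    labels <- integer(n_steps)
    path_len <- numeric(n_steps)
    for (i in seq_len(n_steps)) {
      comp <- if (stats::runif(1) < weight) 2L else 1L
      labels[i] <- comp
      sp <- if (speed_sds[comp] > 0) {
        rtrunc_norm(1, speed_means[comp], speed_sds[comp], lower = 0)
      } else speed_means[comp]
      # billiard motion: the end travels sp * interval of path inside the
      # sphere, reflecting specularly at the envelope; net displacement is
      # shorter, the curvilinear path length equals the drawn speed
      mv <- billiard_step(pos[i, ], random_unit_vector(), sp * interval,
                          nucleus_radius)
      pos[i + 1L, ] <- mv$p
      path_len[i] <- sp * interval
    }
    structure(list(times = times, positions = pos, labels = labels,
                   path_lengths = path_len,
                   interval = interval,
                   nucleus_radius = nucleus_radius),
              class = "motion_track")
  })
}

# advance a point along `dir` for arc length `len` inside a sphere of
# radius R, reflecting at the boundary
billiard_step <- function(p, dir, len, R) {
  for (b in 1:100) {
    if (len <= 0) break
    # first boundary hit: |p + t dir| = R, smallest positive t
    pd <- sum(p * dir)
    disc <- pd^2 - (sum(p^2) - R^2)
    t_hit <- -pd + sqrt(max(disc, 0))
    if (t_hit >= len) {
      p <- p + dir * len
      len <- 0
    } else {
      p <- p + dir * t_hit
      len <- len - t_hit
      nrm <- p / sqrt(sum(p^2))
      dir <- dir - 2 * sum(dir * nrm) * nrm
      p <- p * (1 - 1e-9)               # nudge off the boundary
    }
  }
  list(p = p, dir = dir)
}

#' Per-step speeds of a motion track
#'
#' For simulated tracks the per-step curvilinear path length is known and
#' the returned speed is path length over interval (the quantity whose
#' mixture the generator draws).  For tracks without stored path lengths
#' the net displacement per interval is used.
#'
#' @param track a `"motion_track"`.
#' @return speeds in um/s (one per step).
#' @export
track_speeds <- function(track) {
  stopifnot(inherits(track, "motion_track"))
  if (!is.null(track$path_lengths)) {
    return(track$path_lengths / diff(track$times))
  }
  d <- diff(track$positions)
  sqrt(rowSums(d^2)) / diff(track$times)
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-9) return(v / n)
  }
}

random_point_in_sphere <- function(radius) {
  repeat {
    p <- stats::runif(3, -radius, radius)
    if (sum(p^2) <= radius^2) return(p)
  }
}

# bounded-curvature random chain of total arc length `length` inside a
# sphere; `step` spacing, minimum turning radius `r_min`
random_chain <- function(length_um, radius, step = 0.05, r_min = 0.3,
                         inset = 0.06) {
  r_eff <- radius - inset
  n <- max(2L, ceiling(length_um / step) + 1L)
  pts <- matrix(0, n, 3)
  pts[1, ] <- random_point_in_sphere(0.6 * r_eff)
  dir <- random_unit_vector()
  max_turn <- step / r_min
  # rotate `dir` toward `target` by at most max_turn (curvature bound)
  turn_toward <- function(dir, target) {
    target <- target / sqrt(sum(target^2))
    cosang <- max(min(sum(dir * target), 1), -1)
    ang <- acos(cosang)
    if (ang <= max_turn) return(target)
    perp <- target - cosang * dir
    pn <- sqrt(sum(perp^2))
    if (pn < 1e-9) return(dir)
    cos(max_turn) * dir + sin(max_turn) * perp / pn
  }
  for (i in 2:n) {
    desired <- dir
    perp <- random_unit_vector()
    perp <- perp - sum(perp * dir) * dir
    pn <- sqrt(sum(perp^2))
    if (pn > 1e-9) {
      theta <- stats::runif(1, 0, max_turn)
      desired <- cos(theta) * dir + sin(theta) * perp / pn
    }
    look <- pts[i - 1L, ] + desired * step
    r_look <- sqrt(sum(look^2))
    if (r_look > 0.85 * r_eff) {        # steer back toward the centre
      desired <- desired - 0.6 * look / r_look * (r_look / r_eff)
      desired <- desired / sqrt(sum(desired^2))
    }
    dir <- turn_toward(dir, desired)    # curvature stays bounded
    cand <- pts[i - 1L, ] + dir * step
    r <- sqrt(sum(cand^2))
    if (r > r_eff) {                    # slide along the boundary sphere
      cand <- cand / r * r_eff
      dd <- cand - pts[i - 1L, ]
      dir <- dd / sqrt(sum(dd^2))
    }
    pts[i, ] <- cand
  }
  pts
}

# arc-length parameterised sub-polyline of chain `pts` covering
# [s_from, s_to] (um along the chain)
sub_polyline <- function(pts, s_from, s_to, step = 0.05) {
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  s_from <- max(0, s_from); s_to <- min(max(s), s_to)
  if (s_to <= s_from) return(NULL)
  svals <- unique(c(s_from, s[s > s_from & s < s_to], s_to))
  t(vapply(svals, function(si) {
    j <- findInterval(si, s, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(seg))
    w <- (si - s[j]) / seg[j]
    pts[j, ] * (1 - w) + pts[j + 1L, ] * w
  }, numeric(3)))
}

polyline_length <- function(pts) {
  if (is.null(pts) || nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Build a nucleus scene from kinetic programs
#'
#' Lays out one smooth random curve (bounded curvature, minimum turning
#' radius 0.3 um) inside the spherical nucleus per SC, then for every
#' requested timepoint extracts the sub-curve whose arc length equals the
#' kinetic program's true length, growing from the nucleation point in
#' both directions according to `arm_fraction`.
#'
#' @param models list of [kinetic_model()] objects (or a single model).
#' @param timepoints minutes at which the scene is realised.
#' @param zip1 optional [zip1_model()] providing the diffuse-pool dynamic;
#'   when NULL the diffuse intensity is constant.
#' @param nucleus_radius um (default 1.0, a 2-um-diameter nucleus).
#' @param diffuse_intensity IU per voxel-volume-equivalent of nucleoplasmic
#'   Zip1 pool (default 10).
#' @param contrast SC peak brightness relative to the diffuse level
#'   (default 5).
#' @param arm_fraction share of growth allotted to the trailing arm, in
#'   [0, 1] (default 0.3; 0.5 grows both arms equally).
#' @param geometry_seed integer seed for curve geometry.
#' @param rigid_motion_sd per-frame random rigid rotation of each curve
#'   about the nucleus centre, radians (default 0 = static geometry).
#' @return object of class `"nucleus_scene"`: list with `nucleus_radius`,
#'   `timepoints`, `sc` (per timepoint, list of `list(sc_id, points)`),
#'   `models`, `diffuse_intensity`, `contrast`, `truth` (data frame of
#'   sc_id, timepoint, true length, polyline arc length).
#' @export
build_scene <- function(models, timepoints, zip1 = NULL,
                        nucleus_radius = 1.0, diffuse_intensity = 10,
                        contrast = 5, arm_fraction = 0.3,
                        geometry_seed = 1, rigid_motion_sd = 0) {
  if (inherits(models, "kinetic_model")) models <- list(models)
  if (arm_fraction < 0 || arm_fraction > 1) {
    stop("arm_fraction must be in [0, 1]")
  }
  max_sc <- pi * nucleus_radius
  for (m in models) {
    if (max(model_knots(m)$length) > max_sc) {
      stop(sprintf("SC '%s' exceeds the maximum length %.2f um that fits",
                   m$sc_id, max_sc))
    }
  }
  with_seed(geometry_seed, {
    chains <- lapply(models, function(m) {
      random_chain(max(model_knots(m)$length) + 0.1, nucleus_radius)
    })
    truth <- NULL
    sc <- lapply(seq_along(timepoints), function(ti) {
      tp <- timepoints[ti]
      out <- list()
      for (mi in seq_along(models)) {
        m <- models[[mi]]
        len <- true_length(m, tp)
        chain <- chains[[mi]]
        if (rigid_motion_sd > 0 && ti > 1L) {
          ang <- stats::rnorm(3, 0, rigid_motion_sd)
          chain <- chain %*% rotation_matrix(ang)
          chains[[mi]] <<- chain
        }
        seg <- sqrt(rowSums(diff(chain)^2))
        s_total <- sum(seg)
        s0 <- arm_fraction * s_total   # nucleation arc position
        pts <- if (len > 0) {
          sub_polyline(chain, s0 - arm_fraction * len,
                       s0 + (1 - arm_fraction) * len)
        } else NULL
        truth <<- rbind(truth, data.frame(
          sc_id = m$sc_id, timepoint = ti, time_min = tp,
          true_length_um = len,
          polyline_length_um = polyline_length(pts)))
        if (!is.null(pts)) {
          out[[length(out) + 1L]] <- list(sc_id = m$sc_id, points = pts)
        }
      }
      out
    })
    structure(list(nucleus_radius = nucleus_radius,
                   timepoints = timepoints,
                   sc = sc,
                   models = models,
                   zip1 = zip1,
                   diffuse_intensity = diffuse_intensity,
                   contrast = contrast,
                   truth = truth),
              class = "nucleus_scene")
  })
}

#' Build a single-timepoint phantom scene from an explicit polyline
#'
#' Convenience constructor for validation phantoms (straight filaments,
#' semicircles, ...) where the filament geometry — and hence the true arc
#' length — is known analytically.
#'
#' @param points n x 3 matrix of polyline coordinates (um, nucleus-centred).
#' @param nucleus_radius um (default 1).
#' @param diffuse_intensity IU per voxel (default 10).
#' @param contrast SC peak over diffuse (default 5).
#' @return a `"nucleus_scene"` with one timepoint.
#' @examples
#' # straight 2-um filament along x
#' ph <- phantom_scene(cbind(0, 0, seq(-1, 1, by = 0.05)),
#'                     nucleus_radius = 1.4)
#' @export
phantom_scene <- function(points, nucleus_radius = 1,
                          diffuse_intensity = 10, contrast = 5) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  len <- polyline_length(points)
  structure(list(nucleus_radius = nucleus_radius,
                 timepoints = 0,
                 sc = list(list(list(sc_id = "phantom", points = points))),
                 models = list(),
                 zip1 = NULL,
                 diffuse_intensity = diffuse_intensity,
                 contrast = contrast,
                 truth = data.frame(sc_id = "phantom", timepoint = 1L,
                                    time_min = 0, true_length_um = len,
                                    polyline_length_um = len)),
            class = "nucleus_scene")
}

rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  rx %*% ry %*% rz
}

#' @export
print.nucleus_scene <- function(x, ...) {
  cat(sprintf("nucleus_scene: radius %.2f um, %d SC model(s), %d timepoint(s)\n",
              x$nucleus_radius, length(x$models), length(x$timepoints)))
  invisible(x)
}
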