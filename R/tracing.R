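# Tracing of SC filaments: geodesic path through the voxel graph,
# sub-voxel centreline refinement, and half-maximum endpoint location.

# trilinear interpolation of vol at physical points (n x 3, um, relative
# to voxel-centre coordinates: centre of voxel (1,1,1) is at origin)
interp3 <- function(vol, pts, voxel_size, origin) {
  d <- dim(vol)
  out <- numeric(nrow(pts))
  for (p in seq_len(nrow(pts))) {
    f <- (pts[p, ] - origin) / voxel_size + 1   # fractional voxel coords
    i0 <- floor(f)
    w <- f - i0
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      iz <- i0[1] + dz; iy <- i0[2] + dy; ix <- i0[3] + dx
      if (iz < 1 || iz > d[1] || iy < 1 || iy > d[2] ||
          ix < 1 || ix > d[3]) next
      wt <- (if (dz) w[1] else 1 - w[1]) *
        (if (dy) w[2] else 1 - w[2]) *
        (if (dx) w[3] else 1 - w[3])
      acc <- acc + wt * vol[iz, iy, ix]
    }
    out[p] <- acc
  }
  out
}

# 3-point moving average smoothing of a polyline, endpoints kept
smooth_polyline <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(pts)
  sm <- pts
  sm[2:(n - 1), ] <- (pts[1:(n - 2), ] + pts[2:(n - 1), ] + pts[3:n, ]) / 3
  sm
}

# geodesic trace of one connected component; returns polyline in physical
# coordinates (um, voxel-centre convention with origin at first voxel).
# Endpoints are the farthest-apart voxel pair under physical distances
# (the filament tips); the path between them minimises distance divided
# by squared intensity, so it follows the bright centreline ridge instead
# of cutting the inside of bends.
trace_component <- function(coords, vol, voxel_size) {
  n <- nrow(coords)
  phys <- sweep(coords - 1, 2, voxel_size, `*`)
  if (n == 1L) return(phys)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  key <- coords[, 1] + coords[, 2] * 1e3 + coords[, 3] * 1e6
  idmap <- new.env(hash = TRUE)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = idmap)
  iv <- pmax(vol[coords], 1e-9)
  ee <- NULL; ww <- NULL; wr <- NULL
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[r, ], `+`)
    nkey <- nb[, 1] + nb[, 2] * 1e3 + nb[, 3] * 1e6
    wdist <- sqrt(sum((offs[r, ] * voxel_size)^2))
    for (i in seq_len(n)) {
      j <- mget(as.character(nkey[i]), envir = idmap,
                ifnotfound = list(NULL))[[1]]
      if (!is.null(j) && j > i) {
        ee <- c(ee, i, j)
        ww <- c(ww, wdist)
        wr <- c(wr, wdist / ((iv[i] + iv[j]) / 2)^2)
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (is.null(ee)) return(phys[1, , drop = FALSE])
  g <- igraph::add_edges(g, ee)
  d1 <- igraph::distances(g, v = 1, weights = ww)
  a <- which.max(ifelse(is.finite(d1), d1, -1))
  da <- igraph::distances(g, v = a, weights = ww)
  b <- which.max(ifelse(is.finite(da), da, -1))
  path <- as.integer(igraph::shortest_paths(g, from = a, to = b,
                                            weights = wr)$vpath[[1]])
  phys[path, , drop = FALSE]
}

# intensity-weighted sub-voxel refinement of path points: a few
# mean-shift iterations pull each point onto the transverse intensity
# ridge (weights above the local floor, so the diffuse pool does not
# drag points off the filament)
refine_centerline <- function(pts, vol, voxel_size, n_iter = 3L) {
  d <- dim(vol)
  out <- pts
  for (iter in seq_len(n_iter)) {
    for (p in seq_len(nrow(out))) {
      idx <- round(out[p, ] / voxel_size) + 1
      zr <- max(1, idx[1] - 1):min(d[1], idx[1] + 1)
      yr <- max(1, idx[2] - 1):min(d[2], idx[2] + 1)
      xr <- max(1, idx[3] - 1):min(d[3], idx[3] + 1)
      block <- vol[zr, yr, xr, drop = FALSE]
      w <- as.numeric(block)
      w <- pmax(w - min(w), 0)
      if (sum(w) <= 0) next
      grid <- as.matrix(expand.grid(z = zr, y = yr, x = xr))
      out[p, ] <- colSums(sweep(grid - 1, 2, voxel_size, `*`) * w) / sum(w)
    }
  }
  out
}

# crop/extend a centerline to its half-maximum endpoints along the path
halfmax_endpoints <- function(pts, vol, voxel_size, background,
                              max_extend = 0.4, ds = 0.02) {
  extend_dir <- function(p_end, p_prev) {
    v <- p_end - p_prev
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) return(NULL)
    v <- v / nv
    k <- seq(ds, max_extend, by = ds)
    sweep(outer(k, v), 2, p_end, `+`)
  }
  n <- nrow(pts)
  ext_head <- extend_dir(pts[1, ], pts[min(2, n), ])
  ext_tail <- extend_dir(pts[n, ], pts[max(1, n - 1), ])
  full <- rbind(if (!is.null(ext_head)) ext_head[rev(seq_len(nrow(ext_head))), ],
                pts,
                ext_tail)
  dense <- resample_polyline(full, ds = ds)
  prof <- interp3(vol, dense, voxel_size, origin = c(0, 0, 0))
  n_core_from <- if (is.null(ext_head)) 1 else nrow(ext_head) + 1
  # plateau level from the middle of the original path
  seg <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  core_len <- polyline_length(pts)
  core_start <- polyline_length(full[seq_len(n_core_from), , drop = FALSE])
  core <- prof[seg >= core_start + 0.2 * core_len &
                 seg <= core_start + 0.8 * core_len]
  if (!length(core)) core <- prof
  # high quantile: for a long filament this is the plateau; for an object
  # shorter than a few PSF widths it is the (attenuated) peak, whose
  # half-maximum still brackets the true extent
  plateau <- stats::quantile(core, 0.95, names = FALSE)
  thr <- background + 0.5 * (plateau - background)
  above <- which(prof >= thr)
  if (!length(above)) return(pts)
  i1 <- above[1]; i2 <- above[length(above)]
  dense[i1:i2, , drop = FALSE]
}

#' Trace SC filament centrelines and measure their lengths
#'
#' For every connected component of the SC voxel mask the longest geodesic
#' path through the 26-connected voxel graph (edges weighted by physical,
#' anisotropy-aware distance) is extracted, refined to a sub-voxel
#' centreline by local intensity centroids, smoothed by a 3-point moving
#' average, and finally cropped (or extended) to the points where the
#' intensity profile along the path falls to half of its plateau above
#' background — for a filament convolved with a symmetric PSF the half-
#' maximum crossing sits at the true filament end.
#'
#' Components smaller than 3 voxels are reported as sub-resolution foci
#' with a nominal length of one xy pixel.
#'
#' @param sc_mask logical 3D mask (from [segment_sc_voxels()]).
#' @param vol the intensity volume the mask was derived from.
#' @param voxel_size `c(z, y, x)` um.
#' @param background diffuse intensity level for the half-maximum rule;
#'   default: median intensity outside the mask.
#' @return list of `"sc_trace"` objects: `list(points, length_um,
#'   mean_intensity, n_voxels, sub_resolution)`.
#' @export
trace_sc_polylines <- function(sc_mask, vol, voxel_size = c(0.2, 0.1, 0.1),
                               background = NULL) {
  vol <- stack_frame(vol)
  if (!any(sc_mask)) return(list())
  labels <- label_components(sc_mask)
  ncomp <- max(labels)
  traces <- list()
  for (ci in seq_len(ncomp)) {
    coords <- which(labels == ci, arr.ind = TRUE)
    if (nrow(coords) < 3L) {
      phys <- sweep(coords - 1, 2, voxel_size, `*`)
      traces[[length(traces) + 1L]] <- structure(
        list(points = phys, length_um = voxel_size[3],
             mean_intensity = mean(vol[labels == ci]),
             n_voxels = nrow(coords), sub_resolution = TRUE),
        class = "sc_trace")
      next
    }
    # local background: median intensity in a 3-voxel shell around the
    # component (the nucleoplasmic diffuse level next to this filament)
    bg <- if (is.null(background)) {
      d <- dim(vol)
      lo <- pmax(apply(coords, 2, min) - 3L, 1L)
      hi <- pmin(apply(coords, 2, max) + 3L, d)
      box <- array(FALSE, d)
      box[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
      shell <- box & !sc_mask
      if (any(shell)) stats::median(vol[shell]) else 0
    } else background
    # trace on the half-maximum core of the component: the PSF smears a
    # filament furthest along z, and for short SCs that smear can exceed
    # the true length, misdirecting the geodesic; the half-max core is
    # again longest along the filament axis
    peak <- stats::quantile(vol[labels == ci], 0.95, names = FALSE)
    half <- bg + 0.5 * (peak - bg)
    core <- labels == ci & vol >= half
    if (sum(core) >= 3L) {
      core_lab <- label_components(core)
      core_tab <- tabulate(core_lab[core_lab > 0L])
      core_coords <- which(core_lab == which.max(core_tab), arr.ind = TRUE)
      if (nrow(core_coords) >= 3L) coords <- core_coords
    }
    path <- trace_component(coords, vol, voxel_size)
    path <- refine_centerline(path, vol, voxel_size)
    path <- smooth_polyline(path)
    path <- halfmax_endpoints(path, vol, voxel_size, bg)
    traces[[length(traces) + 1L]] <- structure(
      list(points = path, length_um = polyline_length(path),
           mean_intensity = mean(vol[labels == ci]),
           n_voxels = nrow(coords), sub_resolution = FALSE),
      class = "sc_trace")
  }
  traces
}

#' @export
print.sc_trace <- function(x, ...) {
  cat(sprintf("sc_trace: %.3f um (%d voxels%s)\n", x$length_um,
              x$n_voxels, if (x$sub_resolution) ", sub-resolution" else ""))
  invisible(x)
}

trace_centroid <- function(trace) colMeans(trace$points)

#' Link SC traces between consecutive timepoints
#'
#' Greedy minimum-cost matching with cost = centroid distance (um) +
#' 2 x |length change| (um).  Pairs costing more than `max_cost` are left
#' unmatched; unmatched new traces start new identities, unmatched old
#' traces are reported as candidates for disappearance.
#'
#' @param traces_a,traces_b lists of `"sc_trace"` at times t and t+1.
#' @param max_cost maximum admissible cost (default 2).
#' @return list: `match` (integer vector over `traces_b`: index into
#'   `traces_a` or NA for new), `disappeared` (indices of `traces_a` with
#'   no partner).
#' @export
link_traces <- function(traces_a, traces_b, max_cost = 2) {
  na <- length(traces_a); nb <- length(traces_b)
  match_b <- rep(NA_integer_, nb)
  if (na > 0 && nb > 0) {
    cost <- matrix(Inf, na, nb)
    for (i in seq_len(na)) {
      for (j in seq_len(nb)) {
        cd <- sqrt(sum((trace_centroid(traces_a[[i]]) -
                          trace_centroid(traces_b[[j]]))^2))
        cost[i, j] <- cd + 2 * abs(traces_a[[i]]$length_um -
                                     traces_b[[j]]$length_um)
      }
    }
    repeat {
      m <- which.min(cost)
      if (!length(m) || !is.finite(cost[m])) break
      if (cost[m] > max_cost) break
      i <- (m - 1) %% na + 1
      j <- (m - 1) %/% na + 1
      match_b[j] <- i
      cost[i, ] <- Inf
      cost[, j] <- Inf
    }
  }
  list(match = match_b,
       disappeared = setdiff(seq_len(na),
                             match_b[!is.na(match_b)]))
}

#' Measure a full 3D+time stack
#'
#' Runs nucleus segmentation, SC voxel segmentation and tracing on every
#' timepoint, links traces across time (tolerating single-frame detection
#' dropouts; disappearance is declared after two consecutive unmatched
#' frames), and assembles per-SC length-versus-time trajectories annotated
#' with the nucleus's total-fluorescence context.
#'
#' @param stack 4D `"sc_stack"` (t, z, y, x).
#' @param k_sigma SC segmentation threshold (default 3).
#' @param max_cost linking cost ceiling (default 2 um).
#' @return list: `measurements` (data frame: timepoint, time_min,
#'   total_fi, volume_um3, n_scs), `trajectories` (list of
#'   `"sc_trajectory"` data frames with columns time_min, length_um,
#'   zip1_fi), `traces` (per-timepoint trace lists).
#' @export
measure_timecourse <- function(stack, k_sigma = 3, max_cost = 2) {
  d <- dim(stack)
  stopifnot(length(d) == 4L)
  voxel_size <- attr(stack, "voxel_size")
  if (is.null(voxel_size)) voxel_size <- c(0.2, 0.1, 0.1)
  tps <- attr(stack, "timepoints")
  if (is.null(tps)) {
    dt <- attr(stack, "time_interval")
    if (is.null(dt) || is.na(dt)) dt <- 1
    tps <- (seq_len(d[1]) - 1) * dt
  }
  meas <- NULL
  all_traces <- vector("list", d[1])
  # active SC identities: list(id, last_trace, missed, rows)
  active <- list(); next_id <- 1L; finished <- list()
  for (ti in seq_len(d[1])) {
    vol <- stack_frame(stack, ti)
    nuc <- segment_nucleus(vol, voxel_size)
    scm <- if (nuc$empty) array(FALSE, d[-1]) else {
      segment_sc_voxels(vol, nuc$mask, k_sigma)
    }
    diffuse_bg <- if (any(nuc$mask & !scm)) {
      stats::median(vol[nuc$mask & !scm])
    } else nuc$background
    traces <- trace_sc_polylines(scm, vol, voxel_size,
                                 background = diffuse_bg)
    all_traces[[ti]] <- traces
    meas <- rbind(meas, data.frame(
      timepoint = ti, time_min = tps[ti], total_fi = nuc$total_fi,
      volume_um3 = nuc$volume_um3, n_scs = length(traces)))
    prev <- lapply(active, `[[`, "last_trace")
    lk <- link_traces(prev, traces, max_cost)
    used <- rep(FALSE, length(active))
    new_active <- list()
    for (j in seq_along(traces)) {
      i <- lk$match[j]
      if (!is.na(i)) {
        a <- active[[i]]
        used[i] <- TRUE
        a$last_trace <- traces[[j]]
        a$missed <- 0L
        a$rows <- rbind(a$rows,
                        data.frame(time_min = tps[ti],
                                   length_um = traces[[j]]$length_um,
                                   zip1_fi = nuc$total_fi))
        new_active[[length(new_active) + 1L]] <- a
      } else {
        new_active[[length(new_active) + 1L]] <- list(
          id = sprintf("sc%03d", next_id),
          last_trace = traces[[j]], missed = 0L,
          rows = data.frame(time_min = tps[ti],
                            length_um = traces[[j]]$length_um,
                            zip1_fi = nuc$total_fi))
        next_id <- next_id + 1L
      }
    }
    for (i in seq_along(active)) {
      if (used[i]) next
      a <- active[[i]]
      a$missed <- a$missed + 1L
      a$rows <- rbind(a$rows,
                      data.frame(time_min = tps[ti], length_um = 0,
                                 zip1_fi = nuc$total_fi))
      if (a$missed >= 2L) {
        finished[[length(finished) + 1L]] <- a
      } else {
        new_active[[length(new_active) + 1L]] <- a
      }
    }
    active <- new_active
  }
  finished <- c(finished, active)
  trajectories <- lapply(finished, function(a) {
    structure(a$rows, sc_id = a$id,
              class = c("sc_trajectory", "data.frame"))
  })
  list(measurements = meas, trajectories = trajectories,
       traces = all_traces)
}
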