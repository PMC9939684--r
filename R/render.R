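# Rendering of nucleus scenes into 3D+time image stacks.

# dense arc-length resampling of a polyline at spacing ds
resample_polyline <- function(pts, ds = 0.02) {
  if (nrow(pts) < 2) return(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total < ds) return(pts[c(1, nrow(pts)), , drop = FALSE])
  svals <- seq(0, total, by = ds)
  t(vapply(svals, function(si) {
    j <- min(max(findInterval(si, s, rightmost.closed = TRUE), 1L),
             length(seg))
    w <- (si - s[j]) / seg[j]
    pts[j, ] * (1 - w) + pts[j + 1L, ] * w
  }, numeric(3)))
}

gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 1e-6) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k / sum(k)
}

# 1-D convolution along the first axis of a matrix (zero padding)
conv_cols <- function(mat, kernel) {
  if (length(kernel) == 1L) return(mat * kernel)
  n <- nrow(mat)
  r <- (length(kernel) - 1L) / 2L
  cm <- matrix(0, n, n)
  for (d in seq(-r, r)) {
    idx <- seq_len(n)
    src <- idx + d
    ok <- src >= 1L & src <= n
    cm[cbind(idx[ok], src[ok])] <- kernel[d + r + 1L]
  }
  cm %*% mat
}

# separable anisotropic Gaussian blur of a 3D (z, y, x) array
gauss_blur3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  kz <- gauss_kernel(sigma_vox[1])
  ky <- gauss_kernel(sigma_vox[2])
  kx <- gauss_kernel(sigma_vox[3])
  m <- matrix(arr, d[1], d[2] * d[3])            # z first
  arr <- array(conv_cols(m, kz), d)
  arr <- aperm(arr, c(2, 1, 3))                  # y first
  m <- matrix(arr, d[2], d[1] * d[3])
  arr <- array(conv_cols(m, ky), c(d[2], d[1], d[3]))
  arr <- aperm(arr, c(2, 1, 3))
  arr <- aperm(arr, c(3, 2, 1))                  # x first
  m <- matrix(arr, d[3], d[2] * d[1])
  arr <- array(conv_cols(m, kx), c(d[3], d[2], d[1]))
  aperm(arr, c(3, 2, 1))
}

#' Render a nucleus scene into a 3D+time image stack
#'
#' Voxelises the diffuse nucleoplasmic pool and the line-integral
#' brightness of every SC polyline, convolves each volume with an
#' anisotropic Gaussian point-spread function, and applies the standard
#' camera noise model: Poisson shot noise at `photon_scale` photons per
#' intensity unit plus additive Gaussian read noise, clipped at zero.
#'
#' SC line brightness is set so that the rendered filament peak is
#' `scene$contrast` times the diffuse level (default 5:1).
#'
#' @param scene a [build_scene()] result.
#' @param voxel_size `c(z, y, x)` um (default `c(0.2, 0.1, 0.1)`, the
#'   0.2-um optical sectioning used experimentally over a typical
#'   100x/1.45 NA xy pixel).
#' @param psf_sigma `c(z, xy)` um (default `c(0.25, 0.12)`).
#' @param photon_scale photons per IU; `Inf` disables shot noise.
#' @param read_noise_sd IU (default 0).
#' @param margin um of padding around the nucleus (default 0.6).
#' @param time_interval minutes between frames recorded in the metadata;
#'   defaults to the spacing of `scene$timepoints`.
#' @param seed integer seed for the noise.
#' @return 4D array `(t, z, y, x)` of class `"sc_stack"` with attributes
#'   `voxel_size`, `time_interval`, `origin` (um position of the first
#'   voxel centre), `nucleus_radius`, `scene_truth`.
#' @export
render_timelapse <- function(scene, voxel_size = c(0.2, 0.1, 0.1),
                             psf_sigma = c(0.25, 0.12),
                             photon_scale = Inf, read_noise_sd = 0,
                             margin = 0.6, time_interval = NULL,
                             seed = 1) {
  stopifnot(inherits(scene, "nucleus_scene"))
  if (photon_scale <= 0) stop("photon_scale must be positive")
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  half <- scene$nucleus_radius + margin
  dims <- ceiling(2 * half / voxel_size)         # (z, y, x) voxel counts
  centres <- lapply(1:3, function(a) {
    (seq_len(dims[a]) - 0.5) * voxel_size[a] - half
  })
  voxvol <- prod(voxel_size)
  # diffuse pool template: voxels whose centre lies inside the nucleus
  dist2 <- outer(outer(centres[[1]]^2, centres[[2]]^2, `+`),
                 centres[[3]]^2, `+`)
  inside <- dist2 <= scene$nucleus_radius^2
  rho <- scene$contrast * (scene$diffuse_intensity / voxvol) *
    2 * pi * psf_sigma[2] * psf_sigma[1]         # IU per um of filament
  sig_vox <- c(psf_sigma[1] / voxel_size[1],
               psf_sigma[2] / voxel_size[2],
               psf_sigma[2] / voxel_size[3])
  nt <- length(scene$timepoints)
  stack <- array(0, c(nt, dims))
  with_seed(seed, {
    for (ti in seq_len(nt)) {
      vol <- array(0, dims)
      dif <- scene$diffuse_intensity
      if (!is.null(scene$zip1)) {
        z <- scene$zip1
        dif <- dif * zip1_fi(z, scene$timepoints[ti] / 60) / z$plateau_level
      }
      vol[inside] <- dif
      for (sc in scene$sc[[ti]]) {
        dense <- resample_polyline(sc$points, ds = 0.02)
        if (nrow(dense) < 2) next
        seg <- sqrt(rowSums(diff(dense)^2))
        mass <- rho * c(seg / 2, 0) + rho * c(0, seg / 2)  # per vertex
        iz <- pmin(pmax(ceiling((dense[, 1] + half) / voxel_size[1]), 1L),
                   dims[1])
        iy <- pmin(pmax(ceiling((dense[, 2] + half) / voxel_size[2]), 1L),
                   dims[2])
        ix <- pmin(pmax(ceiling((dense[, 3] + half) / voxel_size[3]), 1L),
                   dims[3])
        for (p in seq_len(nrow(dense))) {
          vol[iz[p], iy[p], ix[p]] <- vol[iz[p], iy[p], ix[p]] + mass[p]
        }
      }
      vol <- gauss_blur3(vol, sig_vox)
      if (is.finite(photon_scale)) {
        vol <- array(stats::rpois(length(vol),
                                  pmax(vol, 0) * photon_scale) /
                       photon_scale, dims)
      }
      if (read_noise_sd > 0) {
        vol <- vol + array(stats::rnorm(length(vol), 0, read_noise_sd),
                           dims)
      }
      stack[ti, , , ] <- pmax(vol, 0)
    }
  })
  if (is.null(time_interval)) {
    time_interval <- if (nt > 1) diff(scene$timepoints)[1] else NA_real_
  }
  structure(stack,
            voxel_size = voxel_size,
            time_interval = time_interval,
            timepoints = scene$timepoints,
            origin = -half + voxel_size / 2,
            nucleus_radius = scene$nucleus_radius,
            scene_truth = scene$truth,
            class = "sc_stack")
}

#' Extract one 3D volume from a 4D stack
#' @param stack an `"sc_stack"` (t, z, y, x) array or a plain 3D array.
#' @param t timepoint index.
#' @return 3D (z, y, x) array; voxel-size attribute is carried over.
#' @export
stack_frame <- function(stack, t = 1L) {
  if (length(dim(stack)) == 3L) return(stack)
  vol <- array(stack[t, , , ], dim(stack)[-1])
  attr(vol, "voxel_size") <- attr(stack, "voxel_size")
  vol
}

#' Write a 3D+time stack as multi-page TIFF with JSON metadata sidecar
#'
#' Pages are the z-slices of successive timepoints; intensities are
#' rescaled to the unit range for 32-bit float TIFF storage and the scale
#' factor, voxel size, time interval and array dimensions are written to
#' `<file>.json` alongside.
#'
#' @param stack an `"sc_stack"`.
#' @param file output TIFF path.
#' @return `file`, invisibly.
#' @export
write_stack_tiff <- function(stack, file) {
  d <- dim(stack)
  scale <- max(stack, 1e-12)
  pages <- list()
  for (ti in seq_len(d[1])) {
    for (zi in seq_len(d[2])) {
      pages[[length(pages) + 1L]] <-
        matrix(stack[ti, zi, , ] / scale, d[3], d[4])
    }
  }
  tiff::writeTIFF(pages, file, bits.per.sample = 32L)
  meta <- list(dims = d, scale = scale,
               voxel_size_um = attr(stack, "voxel_size"),
               time_interval_min = attr(stack, "time_interval"),
               timepoints_min = attr(stack, "timepoints"))
  jsonlite::write_json(meta, paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a stack written by [write_stack_tiff()]
#' @param file TIFF path (its `.json` sidecar must be present).
#' @return an `"sc_stack"` 4D array.
#' @export
read_stack_tiff <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(file, all = TRUE)
  d <- meta$dims
  stack <- array(0, d)
  p <- 1L
  for (ti in seq_len(d[1])) {
    for (zi in seq_len(d[2])) {
      stack[ti, zi, , ] <- pages[[p]] * meta$scale
      p <- p + 1L
    }
  }
  structure(stack,
            voxel_size = meta$voxel_size_um,
            time_interval = meta$time_interval_min,
            timepoints = meta$timepoints_min,
            class = "sc_stack")
}
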