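# Detection and measurement of nuclei and SC filaments in 3D stacks.

# Otsu threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) < 1e-12) return(Inf)
  h <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = 257),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# connected-component labelling of a 3D logical array (26-connectivity)
label_components <- function(mask) {
  d <- dim(mask)
  coords <- which(mask, arr.ind = TRUE)
  n <- nrow(coords)
  labels <- array(0L, d)
  if (n == 0L) return(labels)
  lin <- coords[, 1] + (coords[, 2] - 1L) * d[1] +
    (coords[, 3] - 1L) * d[1] * d[2]
  idmap <- integer(prod(d))
  idmap[lin] <- seq_len(n)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]                     # half of the 26 neighbours
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    ni <- coords[, 1] + offs[r, 1]
    nj <- coords[, 2] + offs[r, 2]
    nk <- coords[, 3] + offs[r, 3]
    ok <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] &
      nk >= 1L & nk <= d[3]
    nlin <- ni[ok] + (nj[ok] - 1L) * d[1] + (nk[ok] - 1L) * d[1] * d[2]
    nid <- idmap[nlin]
    hit <- nid > 0L
    if (any(hit)) {
      edges <- rbind(edges, cbind(which(ok)[hit], nid[hit]))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  labels[lin] <- comp
  labels
}

#' Segment the nucleus in a single 3D volume
#'
#' The nucleus is the connected region of above-background diffuse
#' Zip1-GFP signal.  The volume is smoothed with a 1-voxel Gaussian, Otsu's
#' threshold separates nucleoplasm from background, and the largest
#' connected component is kept.  The background level is the mode of the
#' out-of-nucleus voxel histogram, and the total fluorescence is the
#' background-subtracted sum over the whole volume (intensity spread
#' beyond the mask by the PSF is thereby conserved).
#'
#' @param vol 3D (z, y, x) array (one timepoint), or an `"sc_stack"` with
#'   a single timepoint.
#' @param voxel_size `c(z, y, x)` um; defaults to the array's attribute or
#'   `c(0.2, 0.1, 0.1)`.
#' @return list: `mask` (logical array), `background` (IU), `volume_um3`,
#'   `total_fi` (IU), `empty` (flag: no nucleus found).
#' @export
segment_nucleus <- function(vol, voxel_size = NULL) {
  vol <- stack_frame(vol)
  if (is.null(voxel_size)) {
    voxel_size <- attr(vol, "voxel_size")
    if (is.null(voxel_size)) voxel_size <- c(0.2, 0.1, 0.1)
  }
  d <- dim(vol)
  sm <- gauss_blur3(array(vol, d), c(1, 1, 1))
  if (diff(range(sm)) < 1e-9) {
    return(list(mask = array(FALSE, d), background = stats::median(vol),
                volume_um3 = 0, total_fi = 0, empty = TRUE))
  }
  # two-pass threshold: Otsu gives a first cut, then the nucleus boundary
  # is re-drawn at half-way between the outside background mode and the
  # inside diffuse median, so a bright SC inside the nucleus cannot drag
  # the boundary inward
  thr <- otsu_threshold(as.numeric(sm))
  mask <- sm > thr
  if (!any(mask)) {
    return(list(mask = mask, background = stats::median(vol),
                volume_um3 = 0, total_fi = 0, empty = TRUE))
  }
  mode_of <- function(v) {
    h <- graphics::hist(v, breaks = 64, plot = FALSE)
    h$mids[which.max(h$counts)]
  }
  background <- mode_of(vol[!mask])
  diffuse <- stats::median(sm[mask])
  mask <- sm > background + 0.5 * (diffuse - background)
  if (!any(mask)) {
    return(list(mask = mask, background = background,
                volume_um3 = 0, total_fi = 0, empty = TRUE))
  }
  labels <- label_components(mask)
  tab <- tabulate(labels[labels > 0L])
  mask <- labels == which.max(tab)
  background <- mode_of(vol[!mask])
  total_fi <- sum(vol) - background * length(vol)
  list(mask = mask, background = background,
       volume_um3 = sum(mask) * prod(voxel_size),
       total_fi = total_fi, empty = FALSE)
}

#' Segment SC filament voxels within a nucleus
#'
#' After 1-voxel Gaussian smoothing, voxels brighter than the nuclear
#' diffuse level plus `k_sigma` diffuse standard deviations are kept
#' (restricted to the nucleus mask).  The diffuse mean and SD are
#' estimated robustly (median and scaled MAD) from the interior half of
#' the nucleus so that the bright SC minority does not inflate them.
#' Connected components smaller than 3 voxels are discarded.
#'
#' @param vol 3D volume.
#' @param nucleus logical nucleus mask (from [segment_nucleus()]).
#' @param k_sigma threshold multiplier (default 3).
#' @return logical SC voxel mask.
#' @export
segment_sc_voxels <- function(vol, nucleus, k_sigma = 3) {
  vol <- stack_frame(vol)
  d <- dim(vol)
  sm <- gauss_blur3(array(vol, d), c(1, 1, 1))
  if (!any(nucleus)) return(array(FALSE, d))
  coords <- which(nucleus, arr.ind = TRUE)
  ctr <- colMeans(coords)
  dist2 <- (coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2 +
    (coords[, 3] - ctr[3])^2
  interior <- coords[dist2 <= stats::median(dist2), , drop = FALSE]
  iv <- sm[interior]
  # diffuse level and spread estimated from the histogram mode and the
  # deviations below it: bright SC voxels can dominate the interior when
  # several filaments cross it, but they cannot contaminate the lower
  # half of the diffuse peak
  h <- graphics::hist(iv, breaks = 64, plot = FALSE)
  mu <- h$mids[which.max(h$counts)]
  below <- mu - iv[iv <= mu]
  sdv <- 1.4826 * stats::median(below)
  thr <- mu + k_sigma * max(sdv, 1e-9)
  mask <- sm > thr & nucleus
  if (!any(mask)) return(mask)
  labels <- label_components(mask)
  tab <- tabulate(labels[labels > 0L])
  small <- which(tab < 3L)
  if (length(small)) mask[labels %in% small] <- FALSE
  mask
}

#' Maximum and summation projections along z
#'
#' @param vol 3D (z, y, x) volume.
#' @return list with 2D matrices `max` and `sum`.
#' @export
project_max_sum <- function(vol) {
  vol <- stack_frame(vol)
  list(max = apply(vol, c(2, 3), max),
       sum = apply(vol, c(2, 3), sum))
}
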