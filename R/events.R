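# Event-level analysis: Zip1-profile alignment, onset thresholds,
# assembly/final/abortive classification, accumulation rates, size classes.

#' Time of Zip1 depletion in a fluorescence profile
#'
#' Depletion is the first time after the profile maximum at which FI falls
#' to 10% (or `frac`) of that cell's maximum, located by linear
#' interpolation between samples.
#'
#' @param profile a `"zip1_profile"` data frame (columns `time_h`, `fi`)
#'   or any data frame with those columns.
#' @param frac depletion threshold as a fraction of the maximum
#'   (default 0.10).
#' @return depletion time in hours, or `NA` (with attribute
#'   `flag = "no_depletion"`) when the profile never falls below the
#'   threshold.
#' @export
detect_depletion_time <- function(profile, frac = 0.10) {
  t <- profile$time_h; fi <- profile$fi
  imax <- which.max(fi)
  thr <- frac * fi[imax]
  post_t <- t[imax:length(t)]; post_fi <- fi[imax:length(fi)]
  below <- which(post_fi <= thr)
  if (!length(below)) {
    return(structure(NA_real_, flag = "no_depletion"))
  }
  i <- below[1]
  if (i == 1L) return(post_t[1])
  # linear interpolation between the last sample above and first at/below
  t0 <- post_t[i - 1L]; t1 <- post_t[i]
  f0 <- post_fi[i - 1L]; f1 <- post_fi[i]
  if (f0 == f1) return(t1)
  t0 + (f0 - thr) / (f0 - f1) * (t1 - t0)
}

#' Align Zip1 profiles at depletion and average them
#'
#' Each profile's times are shifted so that its depletion time is zero,
#' samples are binned at the acquisition interval, and the per-bin mean FI
#' (and mean SC count, when a `n_scs` column is present) is computed over
#' cells.  Profiles with no depletion are excluded and counted.
#'
#' @param profiles list of profile data frames (columns `time_h`, `fi`,
#'   optional `n_scs`).
#' @param bin_width hours; default: median sampling interval of the first
#'   profile.
#' @return data frame of class `"aligned_profiles"`: `relative_time_h`,
#'   `mean_fi`, `mean_n_scs` (NA when absent), `n_cells`; attribute
#'   `n_excluded`.
#' @export
align_and_average <- function(profiles, bin_width = NULL) {
  stopifnot(length(profiles) > 0)
  if (is.null(bin_width)) {
    bin_width <- stats::median(diff(profiles[[1]]$time_h))
  }
  shifted <- list(); n_excluded <- 0L
  for (p in profiles) {
    dep <- detect_depletion_time(p)
    if (is.na(dep)) {
      n_excluded <- n_excluded + 1L
      next
    }
    q <- p
    q$rel <- round((p$time_h - dep) / bin_width) * bin_width
    shifted[[length(shifted) + 1L]] <- q
  }
  if (!length(shifted)) stop("no profile has a depletion time")
  all <- do.call(rbind, lapply(shifted, function(q) {
    data.frame(rel = q$rel, fi = q$fi,
               n_scs = if ("n_scs" %in% names(q)) q$n_scs else NA_real_)
  }))
  agg <- do.call(rbind, lapply(split(all, all$rel), function(g) {
    data.frame(relative_time_h = g$rel[1],
               mean_fi = mean(g$fi),
               mean_n_scs = if (all(is.na(g$n_scs))) NA_real_
                            else mean(g$n_scs, na.rm = TRUE),
               n_cells = nrow(g))
  }))
  agg <- agg[order(agg$relative_time_h), ]
  rownames(agg) <- NULL
  structure(agg, n_excluded = n_excluded,
            class = c("aligned_profiles", "data.frame"))
}

#' Synapsis-onset fluorescence threshold of a cohort
#'
#' The mean total nuclear FI at the moment each cell's first SC is
#' detected; cells in which no SC ever appears are excluded and counted.
#'
#' @param profiles list of profile data frames with columns `time_h`,
#'   `fi`, and either a `n_scs` column or a `first_sc_time` attribute (as
#'   set by [simulate_zip1_profile()]).
#' @return mean onset FI (IU) with attribute `n_excluded`.
#' @export
detect_onset_threshold <- function(profiles) {
  fis <- numeric(0); n_excluded <- 0L
  for (p in profiles) {
    t1 <- attr(p, "first_sc_time")
    if (is.null(t1) && "n_scs" %in% names(p)) {
      w <- which(p$n_scs >= 1)
      t1 <- if (length(w)) p$time_h[w[1]] else NA_real_
    }
    if (is.null(t1) || is.na(t1)) {
      n_excluded <- n_excluded + 1L
      next
    }
    fis <- c(fis, p$fi[which.min(abs(p$time_h - t1))])
  }
  if (!length(fis)) stop("no cell with a detected first SC")
  structure(mean(fis), n_excluded = n_excluded)
}

#' Classify one SC trajectory as assembly, final or abortive disassembly
#'
#' An SC that disappears (length at or below `zero_tol` for at least two
#' consecutive frames) while the nuclear Zip1 fluorescence is still at or
#' above `abortive_threshold` of its running maximum is an abortive
#' disassembly; a disappearance accompanied by FI decline below that
#' fraction is final disassembly; a trajectory that persists to the end of
#' the record is assembly.  The disassembly rate is fitted on the
#' shortening portion (running maximum to disappearance) with the
#' lag-aware rule of [disassembly_rate()]; growing portions are fitted for
#' the assembly rate.
#'
#' @param traj `"sc_trajectory"` data frame with columns `time_min`,
#'   `length_um` and `zip1_fi` (total nuclear FI context).
#' @param abortive_threshold fraction of running-max FI above which a
#'   disappearance is abortive (default 0.75).
#' @param zero_tol um below which a length counts as disappeared
#'   (default 0.1, one xy pixel).
#' @param size_breaks um boundaries of the small/medium/large classes
#'   (default 0.5 and 1.5; classes are half-open `[0, 0.5)`, `[0.5, 1.5)`,
#'   `[1.5, Inf)`).
#' @return data frame (one row) of class `"sc_event"`: `sc_id`,
#'   `event_type`, `rate_nm_min`, `max_length_um`, `size_class`,
#'   `fi_at_disappearance_fraction`.
#' @export
classify_event <- function(traj, abortive_threshold = 0.75,
                           zero_tol = 0.1, size_breaks = c(0.5, 1.5)) {
  stopifnot(all(c("time_min", "length_um") %in% names(traj)))
  fi <- if ("zip1_fi" %in% names(traj)) traj$zip1_fi else
    rep(NA_real_, nrow(traj))
  len <- traj$length_um; tt <- traj$time_min
  n <- length(len)
  zero <- len <= zero_tol
  # disappearance: trailing run of >= 2 zero frames after a nonzero phase
  disappeared <- FALSE; i_gone <- NA_integer_
  if (n >= 3) {
    runs <- rle(zero)
    k <- length(runs$values)
    if (runs$values[k] && runs$lengths[k] >= 2 && !all(zero)) {
      disappeared <- TRUE
      i_gone <- n - runs$lengths[k] + 1L
    }
  }
  max_len <- max(len)
  size_class <- cut(max_len, c(0, size_breaks, Inf),
                    labels = c("small", "medium", "large"), right = FALSE)
  if (!disappeared) {
    rate <- fit_portion_rate(tt, len, which.max(len), direction = "up")
    ev <- "assembly"; fi_frac <- NA_real_
  } else {
    run_max <- cummax(ifelse(is.na(fi), -Inf, fi))
    fi_frac <- if (all(is.na(fi))) NA_real_ else fi[i_gone] / run_max[i_gone]
    ev <- if (!is.na(fi_frac) && fi_frac >= abortive_threshold) {
      "abortive_disassembly"
    } else "final_disassembly"
    i_max <- which.max(len)
    keep <- i_max:(i_gone - 1L)
    keep <- keep[len[keep] > zero_tol]
    rate <- fit_portion_rate(tt, len, keep, direction = "down")
  }
  structure(data.frame(sc_id = attr(traj, "sc_id") %||% NA_character_,
                       event_type = ev,
                       rate_nm_min = rate,
                       max_length_um = max_len,
                       size_class = as.character(size_class),
                       fi_at_disappearance_fraction = fi_frac,
                       stringsAsFactors = FALSE),
            class = c("sc_event", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fit a rate on part of a trajectory; `idx` either indices to use (down)
# or the index of the maximum (up: everything up to the maximum is used)
fit_portion_rate <- function(tt, len, idx, direction) {
  use <- if (direction == "up") seq_len(max(idx, 2L)) else idx
  if (length(use) < 3L) return(NA_real_)
  if (length(use) < 6L) {
    f <- fit_piecewise_linear(tt[use], len[use], 1L)
    return(f$slopes[1])
  }
  kin <- fit_sc_kinetics(tt[use], len[use])
  if (direction == "down") disassembly_rate(kin$best)$rate
  else kin$initial_rate
}

#' Classify every trajectory of a set
#'
#' @param trajectories list of trajectories (see [classify_event()]).
#' @param ... passed to [classify_event()].
#' @return data frame of events, one row per trajectory.
#' @export
classify_events <- function(trajectories, ...) {
  do.call(rbind, lapply(trajectories, classify_event, ...))
}

#' SC accumulation rate of a nucleus
#'
#' Maximum number of simultaneously distinguishable SCs divided by the
#' time from the first SC to the first attainment of that maximum plus one
#' acquisition interval (so single-step attainment does not divide by
#' zero).
#'
#' @param n_scs integer vector of SC counts per timepoint.
#' @param times_h acquisition times (hours).
#' @return SCs per hour, or `NA` (flagged) when no SC is ever seen.
#' @export
accumulation_rate <- function(n_scs, times_h) {
  stopifnot(length(n_scs) == length(times_h))
  if (all(n_scs == 0)) {
    return(structure(NA_real_, flag = "no_sc"))
  }
  interval <- stats::median(diff(times_h))
  t_first <- times_h[which(n_scs > 0)[1]]
  mx <- max(n_scs)
  t_max <- times_h[which(n_scs == mx)[1]]
  mx / (t_max - t_first + interval)
}

#' Size-class composition of SC events
#'
#' Fractions of events in the small (< 0.5 um), medium (0.5-1.5 um) and
#' large (> 1.5 um) classes, per event type.
#'
#' @param events data frame from [classify_events()] (columns
#'   `event_type`, `size_class`).
#' @param by group by event type (default TRUE).
#' @return data frame: event_type, small, medium, large (fractions summing
#'   to 1 within each row).
#' @export
size_class_histogram <- function(events, by = TRUE) {
  stopifnot(nrow(events) > 0)
  classes <- c("small", "medium", "large")
  split_on <- if (by) events$event_type else rep("all", nrow(events))
  out <- do.call(rbind, lapply(split(events, split_on), function(g) {
    counts <- vapply(classes, function(cl) sum(g$size_class == cl),
                     numeric(1))
    data.frame(event_type = g$event_type[1],
               small = counts[1] / nrow(g),
               medium = counts[2] / nrow(g),
               large = counts[3] / nrow(g))
  }))
  rownames(out) <- NULL
  out
}
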