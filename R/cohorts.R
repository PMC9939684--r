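# Cohort generators: batches of simulated trajectories drawn at the
# printed population parameters, with full ground-truth bookkeeping.

# rejection-sampled truncated normal
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x > lower && x < upper) break
    }
    out[i] <- x
  }
  out
}

# pick the widest acquisition interval (10, 5 or 3 min) that still gives a
# fittable number of samples over `duration` minutes
pick_interval <- function(duration, min_points = 5L,
                          candidates = c(10, 5, 3)) {
  for (dt in candidates) {
    if (floor(duration / dt) + 1L >= min_points) return(dt)
  }
  candidates[length(candidates)]
}

#' Simulate a cohort of SC assembly trajectories
#'
#' Draws a mixture of monophasic and biphasic assembly events at the
#' population parameters of the live-cell measurements: monophasic rates
#' N(56, 23^2) nm/min, biphasic first-phase rates N(88, 42^2) and
#' second-phase rates N(19, 12^2) (all truncated positive), phase-1 length
#' fractions N(0.59, 0.16^2) truncated to (0.05, 0.95), final SC lengths
#' uniform on 1.5-3.0 um (single long synapsing chromosome), 3-min
#' sampling.
#'
#' @param n number of trajectories (default 34).
#' @param mono_fraction expected monophasic share (default 0.65); the
#'   realised number of monophasic events is `round(mono_fraction * n)` so
#'   the mixture is exact per cohort.
#' @param seed integer seed.
#' @param mono_rate,mono_rate_sd monophasic rate distribution (nm/min).
#' @param bi_rate1,bi_rate1_sd first-phase rate distribution (nm/min).
#' @param bi_rate2,bi_rate2_sd second-phase rate distribution (nm/min).
#' @param frac1,frac1_sd phase-1 length fraction distribution.
#' @param length_range final SC length range (um).
#' @param sampling_interval minutes (default 3).
#' @param noise_sd measurement noise (um, default 0.05).
#' @param max_points observation-window cap per trajectory (default 50
#'   samples; very slow second phases are truncated rather than followed
#'   for hours).
#' @return object of class `"sc_cohort"`: list with `trajectories` (list of
#'   `"sc_trajectory"`) and `truth` (data frame: sc_id, phasic, rate1,
#'   rate2, frac1, final_length_um).
#' @export
simulate_assembly_cohort <- function(n = 34, mono_fraction = 0.65,
                                     seed = 1,
                                     mono_rate = 56, mono_rate_sd = 23,
                                     bi_rate1 = 88, bi_rate1_sd = 42,
                                     bi_rate2 = 19, bi_rate2_sd = 12,
                                     frac1 = 0.59, frac1_sd = 0.16,
                                     length_range = c(1.5, 3),
                                     sampling_interval = 3,
                                     noise_sd = 0.05,
                                     max_points = 50L) {
  with_seed(seed, {
    n_mono <- round(mono_fraction * n)
    is_mono <- rep(c(TRUE, FALSE), c(n_mono, n - n_mono))
    trajs <- vector("list", n)
    truth <- data.frame(sc_id = sprintf("sc%03d", seq_len(n)),
                        phasic = ifelse(is_mono, "monophasic", "biphasic"),
                        rate1 = NA_real_, rate2 = NA_real_,
                        frac1 = NA_real_, final_length_um = NA_real_)
    for (i in seq_len(n)) {
      L <- stats::runif(1, length_range[1], length_range[2])
      if (is_mono[i]) {
        r1 <- rtrunc_norm(1, mono_rate, mono_rate_sd, lower = 0)
        model <- kinetic_model(truth$sc_id[i],
                               phases = list(c(r1, L * 1000 / r1)))
        truth$rate1[i] <- r1
      } else {
        r1 <- rtrunc_norm(1, bi_rate1, bi_rate1_sd, lower = 0)
        r2 <- rtrunc_norm(1, bi_rate2, bi_rate2_sd, lower = 0)
        f <- rtrunc_norm(1, frac1, frac1_sd, lower = 0.05, upper = 0.95)
        model <- kinetic_model(truth$sc_id[i],
                               phases = list(c(r1, f * L * 1000 / r1),
                                             c(r2, (1 - f) * L * 1000 / r2)))
        truth$rate1[i] <- r1; truth$rate2[i] <- r2; truth$frac1[i] <- f
      }
      truth$final_length_um[i] <- L
      trajs[[i]] <- simulate_trajectory(model, sampling_interval,
                                        noise_sd = noise_sd,
                                        max_points = max_points)
    }
    structure(list(trajectories = trajs, truth = truth),
              class = "sc_cohort")
  })
}

#' Simulate a cohort of final-disassembly trajectories
#'
#' Monophasic shrinkage from full length to zero at rates drawn from
#' N(-66, 30^2) nm/min (truncated negative).  The acquisition interval is
#' chosen per event from the 3-10 min range used experimentally: the widest
#' of 10, 5 or 3 min that still yields at least five samples before the SC
#' vanishes, so fast events are sampled faster instead of being dropped.
#'
#' @param n number of trajectories (default 50).
#' @param seed integer seed.
#' @param rate,rate_sd disassembly rate distribution (nm/min; mean is
#'   negative).
#' @param length_range initial SC length range (um).
#' @param noise_sd measurement noise (um).
#' @param lag if TRUE, prepend a slow initial phase (-5 nm/min for 10 min)
#'   before rapid shortening, emulating the brief low-rate period sometimes
#'   seen at the start of final disassembly.
#' @param max_points observation-window cap per trajectory (default 40
#'   samples; a rare near-zero rate draw would otherwise be followed for
#'   many hours).
#' @return an `"sc_cohort"` (truth columns: sc_id, rate1, start_length_um,
#'   sampling_interval).
#' @export
simulate_disassembly_cohort <- function(n = 50, seed = 1,
                                        rate = -66, rate_sd = 30,
                                        length_range = c(1.5, 3),
                                        noise_sd = 0.05,
                                        lag = FALSE, max_points = 40L) {
  with_seed(seed, {
    trajs <- vector("list", n)
    truth <- data.frame(sc_id = sprintf("dis%03d", seq_len(n)),
                        rate1 = NA_real_, start_length_um = NA_real_,
                        sampling_interval = NA_real_)
    for (i in seq_len(n)) {
      L <- stats::runif(1, length_range[1], length_range[2])
      r <- rtrunc_norm(1, rate, rate_sd, upper = 0)
      lag_len <- if (lag) 5 * 10 / 1000 else 0   # um removed during lag
      build <- list(c(100, (L + lag_len) * 1000 / 100))   # fast assembly
      dis <- if (lag) {
        list(c(-5, 10), c(r, L * 1000 / abs(r)))
      } else {
        list(c(r, L * 1000 / abs(r)))
      }
      model <- kinetic_model(truth$sc_id[i], phases = build,
                             disassembly_phases = dis,
                             event_type = "assembly_then_final")
      t_dis <- sum(vapply(build, `[[`, numeric(1), 2))   # disassembly start
      dur <- sum(vapply(dis, `[[`, numeric(1), 2))
      dt <- pick_interval(dur)
      trajs[[i]] <- simulate_trajectory(model, dt, noise_sd = noise_sd,
                                        window = c(t_dis,
                                                   t_dis +
                                                     min(dur, (max_points -
                                                                 1L) * dt)))
      truth$rate1[i] <- r
      truth$start_length_um[i] <- L
      truth$sampling_interval[i] <- dt
    }
    structure(list(trajectories = trajs, truth = truth),
              class = "sc_cohort")
  })
}

#' Simulate a cohort of abortive-disassembly trajectories
#'
#' Medium and large SCs that shrink to zero at ~25 nm/min while the
#' nucleus's Zip1 fluorescence remains at plateau, the signature that
#' distinguishes abortive from final disassembly.  Each trajectory carries
#' a `zip1_fi` column (total nuclear FI context, held at the zip3-deletion
#' plateau level) and two trailing zero-length frames after disappearance.
#'
#' @param n number of trajectories (default 15).
#' @param seed integer seed.
#' @param rate,rate_sd shrink-rate distribution (nm/min; default -25, SD 1).
#' @param length_range initial SC length range (um; default 1.0-2.5,
#'   medium/large size classes).
#' @param sampling_interval minutes (default 5).
#' @param noise_sd measurement noise (um).
#' @param plateau_fi nuclear FI during the events (IU; default the zip3d
#'   plateau, 424).
#' @return an `"sc_cohort"` (truth columns: sc_id, rate1, start_length_um).
#' @export
simulate_abortive_cohort <- function(n = 15, seed = 1,
                                     rate = -25, rate_sd = 1,
                                     length_range = c(1.0, 2.5),
                                     sampling_interval = 5,
                                     noise_sd = 0.05,
                                     plateau_fi = 424) {
  with_seed(seed, {
    trajs <- vector("list", n)
    truth <- data.frame(sc_id = sprintf("abo%03d", seq_len(n)),
                        rate1 = NA_real_, start_length_um = NA_real_)
    for (i in seq_len(n)) {
      L <- stats::runif(1, length_range[1], length_range[2])
      r <- rtrunc_norm(1, rate, rate_sd, upper = 0)
      dur <- L * 1000 / abs(r)
      model <- kinetic_model(truth$sc_id[i],
                             phases = list(c(100, L * 1000 / 100)),
                             disassembly_phases = list(c(r, dur)),
                             event_type = "assembly_then_abortive")
      t_dis <- L * 1000 / 100
      tr <- simulate_trajectory(model, sampling_interval,
                                noise_sd = noise_sd,
                                window = c(t_dis,
                                           t_dis + dur +
                                             2 * sampling_interval))
      # after complete disassembly there is nothing to detect: the tracker
      # reports exactly zero, not measurement noise
      tr$length_um[attr(tr, "true_length_um") == 0] <- 0
      tr$zip1_fi <- plateau_fi
      trajs[[i]] <- tr
      truth$rate1[i] <- r
      truth$start_length_um[i] <- L
    }
    structure(list(trajectories = trajs, truth = truth),
              class = "sc_cohort")
  })
}

#' Simulate a mixed cohort of labelled assembly/final/abortive events
#'
#' Builds trajectories with their nuclear Zip1 context for end-to-end
#' classifier validation: assembly events persist to the end of the record
#' under rising Zip1; final-disassembly events shrink to zero while Zip1
#' falls with them; abortive events shrink to zero while Zip1 stays at
#' plateau.  Disappeared SCs carry two trailing zero-length frames, as the
#' tracker would report.
#'
#' @param n_assembly,n_final,n_abortive event counts.
#' @param seed integer seed.
#' @param noise_sd trajectory noise (um).
#' @param plateau_fi nuclear plateau fluorescence (IU, default 424).
#' @return an `"sc_cohort"`; `truth$event_type` holds the generating label.
#' @export
simulate_event_cohort <- function(n_assembly = 10, n_final = 10,
                                  n_abortive = 10, seed = 1,
                                  noise_sd = 0.05, plateau_fi = 424) {
  asm <- simulate_assembly_cohort(n = max(n_assembly, 1),
                                  seed = child_seed(seed, 1),
                                  noise_sd = noise_sd)
  fin <- simulate_disassembly_cohort(n = max(n_final, 1),
                                     seed = child_seed(seed, 2),
                                     noise_sd = noise_sd)
  abo <- simulate_abortive_cohort(n = max(n_abortive, 1),
                                  seed = child_seed(seed, 3),
                                  noise_sd = noise_sd,
                                  plateau_fi = plateau_fi)
  trajs <- list(); truth <- NULL
  add <- function(tr, label) {
    trajs[[length(trajs) + 1L]] <<- tr
    truth <<- rbind(truth, data.frame(sc_id = attr(tr, "sc_id"),
                                      event_type = label))
  }
  for (tr in asm$trajectories[seq_len(n_assembly)]) {
    # rising sub-plateau Zip1 during the accumulation phase
    tr$zip1_fi <- plateau_fi * (0.6 + 0.4 * seq_len(nrow(tr)) / nrow(tr))
    add(tr, "assembly")
  }
  for (tr in fin$trajectories[seq_len(n_final)]) {
    id <- attr(tr, "sc_id")
    dt <- stats::median(diff(tr$time_min))
    last <- tr$time_min[nrow(tr)]
    tr <- rbind(as.data.frame(tr),
                data.frame(time_min = last + dt * (1:2), length_um = 0))
    # Zip1 degraded alongside the SCs: falls from plateau to 20%
    tr$zip1_fi <- plateau_fi * seq(1, 0.2, length.out = nrow(tr))
    attr(tr, "sc_id") <- id
    add(tr, "final_disassembly")
  }
  for (tr in abo$trajectories[seq_len(n_abortive)]) {
    add(tr, "abortive_disassembly")
  }
  # restore per-trajectory ids lost in rbind above
  for (i in seq_along(trajs)) {
    attr(trajs[[i]], "sc_id") <- truth$sc_id[i]
    class(trajs[[i]]) <- c("sc_trajectory", "data.frame")
  }
  structure(list(trajectories = trajs, truth = truth),
            class = "sc_cohort")
}

#' @export
print.sc_cohort <- function(x, ...) {
  cat(sprintf("SC trajectory cohort: %d trajectories\n",
              length(x$trajectories)))
  if ("phasic" %in% names(x$truth)) {
    print(table(x$truth$phasic))
  }
  invisible(x)
}

#' Fit every trajectory of a cohort and summarise recovered rates
#'
#' Runs [fit_sc_kinetics()] on each trajectory (falling back to a plain
#' one-segment fit when a trajectory has only three points) and tabulates
#' the selected model class and fitted rates.
#'
#' @param cohort an `"sc_cohort"`.
#' @param direction `"assembly"` (first-segment slope is the initial rate)
#'   or `"disassembly"` (the main-phase slope from [disassembly_rate()],
#'   lag-aware).
#' @param ... passed to [fit_sc_kinetics()].
#' @return data frame: sc_id, n_points, n_segments, phasic, initial_rate,
#'   second_rate, phase1_length_fraction, rate (direction-appropriate
#'   headline rate, nm/min), adj_r2, press.
#' @export
fit_cohort <- function(cohort, direction = c("assembly", "disassembly"),
                       ...) {
  stopifnot(inherits(cohort, "sc_cohort"))
  direction <- match.arg(direction)
  rows <- lapply(cohort$trajectories, function(tr) {
    n <- nrow(tr)
    if (n < 6L) {
      f <- fit_piecewise_linear(tr$time_min, tr$length_um, 1L)
      kin <- list(best = f, phasic = "monophasic",
                  initial_rate = f$slopes[1], second_rate = NA_real_,
                  phase1_length_fraction = NA_real_,
                  candidates = data.frame(adj_r2 = NA_real_,
                                          press = NA_real_))
    } else {
      kin <- fit_sc_kinetics(tr, ...)
    }
    rate <- if (direction == "assembly") {
      kin$initial_rate
    } else {
      disassembly_rate(kin$best)$rate
    }
    data.frame(sc_id = attr(tr, "sc_id"),
               n_points = n,
               n_segments = kin$best$n_segments,
               phasic = kin$phasic,
               initial_rate = kin$initial_rate,
               second_rate = kin$second_rate,
               phase1_length_fraction = kin$phase1_length_fraction,
               rate = rate,
               adj_r2 = max(kin$candidates$adj_r2),
               press = min(kin$candidates$press))
  })
  do.call(rbind, rows)
}
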