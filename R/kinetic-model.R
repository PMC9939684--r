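#' Ground-truth kinetic program for one synaptonemal complex
#'
#' A `kinetic_model` is the piecewise-linear length program of a single SC:
#' an onset time, one or more assembly phases (positive rates), an optional
#' plateau, and optional disassembly phases (negative rates).  It is the
#' ground truth against which trajectory fitting is validated.
#'
#' @param sc_id identifier.
#' @param phases list of assembly phases, each `c(rate, duration)` with rate
#'   in nm/min (> 0) and duration in minutes.
#' @param onset_time minutes at which assembly begins (length 0 before).
#' @param plateau_duration minutes at full length before disassembly.
#' @param disassembly_phases list of `c(rate, duration)` phases with
#'   negative rates (nm/min).
#' @param event_type one of `"assembly_only"`, `"assembly_then_final"`,
#'   `"assembly_then_abortive"`.
#' @return object of class `"kinetic_model"`.
#' @examples
#' m <- kinetic_model("sc1", phases = list(c(56, 30)))
#' true_length(m, c(0, 15, 30, 60))
#' @export
kinetic_model <- function(sc_id, phases, onset_time = 0,
                          plateau_duration = 0,
                          disassembly_phases = list(),
                          event_type = c("assembly_only",
                                         "assembly_then_final",
                                         "assembly_then_abortive")) {
  event_type <- match.arg(event_type)
  chk <- function(ph, sign, what) {
    for (p in ph) {
      if (length(p) != 2L || !is.numeric(p)) {
        stop(what, " phases must be numeric c(rate, duration) pairs")
      }
      if (sign > 0 && p[1] <= 0) stop("assembly rates must be > 0")
      if (sign < 0 && p[1] >= 0) stop("disassembly rates must be < 0")
      if (p[2] < 0) stop("phase durations must be >= 0")
    }
  }
  chk(phases, +1, "assembly")
  chk(disassembly_phases, -1, "disassembly")
  if (plateau_duration < 0) stop("plateau_duration must be >= 0")
  m <- structure(list(sc_id = sc_id, onset_time = onset_time,
                      phases = phases,
                      plateau_duration = plateau_duration,
                      disassembly_phases = disassembly_phases,
                      event_type = event_type),
                 class = "kinetic_model")
  if (any(model_knots(m)$length < -1e-9)) {
    stop("kinetic program implies negative length")
  }
  m
}

# knot times (min, from onset) and lengths (um) of the piecewise program
model_knots <- function(model) {
  t <- 0; l <- 0
  tt <- t; ll <- l
  for (p in model$phases) {
    t <- t + p[2]; l <- l + p[1] * p[2] / 1000
    tt <- c(tt, t); ll <- c(ll, l)
  }
  if (model$plateau_duration > 0) {
    t <- t + model$plateau_duration
    tt <- c(tt, t); ll <- c(ll, l)
  }
  for (p in model$disassembly_phases) {
    t <- t + p[2]; l <- l + p[1] * p[2] / 1000
    tt <- c(tt, t); ll <- c(ll, l)
  }
  list(time = tt, length = ll)
}

#' True SC length of a kinetic program
#'
#' @param model a [kinetic_model()].
#' @param times minutes (absolute; the program starts at the model's
#'   `onset_time`).
#' @return lengths in um (0 before onset, final knot value after the
#'   program ends).
#' @export
true_length <- function(model, times) {
  stopifnot(inherits(model, "kinetic_model"))
  k <- model_knots(model)
  rel <- times - model$onset_time
  y <- stats::approx(k$time, k$length, xout = pmax(pmin(rel, max(k$time)), 0),
                     rule = 2)$y
  y[rel < 0] <- 0
  pmax(y, 0)
}

#' Total duration (minutes) of a kinetic program after onset
#' @param model a [kinetic_model()].
#' @return minutes from onset to the end of the last phase.
#' @export
model_duration <- function(model) max(model_knots(model)$time)

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("kinetic_model '%s' (%s): %d assembly phase(s)",
              x$sc_id, x$event_type, length(x$phases)))
  if (x$plateau_duration > 0) cat(sprintf(", plateau %g min",
                                          x$plateau_duration))
  if (length(x$disassembly_phases)) {
    cat(sprintf(", %d disassembly phase(s)", length(x$disassembly_phases)))
  }
  cat(sprintf("; final length %.3g um\n",
              max(model_knots(x)$length)))
  invisible(x)
}

#' Simulate an observed length-versus-time trajectory
#'
#' Samples the ground-truth piecewise-linear length program at a regular
#' interval and adds independent zero-mean Gaussian measurement noise,
#' truncated at zero (lengths cannot be negative).  The generating model is
#' attached so recovery tests can join observations to truth.
#'
#' @param model a [kinetic_model()].
#' @param sampling_interval minutes between observations (> 0).
#' @param noise_sd measurement noise SD in um (>= 0).
#' @param seed integer seed; identical seeds give identical trajectories.
#' @param duration minutes of observation from onset; defaults to the
#'   program duration.
#' @param window optional `c(from, to)` in minutes from onset, overriding
#'   `duration` (e.g. to observe only the disassembly portion).
#' @param max_points optional cap on the number of samples (observation
#'   window truncation for very slow phases).
#' @return data frame of class `"sc_trajectory"` with columns `time_min`,
#'   `length_um` and attributes `sc_id`, `truth` (the model),
#'   `true_length_um`, `event_type`.
#' @export
simulate_trajectory <- function(model, sampling_interval, noise_sd = 0,
                                seed = NULL, duration = NULL,
                                window = NULL, max_points = Inf) {
  stopifnot(inherits(model, "kinetic_model"))
  if (sampling_interval <= 0) stop("sampling_interval must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(duration)) duration <- model_duration(model)
  if (is.null(window)) window <- c(0, duration)
  times <- seq(window[1], window[2], by = sampling_interval)
  if (length(times) > max_points) times <- times[seq_len(max_points)]
  truth <- true_length(model, model$onset_time + times)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      obs <- with_seed(seed, truth + stats::rnorm(length(truth), 0, noise_sd))
    } else {
      obs <- truth + stats::rnorm(length(truth), 0, noise_sd)
    }
    obs <- pmax(obs, 0)
  } else {
    obs <- truth
  }
  structure(data.frame(time_min = model$onset_time + times,
                       length_um = obs),
            sc_id = model$sc_id,
            truth = model,
            true_length_um = truth,
            event_type = model$event_type,
            class = c("sc_trajectory", "data.frame"))
}

# run expr with a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic per-stage child seeds derived from one pipeline seed
child_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 1e6 * 7919 + 104729 * stage) %% 2147483647)
}
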