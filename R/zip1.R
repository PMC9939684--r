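#' Nuclear Zip1 expression model
#'
#' Piecewise-linear program for total nuclear Zip1-GFP fluorescence over
#' meiotic prophase: a linear rise from zero, a plateau, and a linear
#' decline to a depletion floor.  The onset threshold is the fluorescence
#' level at which the first SC may appear.
#'
#' Defaults come from [zip1_preset()]; units are arbitrary intensity units
#' (IU) on the scale where the wild-type plateau is 740.
#'
#' @param rise_rate IU per hour during the rise.
#' @param onset_threshold IU at which synapsis is first permitted
#'   (must be <= `plateau_level`).
#' @param plateau_level IU.
#' @param plateau_duration hours.
#' @param decline_duration hours over which Zip1 is degraded.
#' @param depletion_floor IU after degradation (default 0).
#' @return object of class `"zip1_model"`.
#' @export
zip1_model <- function(rise_rate, onset_threshold, plateau_level,
                       plateau_duration, decline_duration,
                       depletion_floor = 0) {
  if (onset_threshold > plateau_level) {
    stop("onset_threshold must be <= plateau_level")
  }
  if (plateau_duration < 0 || decline_duration < 0) {
    stop("durations must be >= 0")
  }
  if (rise_rate < 0 || depletion_floor < 0 || plateau_level < 0) {
    stop("intensities and rates must be >= 0")
  }
  structure(list(rise_rate = rise_rate,
                 onset_threshold = onset_threshold,
                 plateau_level = plateau_level,
                 plateau_duration = plateau_duration,
                 decline_duration = decline_duration,
                 depletion_floor = depletion_floor),
            class = "zip1_model")
}

#' Genotype presets for the Zip1 expression model
#'
#' Wild type (`"WT"`): plateau 740 IU for 1.5 h, degradation within 1 h,
#' synapsis onset at 380 IU.  `"zip3d"` (zip3 deletion): plateau 424 IU
#' (57% of wild type) lasting 6.3 h, degradation over 3 h, onset at 310 IU.
#' Rise rates (42 and 15 IU/h) are set so the full onset-to-depletion
#' period lasts about 11 h (WT) and 17 h (zip3d).
#'
#' @param genotype `"WT"` or `"zip3d"`.
#' @param ... overrides passed to [zip1_model()].
#' @return a `"zip1_model"`.
#' @export
zip1_preset <- function(genotype = c("WT", "zip3d"), ...) {
  genotype <- match.arg(genotype)
  defaults <- switch(genotype,
    WT = list(rise_rate = 42, onset_threshold = 380, plateau_level = 740,
              plateau_duration = 1.5, decline_duration = 1),
    zip3d = list(rise_rate = 15, onset_threshold = 310, plateau_level = 424,
                 plateau_duration = 6.3, decline_duration = 3))
  args <- utils::modifyList(defaults, list(...))
  do.call(zip1_model, args)
}

# knot times (h) and FI values of the expression program
zip1_knots <- function(model) {
  rise_t <- if (model$rise_rate > 0) {
    model$plateau_level / model$rise_rate
  } else Inf
  if (!is.finite(rise_t)) {
    return(list(time = c(0, 1e6), fi = c(0, 0)))
  }
  t_plat_end <- rise_t + model$plateau_duration
  t_dep <- t_plat_end + model$decline_duration
  list(time = c(0, rise_t, t_plat_end, t_dep),
       fi = c(0, model$plateau_level, model$plateau_level,
              model$depletion_floor))
}

#' True Zip1 fluorescence of an expression program
#' @param model a [zip1_model()].
#' @param times_h hours since expression onset.
#' @return FI in IU.
#' @export
zip1_fi <- function(model, times_h) {
  k <- zip1_knots(model)
  stats::approx(k$time, k$fi, xout = times_h, rule = 2)$y
}

#' Simulate a per-nucleus Zip1 fluorescence profile
#'
#' Samples the expression program at a regular interval with optional
#' Gaussian measurement noise.  The first-SC flag marks the first sample at
#' which FI crosses the onset threshold.
#'
#' @param model a [zip1_model()]; alternatively give `genotype` to use a
#'   preset.
#' @param genotype `"WT"` or `"zip3d"` (ignored when `model` is supplied).
#' @param sampling_interval hours between samples (default 1, matching
#'   hourly acquisition).
#' @param noise_sd IU (default 0).
#' @param seed integer seed.
#' @param duration hours; default covers the program plus a 2-h tail.
#' @return data frame of class `"zip1_profile"` with columns `time_h`,
#'   `fi`, and attributes `model`, `first_sc_time` (NA when the threshold
#'   is never reached).
#' @export
simulate_zip1_profile <- function(model = NULL,
                                  genotype = c("WT", "zip3d"),
                                  sampling_interval = 1, noise_sd = 0,
                                  seed = NULL, duration = NULL) {
  if (is.null(model)) model <- zip1_preset(match.arg(genotype))
  stopifnot(inherits(model, "zip1_model"))
  if (sampling_interval <= 0) stop("sampling_interval must be > 0")
  k <- zip1_knots(model)
  if (is.null(duration)) duration <- min(max(k$time), 1e5) + 2
  times <- seq(0, duration, by = sampling_interval)
  fi <- zip1_fi(model, times)
  if (noise_sd > 0) {
    noise <- if (!is.null(seed)) {
      with_seed(seed, stats::rnorm(length(fi), 0, noise_sd))
    } else stats::rnorm(length(fi), 0, noise_sd)
    fi <- pmax(fi + noise, 0)
  }
  onset_ok <- model$rise_rate > 0 & fi >= model$onset_threshold &
    model$onset_threshold > 0
  first_sc <- if (any(onset_ok)) times[which(onset_ok)[1]] else NA_real_
  structure(data.frame(time_h = times, fi = fi),
            model = model,
            first_sc_time = first_sc,
            class = c("zip1_profile", "data.frame"))
}
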