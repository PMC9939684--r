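# End-to-end orchestration of the synthetic experiments.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end synthetic analysis
#' in one serialisable object.  A single global seed is expanded into
#' per-stage child seeds by a fixed affine scheme
#' (`(seed * 7919 + 104729 * stage) mod (2^31 - 1)`), so stages can be
#' rerun in isolation and the whole run is reproducible.
#'
#' @param seed global integer seed.
#' @param n_assembly,mono_fraction assembly cohort size and monophasic
#'   share (defaults 34 and 0.65).
#' @param n_disassembly,n_abortive disassembly cohort sizes (50, 15).
#' @param n_seeds number of replicate cohorts averaged (default 20).
#' @param noise_sd trajectory measurement noise (um).
#' @param k_sigma,depletion_frac,abortive_threshold,size_breaks analysis
#'   thresholds.
#' @param render include a rendered-scene tracing stage (slower; default
#'   FALSE fits simulated trajectories directly).
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return list of class `"run_config"`.
#' @export
pipeline_config <- function(seed = 1, n_assembly = 34, mono_fraction = 0.65,
                            n_disassembly = 50, n_abortive = 15,
                            n_seeds = 20, noise_sd = 0.05,
                            k_sigma = 3, depletion_frac = 0.10,
                            abortive_threshold = 0.75,
                            size_breaks = c(0.5, 1.5),
                            render = FALSE, out_dir = NULL) {
  structure(list(seed = seed, n_assembly = n_assembly,
                 mono_fraction = mono_fraction,
                 n_disassembly = n_disassembly, n_abortive = n_abortive,
                 n_seeds = n_seeds, noise_sd = noise_sd,
                 k_sigma = k_sigma, depletion_frac = depletion_frac,
                 abortive_threshold = abortive_threshold,
                 size_breaks = size_breaks, render = render,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full synthetic SC kinetics analysis
#'
#' Simulates assembly, final-disassembly and abortive-disassembly cohorts
#' at the printed population parameters, fits and selects segmented
#' models, classifies events, and computes the closed-form statistics.
#' Returns all tables plus a summary of the headline quantities; with
#' `config$out_dir` set, tables are written as CSV and the summary as
#' JSON.
#'
#' @param config a [pipeline_config()].
#' @return list of class `"sc_report"`: `summary` (named numerics),
#'   `tables` (data frames: assembly fits, disassembly fits, abortive
#'   events), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- vapply(seq_len(config$n_seeds),
                  function(k) child_seed(config$seed, k), integer(1))

  # --- assembly cohorts: initial rates, phasic mix, phase-1 fraction ----
  asm <- lapply(seeds, function(s) {
    co <- simulate_assembly_cohort(n = config$n_assembly,
                                   mono_fraction = config$mono_fraction,
                                   noise_sd = config$noise_sd, seed = s)
    cbind(fit_cohort(co, "assembly"), replicate_seed = s,
          true_phasic = co$truth$phasic, true_rate1 = co$truth$rate1,
          true_rate2 = co$truth$rate2)
  })
  asm <- do.call(rbind, asm)
  bi <- asm[asm$phasic == "biphasic", ]

  # --- final disassembly -----------------------------------------------
  dis_seeds <- seeds[seq_len(min(10, length(seeds)))]
  dis <- do.call(rbind, lapply(dis_seeds, function(s) {
    co <- simulate_disassembly_cohort(n = config$n_disassembly,
                                      noise_sd = config$noise_sd,
                                      seed = child_seed(s, 101))
    cbind(fit_cohort(co, "disassembly"), replicate_seed = s,
          true_rate1 = co$truth$rate1)
  }))

  # --- abortive disassembly (classified, then fitted) -------------------
  abo_co <- simulate_abortive_cohort(n = config$n_abortive,
                                     noise_sd = config$noise_sd,
                                     seed = child_seed(config$seed, 202))
  abo_events <- classify_events(abo_co$trajectories,
                                abortive_threshold =
                                  config$abortive_threshold,
                                size_breaks = config$size_breaks)

  summary <- c(
    multi_initiation_pct = 100 * multi_initiation_frequency(5 / 16),
    miss_probability_pct = 100 * miss_probability(0.04, 230),
    bidirectional_rate_ratio_pct =
      100 * bidirectional_prediction(0.3)$rate_ratio,
    zip1_plateau_ratio_pct = 100 * zip1_preset("zip3d")$plateau_level /
      zip1_preset("WT")$plateau_level,
    mean_initial_rate_nm_min = mean(asm$initial_rate),
    monophasic_pct = 100 * mean(asm$phasic == "monophasic"),
    mean_second_rate_nm_min = mean(bi$second_rate, na.rm = TRUE),
    phase1_length_fraction_pct =
      100 * mean(bi$phase1_length_fraction, na.rm = TRUE),
    final_disassembly_rate_nm_min = mean(dis$rate),
    abortive_rate_magnitude_nm_min =
      mean(abs(abo_events$rate_nm_min), na.rm = TRUE),
    abortive_correctly_flagged_pct =
      100 * mean(abo_events$event_type == "abortive_disassembly")
  )

  report <- structure(list(summary = summary,
                           tables = list(assembly = asm,
                                         disassembly = dis,
                                         abortive = abo_events),
                           config = config),
                      class = "sc_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(report$tables)) {
      utils::write.csv(report$tables[[nm]],
                       file.path(config$out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(as.list(report$summary),
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.sc_report <- function(x, ...) {
  cat("SC kinetics synthetic-analysis report\n")
  s <- x$summary
  for (nm in names(s)) cat(sprintf("  %-34s %10.4g\n", nm, s[[nm]]))
  invisible(x)
}

#' Write a trajectory list as a tidy CSV
#' @param trajectories list of `"sc_trajectory"` data frames.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trajectories_csv <- function(trajectories, file) {
  rows <- do.call(rbind, lapply(trajectories, function(tr) {
    cbind(sc_id = attr(tr, "sc_id") %||% NA_character_,
          as.data.frame(tr))
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Read a trajectory CSV written by [write_trajectories_csv()]
#' @param file CSV with columns sc_id, time_min, length_um (and optional
#'   zip1_fi).
#' @return list of `"sc_trajectory"` data frames.
#' @export
read_trajectories_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("sc_id", "time_min", "length_um") %in% names(df)))
  lapply(split(df, df$sc_id), function(g) {
    structure(g[setdiff(names(g), "sc_id")],
              sc_id = g$sc_id[1],
              class = c("sc_trajectory", "data.frame"))
  })
}
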