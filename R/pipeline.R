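#' Configuration for a full pipeline run
#'
#' Collects every tunable of the simulate/read -> smooth -> change-point
#' downsample -> interpolate -> NS-selection -> metrics chain. A run is
#' reproducible from its configuration alone: all randomness flows from
#' `seed` (via the synthetic generator), and rerunning an identical
#' configuration produces byte-identical outputs.
#'
#' @param input Path to a recording file, or `NULL` to simulate.
#' @param synthetic A [synthetic_lfp_config()] (required when `input` is
#'   `NULL`).
#' @param subject_id,group Labels written to the phase table.
#' @param smooth Apply moving-average denoising (default TRUE).
#' @param smooth_window Odd window length in samples (default 5).
#' @param detect_cps Downsample via change-point detection (default TRUE);
#'   when FALSE the phase is uniformly downsampled to the grid instead.
#' @param cp_penalty Penalty per interior knot (squared signal units).
#' @param cp_max Maximum interior knots per channel and phase.
#' @param grid_points Uniform grid size per phase after interpolation.
#' @param phase_duration_s Phase length in seconds.
#' @param k_min,k_max,rel_err_accept,r_max,rank_tol,distant_budget
#'   NS-selection controls, see [select_ns()].
#' @param spectrogram Compute a sliding-window power spectrum (default
#'   TRUE; skipped with a warning when the recording is shorter than one
#'   window).
#' @param spec_window_s,spec_hop_s Spectrogram window and hop in seconds.
#' @param out_dir Output directory.
#' @param seed Integer seed (overrides the synthetic config's seed so one
#'   value governs the whole run).
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, synthetic = NULL,
                       subject_id = "S1", group = "synthetic",
                       smooth = TRUE, smooth_window = 5,
                       detect_cps = TRUE, cp_penalty = 1, cp_max = 500,
                       grid_points = 3000, phase_duration_s = 300,
                       k_min = 1, k_max = 13, rel_err_accept = 0.25,
                       r_max = 20, rank_tol = 1e-10, distant_budget = 50,
                       spectrogram = TRUE, spec_window_s = 30,
                       spec_hop_s = 15, out_dir = tempfile("eralfp-run-"),
                       seed = 1) {
  if (is.null(input) && is.null(synthetic)) {
    abort("supply either `input` (a recording path) or `synthetic` (a config)")
  }
  smooth_window <- check_count(smooth_window, "smooth_window")
  if (smooth && smooth_window %% 2 == 0) {
    abort("`smooth_window` must be odd")
  }
  check_positive_scalar(cp_penalty, "cp_penalty")
  grid_points <- check_count(grid_points, "grid_points", min = 4)
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_lfp_config")) {
    synthetic <- do.call(synthetic_lfp_config, synthetic)
  }
  structure(
    list(input = input, synthetic = synthetic, subject_id = subject_id,
         group = group, smooth = smooth, smooth_window = smooth_window,
         detect_cps = detect_cps, cp_penalty = cp_penalty, cp_max = cp_max,
         grid_points = grid_points, phase_duration_s = phase_duration_s,
         k_min = k_min, k_max = k_max, rel_err_accept = rel_err_accept,
         r_max = r_max, rank_tol = rank_tol, distant_budget = distant_budget,
         spectrogram = spectrogram, spec_window_s = spec_window_s,
         spec_hop_s = spec_hop_s, out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return [write_run_config()] returns `path` invisibly;
#'   [read_run_config()] returns a validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  if (!is.null(x$synthetic)) x$synthetic <- unclass(x$synthetic)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate or read the recording; moving-average
#' smoothing; partitioning into phases; per phase, change-point
#' downsampling and interpolation to the shared coarse grid, then
#' AIC-driven Number-of-Stacks selection, realization and reconstruction
#' metrics; and a sliding-window power spectrum of the raw recording. All
#' stage outputs are written under `config$out_dir` and inventoried with
#' MD5 checksums in the returned manifest. Any stage failure aborts with
#' the stage name after persisting the partial manifest.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A `run_manifest`: list with `files` (tibble: stage, file, md5),
#'   `phase_table`, `warnings` and `timings`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- tibble(stage = character(), file = character(), md5 = character())
  warnings_log <- character()
  timings <- c()
  say <- function(...) if (!quiet) message(sprintf(...))
  add_file <- function(stage, path) {
    files <<- bind_rows(files, tibble(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path))))
  }
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      partial <- list(files = files, warnings = warnings_log,
                      failed_stage = stage, error = conditionMessage(e))
      write_report(partial, file.path(config$out_dir, "manifest.partial.json"))
      abort(sprintf("pipeline stage `%s` failed: %s", stage,
                    conditionMessage(e)))
    })
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  say("stage: input")
  recording <- run_stage("input", {
    if (!is.null(config$input)) {
      read_recording(config$input)
    } else {
      syn <- config$synthetic
      syn$seed <- config$seed
      generate_synthetic_lfp(do.call(synthetic_lfp_config, unclass(syn)))
    }
  })
  rate <- attr(recording, "rate")
  if (is.null(rate)) rate <- infer_rate(recording)
  rec_path <- file.path(config$out_dir, "recording.csv")
  write_recording(recording, rec_path, rate = rate)
  add_file("input", rec_path)

  say("stage: smooth")
  smoothed <- run_stage("smooth", {
    if (config$smooth) smooth_moving_average(recording, config$smooth_window)
    else recording
  })

  say("stage: partition")
  phased <- run_stage("partition", {
    partition_phases(smoothed, rate = rate,
                     phase_duration_s = config$phase_duration_s)
  })
  phases <- sort(unique(phased$phase))

  cp_all <- list()
  phase_rows <- list()
  reports <- list()
  for (ph in phases) {
    say("stage: phase %d", ph)
    stage_name <- sprintf("phase_%d", ph)
    res <- run_stage(stage_name, {
      d <- phased[phased$phase == ph, c("time", "channel", "value")]
      if (config$detect_cps) {
        cps <- detect_change_points(d, penalty = config$cp_penalty,
                                    max_cps = config$cp_max)
      } else {
        # uniform decimation expressed as knots so interpolation is shared
        cps <- d %>%
          group_by(.data$channel) %>%
          arrange(.data$time, .by_group = TRUE) %>%
          dplyr::slice(unique(round(seq(1, dplyr::n(),
                                        length.out = min(config$grid_points, dplyr::n()))))) %>%
          ungroup() %>%
          select("channel", "time", "value")
      }
      uni <- interpolate_to_uniform(cps, target_points = config$grid_points)
      sel <- select_ns(uni, k_min = config$k_min, k_max = config$k_max,
                       rel_err_accept = config$rel_err_accept,
                       rank_tol = config$rank_tol, r_max = config$r_max,
                       distant_budget = config$distant_budget)
      rep <- reconstruction_report(sel, uni)
      list(cps = cps, selection = sel, report = rep)
    })
    if (res$selection$strategy == "distant") {
      warnings_log <- c(warnings_log, sprintf(
        "phase %d: distant-values strategy (RelErr %.3g)", ph,
        res$selection$rel_err))
    }
    res$cps$phase <- ph
    cp_all[[length(cp_all) + 1L]] <- res$cps
    phase_rows[[length(phase_rows) + 1L]] <- dplyr::mutate(
      res$report$summary, subject = config$subject_id, group = config$group,
      phase = ph, .before = 1)
    reports[[sprintf("phase_%d", ph)]] <- list(
      summary = res$report$summary, per_channel = res$report$per_channel,
      aic_curve = res$selection$aic_curve,
      ns_star = res$selection$ns_star)
  }

  cp_path <- file.path(config$out_dir, "change_points.csv")
  write_change_points(bind_rows(cp_all), cp_path)
  add_file("change_points", cp_path)

  phase_table <- bind_rows(phase_rows)
  pt_path <- file.path(config$out_dir, "phase_table.tsv")
  utils::write.table(as.data.frame(phase_table), pt_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  add_file("phase_table", pt_path)

  rep_path <- file.path(config$out_dir, "reports.json")
  write_report(reports, rep_path)
  add_file("reports", rep_path)

  if (config$spectrogram) {
    say("stage: spectrogram")
    dur <- length(unique(recording$time)) / rate
    if (dur >= config$spec_window_s) {
      spec <- run_stage("spectrogram", {
        windowed_power_spectrum(recording, rate = rate,
                                window_s = config$spec_window_s,
                                hop_s = config$spec_hop_s)
      })
      spec_path <- file.path(config$out_dir, "spectrogram.csv")
      utils::write.csv(as.data.frame(as_tibble(spec)), spec_path,
                       row.names = FALSE)
      add_file("spectrogram", spec_path)
    } else {
      warnings_log <- c(warnings_log,
                        "recording shorter than one spectrogram window; skipped")
    }
  }

  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  add_file("config", cfg_path)

  manifest <- structure(
    list(files = files, phase_table = phase_table,
         warnings = warnings_log, timings = timings),
    class = "run_manifest")
  write_report(list(files = files, warnings = warnings_log),
               file.path(config$out_dir, "manifest.json"))
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d files, %d warning(s)\n",
              nrow(x$files), length(x$warnings)))
  print(x$files)
  invisible(x)
}
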