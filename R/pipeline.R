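#' Pipeline configuration
#'
#' All numeric parameters of the end-to-end pipeline with defaults matching
#' the analysis settings (1-40 Hz band-pass, 2-s epochs, +/-100 uV rejection,
#' K = 7 classes, 100 restarts, 250 Hz, theta 4-7.5 Hz, block length 6).
#' Unknown keys are rejected; the resolved configuration round-trips through
#' JSON unchanged and is written next to every run's outputs.
#'
#' @param ... Overrides of the default entries.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_participants = 1L,
    n_classes = 7L,
    snr_db = 20,
    mean_dwell_baseline = 22,
    mean_dwell_trial = 18,
    sampling_rate = 250,
    stages = c(Training = 7, PracticeA = 8, PracticeB = 7),
    baseline_duration = 30,
    trial_duration = 90,
    filter_low = 1,
    filter_high = 40,
    epoch_seconds = 2,
    amp_uV = 100,
    target_fs = 250,
    n_init = 100L,
    theta_band = c(4, 7.5),
    k_max = 6L,
    seed = 1L,
    do_preprocess = TRUE,
    do_fit = TRUE,
    do_backfit = TRUE,
    do_dynamics = TRUE,
    do_spectral = TRUE,
    do_stats = TRUE
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Write and read a pipeline configuration as JSON
#'
#' The resolved configuration round-trips unchanged; unknown keys in the file
#' are rejected on read.
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$stages <- as.list(x$stages)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$stages <- unlist(x$stages)
  do.call(pipeline_config, x)
}

#' Run the full synthetic-study pipeline
#'
#' Chains simulation, preprocessing, per-task microstate fitting, two-level
#' full-permutation aggregation (tasks within participant, then across
#' participants), canonical A-G labelling, backfitting with microstate
#' parameters, temporal-dependency measures, theta-band area powers and - when
#' at least two participants are simulated - the repeated-measures statistics.
#' Fully reproducible: the run is a pure function of the configuration (which
#' includes the master seed).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, tidy CSV tables, the
#'   resolved configuration and a manifest with content hashes are written.
#' @return A list with the result tables (`parameters`, `dynamics`,
#'   `spectral`, `anova`), `global_maps`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character()
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))
  spec <- protocol_spec(config$stages, config$baseline_duration,
                        config$trial_duration, config$sampling_rate)
  maps_true <- generate_template_maps(config$n_classes, seed = config$seed)
  participants <- lapply(seq_len(config$n_participants), function(p)
    simulate_protocol(spec, maps_true,
                      sequence_model(config$n_classes,
                                     mean_dwell = config$mean_dwell_baseline),
                      sequence_model(config$n_classes,
                                     mean_dwell = config$mean_dwell_trial),
                      snr_db = config$snr_db,
                      seed = config$seed + 1000L * p))
  if (config$do_preprocess) {
    participants <- lapply(participants, function(tasks) lapply(tasks, function(tk) {
      rec <- bandpass_filter(tk$recording, config$filter_low,
                             config$filter_high)
      bc <- detect_bad_channels(rec)
      if (nrow(bc$bad_channels)) {
        rec <- interpolate_spherical(rec, unique(bc$bad_channels$channel))
        note("participant task ", tk$stage, "/", tk$session, "/",
             tk$task_type, ": interpolated bad channel(s) ",
             paste(unique(bc$bad_channels$channel), collapse = ","))
      }
      cl <- epoch_and_clean(rec, config$epoch_seconds, config$amp_uV)
      if (nrow(cl$report$rejected_epochs))
        note("participant task ", tk$stage, "/", tk$session, "/",
             tk$task_type, ": ", nrow(cl$report$rejected_epochs),
             " epoch(s) rejected")
      tk$recording <- finalize_recording(cl$recording, config$target_fs)
      tk
    }))
  }
  out <- list(config = config)
  if (config$do_fit) {
    subject_maps <- lapply(seq_along(participants), function(p) {
      fits <- lapply(participants[[p]], function(tk) {
        g <- compute_gfp(tk$recording)
        pk <- find_gfp_peaks(g)
        modified_kmeans(t(tk$recording$data[, pk, drop = FALSE]),
                        config$n_classes, n_init = config$n_init,
                        seed = config$seed + 17L * p)
      })
      align_full_permutation(fits)$global_maps
    })
    global_maps <- if (length(subject_maps) >= 2)
      align_full_permutation(subject_maps)$global_maps
    else subject_maps[[1]]
    labelled <- label_canonical(global_maps, canonical_templates())
    out$global_maps <- labelled
  }
  meta_df <- function(tk) data.frame(stage = tk$stage, session = tk$session,
                                     task_type = tk$task_type)
  if (config$do_fit && config$do_backfit) {
    out$parameters <- do.call(rbind, unlist(lapply(seq_along(participants),
      function(p) lapply(participants[[p]], function(tk) {
        sq <- backfit(tk$recording, out$global_maps,
                      meta = list(stage = tk$stage, session = tk$session,
                                  task_type = tk$task_type))
        cbind(participant = p, microstate_parameters(sq))
      })), recursive = FALSE))
  }
  if (config$do_fit && config$do_backfit && config$do_dynamics) {
    out$dynamics <- do.call(rbind, unlist(lapply(seq_along(participants),
      function(p) lapply(participants[[p]], function(tk) {
        sq <- backfit(tk$recording, out$global_maps)
        dy <- suppressWarnings(sequence_dynamics(sq, k_max = config$k_max))
        cbind(participant = p, meta_df(tk),
              data.frame(entropy_rate = dy$entropy_rate,
                         hurst_mean = dy$hurst_mean))
      })), recursive = FALSE))
  }
  if (config$do_spectral) {
    out$spectral <- do.call(rbind, unlist(lapply(seq_along(participants),
      function(p) lapply(participants[[p]], function(tk) {
        th <- theta_power(welch_psd(tk$recording), config$theta_band)
        cbind(participant = p, meta_df(tk), group_by_area(th))
      })), recursive = FALSE))
  }
  if (config$do_stats && config$n_participants >= 2) {
    out$anova <- list()
    if (!is.null(out$spectral)) {
      agg <- stats::aggregate(power ~ participant + task_type + stage + area,
                              out$spectral, mean)
      out$anova$theta <- rm_anova(agg, dv = "power",
                                  subject = "participant",
                                  within = c("task_type", "stage", "area"))
    }
    if (!is.null(out$parameters)) {
      for (par in c("coverage", "occurrence", "duration")) {
        agg <- stats::aggregate(
          stats::reformulate(c("participant", "task_type", "stage", "class"),
                             par), out$parameters, mean)
        out$anova[[par]] <- rm_anova(agg, dv = par, subject = "participant",
                                     within = c("task_type", "stage",
                                                "class"))
      }
    }
    if (!is.null(out$dynamics)) {
      for (par in c("entropy_rate", "hurst_mean")) {
        agg <- stats::aggregate(
          stats::reformulate(c("participant", "task_type", "stage"), par),
          out$dynamics, mean)
        out$anova[[par]] <- rm_anova(agg, dv = par, subject = "participant",
                                     within = c("task_type", "stage"))
      }
    }
  } else if (config$do_stats && config$n_participants < 2) {
    note("statistics skipped: fewer than 2 participants")
  }
  out$manifest <- build_manifest(out, config, warnings_log, out_dir)
  out
}

build_manifest <- function(out, config, warnings_log, out_dir) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("mspilot")),
    seed = config$seed,
    record_counts = lapply(out[c("parameters", "dynamics", "spectral")],
                           function(x) if (is.null(x)) 0L else nrow(x)),
    warnings = warnings_log,
    files = list()
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfgj <- file.path(out_dir, "config.json")
    write_pipeline_config(config, cfgj)
    files <- cfgj
    for (nm in c("parameters", "dynamics", "spectral")) {
      if (!is.null(out[[nm]])) {
        f <- file.path(out_dir, paste0(nm, ".csv"))
        utils::write.csv(out[[nm]], f, row.names = FALSE)
        files <- c(files, f)
      }
    }
    if (!is.null(out$global_maps)) {
      f <- file.path(out_dir, "global_maps.csv")
      utils::write.csv(as.data.frame(out$global_maps$maps), f)
      files <- c(files, f)
    }
    manifest$files <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest
}
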