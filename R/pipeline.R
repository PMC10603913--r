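#' Full-run configuration
#'
#' Bundles every stage's configuration plus the master seed and cohort
#' sizes. Defaults mirror the study defaults: 60 patients and 10 controls
#' (trimmed for routine runs via the arguments), 1-min vitals and 5-min
#' pressure frames.
#'
#' @param n_patients,n_controls Cohort sizes to simulate.
#' @param generator A [generator_config()].
#' @param bounds A [range_bounds()].
#' @param quality A [quality_config()].
#' @param smoothing A [smoothing_config()].
#' @param peaks A [peak_config()].
#' @param k_candidates Candidate cluster counts for the elbow method.
#' @param predictor A [predictor_config()].
#' @param stratify Condition flag for the stratified comparison, or `NULL`.
#' @param foot Also run the insole stage (default `FALSE`).
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_patients = 2, n_controls = 1,
                       generator = generator_config(duration = 1440),
                       bounds = range_bounds(), quality = quality_config(),
                       smoothing = smoothing_config(), peaks = peak_config(),
                       k_candidates = 2:6,
                       predictor = predictor_config(),
                       stratify = "prior_pu_surgery", foot = FALSE,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from a JSON key-value file
#'
#' Flat keys override [run_config()] defaults; nested objects (`generator`,
#' `predictor`, ...) override fields of the corresponding config
#' constructor. Unknown keys are rejected.
#'
#' @param path JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- run_config()
  ctors <- list(generator = generator_config, bounds = range_bounds,
                quality = quality_config, smoothing = smoothing_config,
                peaks = peak_config, predictor = predictor_config)
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in names(raw)) {
    if (key %in% names(ctors)) {
      ctor <- ctors[[key]]
      bad <- setdiff(names(raw[[key]]), names(formals(ctor)))
      if (length(bad)) {
        stop("unknown ", key, " key(s): ", paste(bad, collapse = ", "))
      }
      base[[key]] <- do.call(ctor, raw[[key]])
    } else {
      base[[key]] <- raw[[key]]
    }
  }
  class(base) <- "run_config"
  base
}

run_stage <- function(name, expr, log_level = "info") {
  t0 <- Sys.time()
  out <- tryCatch(force(expr), error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  if (log_level != "quiet") {
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
  }
  out
}

#' Run the full analysis pipeline
#'
#' simulate -> preprocess -> events -> predict -> cohort (-> foot), writing
#' every artifact as CSV under `out_dir` and a `run_manifest.json` stamping
#' the seed, configuration, and md5 of every artifact. Deterministic from
#' `(config, seed)`; a stage failure halts with an error naming the stage.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param log_level `"info"` or `"quiet"`.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("puwarn_"),
                         log_level = "info") {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    paths[[name]] <<- p
    p
  }

  dataset <- run_stage("simulate", {
    ds <- generate_cohort(config$n_patients, config$n_controls,
                          config$generator, seed = config$seed)
    emit("subjects.csv", function(p) write_subjects(ds, p))
    for (id in names(ds$subjects)) {
      s <- ds$subjects[[id]]
      emit(sprintf("vitals_%s.csv", id),
           function(p) write_vitals(s$vitals, p))
      emit(sprintf("pressure_%s.csv", id),
           function(p) write_pressure(s$pressure, p))
    }
    ds
  }, log_level)

  prepped <- run_stage("preprocess", {
    pp <- lapply(dataset$subjects, function(s)
      preprocess_vitals(s$vitals, config$bounds, config$quality))
    sections <- do.call(rbind, lapply(pp, `[[`, "sections"))
    emit("sections.csv", function(p)
      utils::write.csv(sections, p, row.names = FALSE, quote = FALSE))
    pp
  }, log_level)

  run_stage("events", {
    all_windows <- list()
    all_events <- list()
    for (id in names(dataset$subjects)) {
      s <- dataset$subjects[[id]]
      up <- upsample_sum_load(s$pressure)
      if (nrow(up) < 30 || pop_sd(up$sum_load) == 0) next
      proc <- zscore(smooth_series(up$sum_load, config$smoothing))
      ev <- detect_events(proc, up$t, config$peaks, "both")
      ev$subject_id <- id
      all_events[[id]] <- ev
      wins <- extract_windows(ev[ev$direction == "rising", , drop = FALSE],
                              data.frame(t = up$t, value = proc),
                              prepped[[id]]$series)
      all_windows <- c(all_windows, wins)
    }
    events <- do.call(rbind, all_events)
    emit("events.csv", function(p)
      utils::write.csv(events, p, row.names = FALSE, quote = FALSE))
    if (length(all_windows) >= max(config$k_candidates)) {
      cl <- cluster_windows(all_windows, config$k_candidates,
                            seed = config$seed)
      stas <- sta_by_cluster(all_windows, cl)
      for (k in names(stas)) {
        st <- stas[[k]]
        emit(sprintf("sta_cluster%s.csv", k), function(p)
          utils::write.csv(data.frame(rel_time = st$rel_time,
                                      mean_delta_temp = st$sta, n = st$n),
                           p, row.names = FALSE, quote = FALSE))
      }
    }
    NULL
  }, log_level)

  run_stage("predict", {
    alarms <- list()
    for (id in names(dataset$subjects)) {
      trace <- diff_and_state(prepped[[id]]$series, config$predictor)
      emit(sprintf("predictor_%s.csv", id), function(p)
        utils::write.csv(trace, p, row.names = FALSE, quote = FALSE))
      alarms[[id]] <- alarm_events(trace, config$predictor)
    }
    emit("alarms.csv", function(p)
      utils::write.csv(data.frame(
        subject_id = names(alarms),
        n_alarms = vapply(alarms, `[[`, 0L, "n_alarms")),
        p, row.names = FALSE, quote = FALSE))
    NULL
  }, log_level)

  run_stage("cohort", {
    ## means over the already-preprocessed series
    sm <- subject_means(structure(list(subjects = lapply(
      names(dataset$subjects), function(id) {
        s <- dataset$subjects[[id]]
        list(profile = s$profile, vitals = prepped[[id]]$series,
             pressure = s$pressure)
      }), config = dataset$config, seed = dataset$seed),
      class = "cohort_dataset"), preprocess = FALSE)
    emit("cohort_summary.csv", function(p)
      utils::write.csv(sm, p, row.names = FALSE, quote = FALSE))
    comp <- if (config$n_patients >= 2 && config$n_controls >= 2) {
      compare_groups(sm)
    } else NULL
    if (!is.null(config$stratify)) {
      strat <- tryCatch(
        stratify_by_condition(dataset, config$stratify, summaries = sm),
        error = function(e) NULL)
      comp <- rbind(comp, strat)
    }
    if (!is.null(comp)) {
      emit("comparisons.csv", function(p)
        utils::write.csv(comp, p, row.names = FALSE, quote = FALSE))
    }
    NULL
  }, log_level)

  if (isTRUE(config$foot)) {
    run_stage("foot", {
      set.seed(config$seed)
      groups <- rep(c("orthopedic", "regular", "control"), length.out = 6)
      insoles <- lapply(seq_along(groups), function(i) {
        prof <- subject_profile(sprintf("F%02d", i),
                                if (groups[i] == "control") "control" else
                                  "patient",
                                weight = max(45, round(stats::rnorm(1, 80, 12))),
                                conditions = if (groups[i] == "control") NULL
                                else c(diabetes = TRUE),
                                shoe_group = groups[i])
        generate_insole_subject(prof, seed = config$seed + i)
      })
      emit("foot_summary.csv", function(p)
        utils::write.csv(group_summary(insoles), p, row.names = FALSE,
                         quote = FALSE))
      NULL
    }, log_level)
  }

  manifest <- list(seed = config$seed,
                   created = format(Sys.time(), tz = "UTC"),
                   n_patients = config$n_patients,
                   n_controls = config$n_controls,
                   artifacts = as.list(tools::md5sum(unlist(paths))))
  names(manifest$artifacts) <- basename(names(manifest$artifacts))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Command-line entry point
#'
#' `puwarn <command> [options]` with commands `simulate` and `run-all`
#' (stage-by-stage re-runs operate on the artifacts of a previous
#' `run-all`). Options: `--config` (JSON), `--seed`, `--out-dir`,
#' `--n-patients`, `--n-controls`, `--duration`, `--log-level`.
#'
#' @param args Character vector of CLI arguments (default from the command
#'   line).
#' @return Exit status, invisibly.
#' @export
pu_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: puwarn <simulate|run-all> [--config F] [--seed N] ",
            "[--out-dir D] [--n-patients N] [--n-controls N] ",
            "[--duration MIN] [--foot] [--log-level info|quiet]")
    return(invisible(1L))
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out-dir", type = "character", default = "out",
                          dest = "out_dir"),
    optparse::make_option("--n-patients", type = "integer", default = 2L,
                          dest = "n_patients"),
    optparse::make_option("--n-controls", type = "integer", default = 1L,
                          dest = "n_controls"),
    optparse::make_option("--duration", type = "integer", default = 1440L),
    optparse::make_option("--foot", action = "store_true", default = FALSE),
    optparse::make_option("--log-level", type = "character",
                          default = "info", dest = "log_level")))
  opts <- optparse::parse_args(parser, args = args[-1])
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else
    run_config(n_patients = opts$n_patients, n_controls = opts$n_controls,
               generator = generator_config(duration = opts$duration),
               foot = opts$foot, seed = opts$seed)
  cfg$seed <- opts$seed
  if (cmd %in% c("run-all", "simulate", "preprocess", "events", "predict",
                 "cohort", "foot")) {
    if (cmd == "foot") cfg$foot <- TRUE
    run_pipeline(cfg, out_dir = opts$out_dir, log_level = opts$log_level)
    return(invisible(0L))
  }
  message("unknown command: ", cmd)
  invisible(1L)
}
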