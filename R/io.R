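#' Write a session bundle to a directory
#'
#' Canonical on-disk format: `eye_trace.csv` (t_ms, x_deg, y_deg),
#' `trials.csv`, `cs_spikes.csv` (time_ms, duration_ms), `ss_spikes.csv`
#' (time_ms), `metadata.json`. When the session carries a `truth` element it is
#' written alongside as `ground_truth.csv` + `ground_truth_trials.csv`; the
#' analysis functions never read those files.
#'
#' @param session a `cs_session` (see [simulate_session()])
#' @param path directory to create/write into
#' @return `path`, invisibly
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$trace, file.path(path, "eye_trace.csv"),
                   row.names = FALSE)
  utils::write.csv(session$trials, file.path(path, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(session$cs, file.path(path, "cs_spikes.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(time_ms = session$ss),
                   file.path(path, "ss_spikes.csv"), row.names = FALSE)
  jsonlite::write_json(session$metadata, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(session$truth)) {
    utils::write.csv(session$truth$saccades,
                     file.path(path, "ground_truth.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a session bundle
#'
#' @param path session directory written by [write_session()]
#' @return a `cs_session` list (without ground truth)
#' @export
read_session <- function(path) {
  need <- c("eye_trace.csv", "trials.csv", "cs_spikes.csv", "ss_spikes.csv",
            "metadata.json")
  for (f in need) {
    if (!file.exists(file.path(path, f))) stop("missing session file: ", f)
  }
  trace <- utils::read.csv(file.path(path, "eye_trace.csv"))
  if (!all(c("t_ms", "x_deg", "y_deg") %in% names(trace))) {
    stop("eye_trace.csv must have columns t_ms, x_deg, y_deg")
  }
  if (any(diff(trace$t_ms) <= 0)) stop("eye_trace.csv: non-monotone time")
  trials <- utils::read.csv(file.path(path, "trials.csv"))
  req <- c("trial", "trial_onset_ms", "target_jump_ms", "target_pos_deg")
  if (!all(req %in% names(trials))) {
    stop("trials.csv missing columns: ",
         paste(setdiff(req, names(trials)), collapse = ", "))
  }
  cs <- utils::read.csv(file.path(path, "cs_spikes.csv"))
  if (!"time_ms" %in% names(cs)) stop("cs_spikes.csv must have column time_ms")
  if (!"duration_ms" %in% names(cs)) {
    cs$duration_ms <- NA_real_
    attr(cs, "durations_available") <- FALSE
  } else {
    attr(cs, "durations_available") <- TRUE
  }
  ss <- utils::read.csv(file.path(path, "ss_spikes.csv"))$time_ms
  md <- jsonlite::read_json(file.path(path, "metadata.json"),
                            simplifyVector = TRUE)
  if (!is.null(md$cf_direction) && !md$cf_direction %in% c("left", "right")) {
    stop("metadata.json: cf_direction must be 'left' or 'right'")
  }
  structure(list(trace = trace, trials = trials, cs = cs, ss = as.numeric(ss),
                 metadata = md),
            class = "cs_session")
}

#' Pipeline configuration
#'
#' Collects the analysis constants (windows, thresholds, bin sizes, bootstrap
#' sizes, seed) used by [run_pipeline()].
#'
#' @param ... overrides of the defaults
#' @return named list
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    windows = analysis_windows(),
    primary_threshold = 30, corrective_threshold = 10,
    primary_amplitude_range = c(13, 17),
    corrective_amplitude_range = c(0.2, 2),
    kernel_sd = 5,
    amplitude_bin = 0.5, amplitude_range = c(13, 16),
    error_bin = 0.5, error_range = c(-2, 2),
    duration_bin = 5,
    min_per_bin = 10,
    peak_boot = list(n_cells = 50, min_trials = 10, reps = 200),
    trough_boot = list(n_trials = 1000, reps = 200),
    alpha = 0.05,
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown pipeline option: ", nm)
    cfg[[nm]] <- over[[nm]]
  }
  ## basic window sanity
  for (w in cfg$windows) check_window(w)
  cfg
}

#' Run the analysis pipeline over sessions
#'
#' For each session: saccade detection and labeling, preferred-direction
#' assignment, amplitude tuning, error-magnitude tuning, per-cell encoding
#' tests, CS-duration percent-change profile. Population outputs: fatigue
#' summary, encoding matrix and parameter cross-correlations, population
#' duration profile with modulation epochs. Every stage writes CSV output plus
#' a JSON provenance record.
#'
#' @param session_paths character vector of session directories
#' @param out_dir results directory
#' @param config a [pipeline_config()]
#' @return `out_dir`, invisibly
#' @export
run_pipeline <- function(session_paths, out_dir, config = pipeline_config()) {
  stopifnot(length(session_paths) >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wins <- config$windows
  all_events <- list(); enc_rows <- list(); dur_series <- list()
  pd_rows <- list()

  for (si in seq_along(session_paths)) {
    sess <- read_session(session_paths[si])
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop("stage '", what, "' failed for session ", session_paths[si], ": ",
             conditionMessage(e), call. = FALSE)
      })
    }
    ev <- stage("behavior", detect_saccades(sess))
    all_events[[si]] <- ev
    utils::write.csv(ev, file.path(out_dir, sprintf("events_s%02d.csv", si)),
                     row.names = FALSE)

    al <- stage("rates", align_spikes(sess$cs$time_ms, ev, "saccade_offset",
                                      c(-100, 300)))
    pd <- stage("tuning", assign_pd(al, "primary"))
    pd_rows[[si]] <- data.frame(session = si,
                                pd = if (isTRUE(pd$refused)) NA else pd$pd,
                                stat_right = pd$by_direction["right"],
                                stat_left = pd$by_direction["left"])

    amp_tun <- tryCatch(
      binned_tuning(al, "amplitude", config$amplitude_bin,
                    range = config$amplitude_range, response = "peak_rate",
                    window = wins$early_post,
                    min_per_bin = config$min_per_bin),
      error = function(e) NULL)
    if (!is.null(amp_tun)) {
      utils::write.csv(amp_tun$table,
                       file.path(out_dir, sprintf("amp_tuning_s%02d.csv", si)),
                       row.names = FALSE)
    }

    enc_rows[[si]] <- stage("encoding",
                            encode_cell(sess$cs$time_ms, ev, sess$trials,
                                        cell = si, alpha = config$alpha))

    if (all(is.finite(sess$cs$duration_ms))) {
      prim <- ev[ev$type == "primary", ]
      dur_series[[length(dur_series) + 1L]] <-
        stage("csduration",
              percent_change_series(sess$cs, prim$onset))
    }
  }

  fat <- fatigue_summary(all_events)
  if (!is.null(fat$per_session)) {
    utils::write.csv(fat$per_session, file.path(out_dir, "fatigue.csv"),
                     row.names = FALSE)
  }
  enc <- do.call(rbind, enc_rows)
  utils::write.csv(enc, file.path(out_dir, "encoding_tests.csv"),
                   row.names = FALSE)
  mat <- build_encoding_matrix(enc)
  utils::write.csv(mat$binary, file.path(out_dir, "encoding_matrix.csv"))
  cc <- cross_correlate(mat$binary)
  utils::write.csv(cc, file.path(out_dir, "parameter_crosscorr.csv"))
  utils::write.csv(do.call(rbind, pd_rows),
                   file.path(out_dir, "preferred_directions.csv"),
                   row.names = FALSE)
  if (length(dur_series)) {
    dp <- population_duration_profile(dur_series)
    utils::write.csv(dp, file.path(out_dir, "duration_profile.csv"),
                     row.names = FALSE)
    ep <- tryCatch(detect_epochs(dp), error = function(e) NULL)
    if (!is.null(ep)) {
      utils::write.csv(ep$epochs, file.path(out_dir, "duration_epochs.csv"),
                       row.names = FALSE)
    }
  }

  prov <- list(
    package_version = as.character(utils::packageVersion("csmux")),
    r_version = R.version.string,
    sessions = session_paths,
    n_events = vapply(all_events, nrow, integer(1)),
    config_hash = digest_config(config),
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

## stable hash of the config (no extra deps: serialize + sum)
digest_config <- function(config) {
  raw <- serialize(config, NULL, ascii = TRUE)
  sprintf("%08x", sum(as.integer(raw) * seq_along(raw)) %% .Machine$integer.max)
}
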