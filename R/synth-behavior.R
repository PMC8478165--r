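#' Session configuration for the oculomotor simulator
#'
#' Bundles the behavioral parameters of a simulated repetitive-saccade session:
#' a trial starts when the central fixation dot reappears, the target jumps to
#' `target_eccentricity` deg left or right after a 400-600 ms fixation period,
#' the animal makes a centrifugal (CF) saccade, possibly followed by a small
#' corrective saccade when the residual retinal error exceeds
#' `corrective_trigger_threshold`, and returns to the center (CP saccade)
#' shortly after the next trial onset. Saccadic fatigue is modeled as a
#' geometric decay of a peak-velocity multiplier from 1 on the first trial to
#' `fatigue_velocity_ratio` on the last, compensated by duration scaling so
#' amplitude is preserved.
#'
#' @param n_trials number of trials
#' @param sampling_rate eye-trace sampling rate (Hz)
#' @param fixation_duration_range ms pair; fixation-dot period before the
#'   target jump
#' @param target_eccentricity target position (deg, unsigned)
#' @param target_display_duration_range ms pair; how long the target stays on
#' @param intertrial_interval ms between target offset and fixation reappearance
#' @param trial_duration nominal trial duration (ms), metadata only
#' @param saccade_latency_mean,saccade_latency_sd CF saccade latency after the
#'   target jump (ms)
#' @param fatigue_velocity_ratio late/early peak-velocity multiplier in (0, 1]
#' @param endpoint_noise_sd SD of Gaussian primary-saccade endpoint scatter (deg)
#' @param corrective_trigger_threshold |error| above which a corrective saccade
#'   is made (deg)
#' @param corrective_latency_mean,corrective_latency_sd corrective-saccade
#'   latency after the primary-saccade offset (ms)
#' @param corrective_endpoint_noise_sd SD of the corrective-saccade landing
#'   scatter around the target (deg); corrective saccades reduce, not erase,
#'   the residual error
#' @param cp_latency_mean,cp_latency_sd CP (return) saccade latency after the
#'   fixation dot reappears (ms)
#' @param position_noise_sd white measurement noise added to the trace (deg)
#' @param base_peak_velocity peak velocity of an unfatigued saccade at
#'   `target_eccentricity` (deg/s)
#' @param cf_direction +1 for rightward CF saccades, -1 for leftward
#' @param seed integer seed for the behavioral random stream
#' @return object of class `session_config`
#' @export
session_config <- function(n_trials = 300,
                           sampling_rate = 1000,
                           fixation_duration_range = c(400, 600),
                           target_eccentricity = 15,
                           target_display_duration_range = c(700, 900),
                           intertrial_interval = 100,
                           trial_duration = 1200,
                           saccade_latency_mean = 170,
                           saccade_latency_sd = 30,
                           fatigue_velocity_ratio = 0.9,
                           endpoint_noise_sd = 0.6,
                           corrective_trigger_threshold = 0.5,
                           corrective_latency_mean = 250,
                           corrective_latency_sd = 40,
                           corrective_endpoint_noise_sd = 0.15,
                           cp_latency_mean = 110,
                           cp_latency_sd = 30,
                           position_noise_sd = 0.02,
                           base_peak_velocity = 600,
                           cf_direction = 1,
                           seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_trials >= 1,
    sampling_rate > 0,
    all(fixation_duration_range > 0), diff(fixation_duration_range) >= 0,
    target_eccentricity > 0,
    all(target_display_duration_range > 0), diff(target_display_duration_range) >= 0,
    intertrial_interval > 0, trial_duration > 0,
    fatigue_velocity_ratio > 0, fatigue_velocity_ratio <= 1,
    endpoint_noise_sd >= 0, position_noise_sd >= 0,
    corrective_endpoint_noise_sd >= 0,
    corrective_trigger_threshold > 0,
    base_peak_velocity > 0,
    cf_direction %in% c(-1, 1)
  )
  ## the CF saccade and a possible corrective saccade must complete while the
  ## target is displayed
  need <- saccade_latency_mean + 3 * saccade_latency_sd +
    corrective_latency_mean + 3 * corrective_latency_sd + 60
  if (need > target_display_duration_range[1]) {
    stop("trial timing cannot fit: saccade + corrective chain (", round(need),
         " ms) exceeds the minimum target display duration")
  }
  structure(cfg, class = "session_config")
}

## sub-generator seed offsets: behavior / CS / SS streams are independently
## reproducible from one session seed
.SEED_BEHAVIOR <- 0L
.SEED_CS <- 104729L
.SEED_SS <- 224737L

#' Generate eye-movement behavior for one session
#'
#' Builds the eye-position trace, the trial table, and a ground-truth record of
#' every simulated saccade. Saccades follow a minimum-jerk position profile
#' (peak velocity `1.875 * A / D`). The primary-saccade endpoint is
#' `target + N(0, endpoint_noise_sd)`; whenever the absolute retinal error
#' exceeds `corrective_trigger_threshold` a corrective saccade lands the eye on
#' the target. Peak velocity decays geometrically across trials to
#' `fatigue_velocity_ratio`, with amplitude preserved by duration scaling.
#'
#' @param config a [session_config()]
#' @return list with elements `trace` (data.frame `t_ms`, `x_deg`, `y_deg`),
#'   `trials` (data.frame of trial events), and `truth` (list with the saccade
#'   table and session metadata; never read by the analysis functions)
#' @export
generate_behavior <- function(config) {
  stopifnot(inherits(config, "session_config"))
  set.seed(config$seed + .SEED_BEHAVIOR)
  n <- config$n_trials
  ecc <- config$target_eccentricity * config$cf_direction

  fixdur <- stats::runif(n, config$fixation_duration_range[1],
                         config$fixation_duration_range[2])
  dispdur <- stats::runif(n, config$target_display_duration_range[1],
                          config$target_display_duration_range[2])
  period <- fixdur + dispdur + config$intertrial_interval
  onset <- c(0, cumsum(period[-n])) + 200  # 200 ms lead-in
  jump <- onset + fixdur
  target_off <- jump + dispdur

  ## fatigue multiplier: 1 on trial 1, fatigue_velocity_ratio on trial n
  mult <- if (n == 1) 1 else config$fatigue_velocity_ratio^((seq_len(n) - 1) / (n - 1))

  base_dur <- minjerk_peak_velocity(config$target_eccentricity, 1) /
    config$base_peak_velocity  # ms at multiplier 1
  sacc <- list()

  ## CF saccades: aimed at the target, launched from wherever the previous
  ## return saccade left the eye (state-consistent positions, no drift)
  lat <- pmax(80, stats::rnorm(n, config$saccade_latency_mean, config$saccade_latency_sd))
  end_noise <- stats::rnorm(n, 0, config$endpoint_noise_sd)
  cp_end <- stats::rnorm(n, 0, config$endpoint_noise_sd)
  cf_start <- c(0, cp_end[-n])
  cf_on <- jump + lat
  cf_end_pos <- ecc + end_noise
  ## duration set by the fatigue multiplier; peak velocity then carries the
  ## main-sequence dependence on amplitude (1.875 * A / D)
  cf_dur <- base_dur / mult
  sacc$cf <- data.frame(
    trial = seq_len(n), kind = "CF",
    onset = cf_on, duration = cf_dur,
    start_pos = cf_start, end_pos = cf_end_pos,
    target = ecc, stringsAsFactors = FALSE
  )

  ## corrective saccades after CF when |error| exceeds the trigger threshold;
  ## they land near, not on, the target
  err <- ecc - cf_end_pos
  do_corr <- abs(err) > config$corrective_trigger_threshold
  corr_end <- rep(NA_real_, n)
  if (any(do_corr)) {
    clat <- pmax(80, stats::rnorm(sum(do_corr), config$corrective_latency_mean,
                                  config$corrective_latency_sd))
    corr_end[do_corr] <- ecc + stats::rnorm(sum(do_corr), 0,
                                            config$corrective_endpoint_noise_sd)
    camp <- abs(corr_end[do_corr] - cf_end_pos[do_corr])
    sacc$corr <- data.frame(
      trial = which(do_corr), kind = "corrective",
      onset = cf_on[do_corr] + cf_dur[do_corr] + clat,
      duration = 25 + 12 * camp,
      start_pos = cf_end_pos[do_corr], end_pos = corr_end[do_corr],
      target = ecc, stringsAsFactors = FALSE
    )
  }

  ## CP return saccades: triggered by the fixation-dot reappearance, i.e. the
  ## *next* trial onset (the last one by the nominal end of the session)
  cp_trigger <- c(onset[-1], target_off[n] + config$intertrial_interval)
  cp_lat <- pmax(40, stats::rnorm(n, config$cp_latency_mean, config$cp_latency_sd))
  cp_start <- ifelse(do_corr, corr_end, cf_end_pos)
  cp_on <- cp_trigger + cp_lat
  sacc$cp <- data.frame(
    trial = seq_len(n), kind = "CP",
    onset = cp_on, duration = base_dur / mult,
    start_pos = cp_start, end_pos = cp_end,
    target = 0, stringsAsFactors = FALSE
  )

  sac <- do.call(rbind, sacc)
  sac <- sac[order(sac$onset), ]
  rownames(sac) <- NULL
  sac$offset <- sac$onset + sac$duration
  sac$amplitude <- abs(sac$end_pos - sac$start_pos)
  sac$direction <- sign(sac$end_pos - sac$start_pos)
  sac$peak_velocity <- minjerk_peak_velocity(sac$amplitude, sac$duration)
  sac$signed_error <- ifelse(sac$kind == "corrective", NA_real_,
                             sac$target - sac$end_pos)

  session_end <- max(sac$offset) + 400

  ## render the trace: per-saccade displacement increments, then cumsum
  dt <- 1000 / config$sampling_rate
  t_ms <- seq(0, session_end, by = dt)
  dx <- numeric(length(t_ms))
  for (k in seq_len(nrow(sac))) {
    i0 <- findInterval(sac$onset[k], t_ms)
    i1 <- min(length(t_ms), i0 + ceiling(sac$duration[k] / dt))
    tau <- (t_ms[i0:i1] - sac$onset[k]) / sac$duration[k]
    prof <- (sac$end_pos[k] - sac$start_pos[k]) * minjerk_pos(tau)
    dx[i0:i1] <- dx[i0:i1] + diff(c(0, prof))
  }
  x <- cumsum(dx)
  if (config$position_noise_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, config$position_noise_sd)
  }
  y <- stats::rnorm(length(t_ms), 0, config$position_noise_sd)

  trials <- data.frame(
    trial = seq_len(n),
    trial_onset_ms = onset,
    target_jump_ms = jump,
    target_off_ms = target_off,
    target_pos_deg = ecc,
    fixation_pos_deg = 0,
    reward = abs(err) <= 2
  )

  list(
    trace = data.frame(t_ms = t_ms, x_deg = x, y_deg = y),
    trials = trials,
    truth = list(
      saccades = sac,
      trials = trials,
      session_end = session_end,
      sampling_rate = config$sampling_rate,
      config = config
    )
  )
}
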