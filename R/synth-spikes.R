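#' Neuron tuning parameters for the complex-spike generator
#'
#' Defines the latent firing-rate model of one simulated Purkinje cell. The
#' complex-spike (CS) rate is
#' `lambda(t) = clip(baseline * (1 - suppression(t)) + burst(t) + error_tonic(t)
#' + corrective_burst(t) + trial_onset(t), 0)`:
#' a ~1 spike/s baseline, perisaccadic suppression of the baseline inside
#' `suppression_window` around every primary-saccade onset, a Gaussian burst
#' locked `burst_latency` ms after each primary-saccade offset whose peak is
#' the direction-specific gain plus `amplitude_slope * (amplitude - 15)`, a
#' tonic error component `error_tonic_gain * E` (E = signed error toward the
#' preferred error direction) in the 50-250 ms window after the primary-saccade
#' offset, a burst after each corrective-saccade offset, and a Gaussian
#' trial-onset bump (SD 30 ms) at `trial_onset_latency` whose amplitude is
#' linearly attenuated by the lateness of the preceding return saccade's
#' arrival at the fixation dot.
#'
#' Each CS is assigned a duration: `cs_base_duration` plus
#' `cs_spikelet_increment` with probability
#' `clip01(spikelet_base_prob + spikelet_prob_gain * (2 * plogis(lambda - baseline) - 1))`,
#' so the long-CS (extra-spikelet) probability rises and falls with the rate
#' modulation, yoking duration changes to rate changes.
#'
#' @param cs_baseline_rate baseline CS rate (spikes/s)
#' @param pd_primary,pd_corrective,pd_error preferred directions (+1 right,
#'   -1 left) for primary saccades, corrective saccades, and retinal errors
#' @param burst_gain_preferred,burst_gain_anti peak burst rate (spikes/s) at
#'   the 15-deg reference amplitude in the preferred / antipreferred direction
#' @param amplitude_slope burst-peak change per deg of saccade amplitude
#'   (spikes/s/deg)
#' @param burst_latency,burst_width burst center (ms after saccade offset) and
#'   Gaussian SD (ms)
#' @param error_tonic_gain tonic rate per deg of signed error (spikes/s/deg),
#'   active 50-250 ms after the primary-saccade offset
#' @param corrective_burst_gain peak burst after corrective saccades in the
#'   preferred corrective direction (spikes/s); the antipreferred direction
#'   gets 30\% of it
#' @param trial_onset_gain,trial_onset_latency,trial_onset_arrival_slope
#'   trial-onset bump peak (spikes/s), its latency (ms), and the attenuation of
#'   the peak per ms of return-saccade arrival lateness
#' @param suppression_window ms pair relative to primary-saccade onset
#' @param suppression_depth fraction of the baseline removed inside the window
#' @param cs_base_duration,cs_spikelet_increment short-CS duration and the
#'   extra-spikelet increment (ms)
#' @param spikelet_base_prob baseline probability of the long (extra-spikelet)
#'   CS class
#' @param spikelet_prob_gain modulation of the long-CS probability by the rate
#'   excursion above baseline
#' @param ss_baseline_rate simple-spike rate (spikes/s)
#' @param ss_pause_range ms pair; the enforced SS pause after every CS
#' @return object of class `neuron_tuning`
#' @export
neuron_tuning <- function(cs_baseline_rate = 1,
                          pd_primary = 1, pd_corrective = 1, pd_error = 1,
                          burst_gain_preferred = 5, burst_gain_anti = 1,
                          amplitude_slope = 0.5,
                          burst_latency = 50, burst_width = 15,
                          error_tonic_gain = 0.8,
                          corrective_burst_gain = 4,
                          trial_onset_gain = 2, trial_onset_latency = 200,
                          trial_onset_arrival_slope = 0.003,
                          suppression_window = c(-75, 85),
                          suppression_depth = 0.7,
                          cs_base_duration = 4.2, cs_spikelet_increment = 1.8,
                          spikelet_base_prob = 0.3, spikelet_prob_gain = 0.3,
                          ss_baseline_rate = 50,
                          ss_pause_range = c(10, 20)) {
  tun <- as.list(environment())
  stopifnot(
    cs_baseline_rate >= 0, ss_baseline_rate >= 0,
    pd_primary %in% c(-1, 1), pd_corrective %in% c(-1, 1), pd_error %in% c(-1, 1),
    burst_gain_preferred >= 0, burst_gain_anti >= 0,
    corrective_burst_gain >= 0, trial_onset_gain >= 0,
    suppression_depth >= 0, suppression_depth <= 1,
    cs_base_duration > 0, cs_spikelet_increment >= 0,
    spikelet_base_prob >= 0, spikelet_base_prob <= 1,
    burst_width > 0, diff(suppression_window) > 0, diff(ss_pause_range) >= 0
  )
  structure(tun, class = "neuron_tuning")
}

## index/value pairs of a Gaussian bump (peak amp, sd w, center mu) on a 1-ms
## grid starting at t = 0; used to accumulate the latent rate without copying
bump_idx <- function(n, mu, amp, w) {
  i0 <- max(1L, as.integer(floor(mu - 5 * w)) + 1L)
  i1 <- min(n, as.integer(ceiling(mu + 5 * w)) + 1L)
  if (i1 < i0 || amp == 0) return(NULL)
  t <- (i0:i1) - 1
  list(i = i0:i1, v = amp * exp(-0.5 * ((t - mu) / w)^2))
}

box_idx <- function(n, from, to, val) {
  i0 <- max(1L, as.integer(floor(from)) + 1L)
  i1 <- min(n, as.integer(ceiling(to)))
  if (i1 < i0 || val == 0) return(NULL)
  list(i = i0:i1, v = rep(val, i1 - i0 + 1L))
}

#' Latent complex-spike rate of a simulated cell
#'
#' Evaluates the generative rate `lambda(t)` on a 1-ms grid over the whole
#' session, from the ground-truth behavior and a [neuron_tuning()].
#'
#' @param tuning a [neuron_tuning()]
#' @param truth the `truth` element returned by [generate_behavior()]
#' @return numeric vector, spikes/s, one value per ms from time 0
#' @export
latent_cs_rate <- function(tuning, truth) {
  stopifnot(inherits(tuning, "neuron_tuning"))
  sac <- truth$saccades
  n_ms <- as.integer(ceiling(truth$session_end)) + 1L
  lam <- rep(tuning$cs_baseline_rate, n_ms)

  prim <- sac[sac$kind %in% c("CF", "CP"), ]
  corr <- sac[sac$kind == "corrective", ]
  parts <- list()

  ## perisaccadic suppression of the baseline
  if (tuning$suppression_depth > 0) {
    for (k in seq_len(nrow(prim))) {
      parts[[length(parts) + 1L]] <-
        box_idx(n_ms, prim$onset[k] + tuning$suppression_window[1],
                prim$onset[k] + tuning$suppression_window[2],
                -tuning$suppression_depth * tuning$cs_baseline_rate)
    }
  }

  ## primary-saccade burst, locked to saccade offset
  for (k in seq_len(nrow(prim))) {
    gain <- if (prim$direction[k] == tuning$pd_primary)
      tuning$burst_gain_preferred else tuning$burst_gain_anti
    amp <- max(0, gain + tuning$amplitude_slope * (prim$amplitude[k] - 15))
    parts[[length(parts) + 1L]] <-
      bump_idx(n_ms, prim$offset[k] + tuning$burst_latency, amp,
               tuning$burst_width)
  }

  ## tonic error component in the late postsaccadic window
  if (tuning$error_tonic_gain != 0) {
    for (k in seq_len(nrow(prim))) {
      e <- prim$signed_error[k] * tuning$pd_error
      parts[[length(parts) + 1L]] <-
        box_idx(n_ms, prim$offset[k] + 50, prim$offset[k] + 250,
                tuning$error_tonic_gain * e)
    }
  }

  ## corrective-saccade burst, locked to corrective offset
  for (k in seq_len(nrow(corr))) {
    gain <- if (corr$direction[k] == tuning$pd_corrective)
      tuning$corrective_burst_gain else 0.3 * tuning$corrective_burst_gain
    parts[[length(parts) + 1L]] <-
      bump_idx(n_ms, corr$offset[k] + tuning$burst_latency, gain,
               tuning$burst_width)
  }

  ## trial-onset bump, attenuated by the arrival lateness of the preceding
  ## return (CP) saccade at the fixation dot
  if (tuning$trial_onset_gain > 0) {
    trials <- truth$trials
    cp <- sac[sac$kind == "CP", ]
    for (i in seq_len(nrow(trials))) {
      t0 <- trials$trial_onset_ms[i]
      prev_cp <- cp$offset[cp$trial == i - 1L]
      lateness <- if (length(prev_cp)) max(0, prev_cp[1] - t0) else 0
      amp <- tuning$trial_onset_gain *
        max(0, 1 - tuning$trial_onset_arrival_slope * lateness)
      parts[[length(parts) + 1L]] <-
        bump_idx(n_ms, t0 + tuning$trial_onset_latency, amp, 30)
    }
  }

  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts)) {
    idx <- unlist(lapply(parts, `[[`, "i"), use.names = FALSE)
    val <- unlist(lapply(parts, `[[`, "v"), use.names = FALSE)
    add <- numeric(n_ms)
    agg <- rowsum(val, idx)
    add[as.integer(rownames(agg))] <- agg[, 1]
    lam <- lam + add
  }
  pmax(lam, 0)
}

#' Sample an inhomogeneous Poisson spike train by thinning
#'
#' @param lam rate vector in spikes/s on a 1-ms grid starting at t = 0
#'   (piecewise constant within each ms)
#' @return sorted spike times in ms
#' @export
simulate_poisson_train <- function(lam) {
  lmax <- max(lam)
  if (lmax <= 0) return(numeric(0))
  t_end_s <- length(lam) / 1000
  n <- stats::rpois(1, lmax * t_end_s)
  if (n == 0) return(numeric(0))
  cand <- sort(stats::runif(n, 0, length(lam)))
  keep <- stats::runif(n) < lam[floor(cand) + 1L] / lmax
  cand[keep]
}

#' Generate complex- and simple-spike trains for one cell
#'
#' Draws CS times from the latent rate by Poisson thinning, assigns each CS a
#' duration from the two-class (short / extra-spikelet) model, and draws SS
#' times at the baseline SS rate with an enforced pause after every CS.
#'
#' @param tuning a [neuron_tuning()]
#' @param truth the `truth` element returned by [generate_behavior()]
#' @param seed integer seed for the spike random streams (CS and SS streams
#'   are seeded independently from it)
#' @param return_lambda keep the latent rate vector in the result?
#' @return list with `cs` (data.frame `time_ms`, `duration_ms`), `ss`
#'   (numeric times), and optionally `lambda` (1-ms latent rate)
#' @export
generate_spikes <- function(tuning, truth, seed = 1L, return_lambda = TRUE) {
  stopifnot(inherits(tuning, "neuron_tuning"))
  lam <- latent_cs_rate(tuning, truth)

  set.seed(seed + .SEED_CS)
  cs_t <- simulate_poisson_train(lam)
  delta <- lam[floor(cs_t) + 1L] - tuning$cs_baseline_rate
  p_long <- clip01(tuning$spikelet_base_prob +
                     tuning$spikelet_prob_gain * (2 * stats::plogis(delta) - 1))
  long <- stats::runif(length(cs_t)) < p_long
  cs <- data.frame(
    time_ms = cs_t,
    duration_ms = tuning$cs_base_duration +
      ifelse(long, tuning$cs_spikelet_increment, 0)
  )

  set.seed(seed + .SEED_SS)
  t_end_s <- length(lam) / 1000
  n_ss <- stats::rpois(1, tuning$ss_baseline_rate * t_end_s)
  ss <- sort(stats::runif(n_ss, 0, length(lam)))
  if (length(cs_t) && length(ss)) {
    pause <- stats::runif(length(cs_t), tuning$ss_pause_range[1],
                          tuning$ss_pause_range[2])
    drop <- rep(FALSE, length(ss))
    for (j in seq_along(cs_t)) {
      drop <- drop | (ss > cs_t[j] & ss <= cs_t[j] + pause[j])
    }
    ss <- ss[!drop]
  }

  out <- list(cs = cs, ss = ss)
  if (return_lambda) out$lambda <- lam
  out
}

#' Simulate a full session (behavior + spikes)
#'
#' Convenience wrapper tying [generate_behavior()] and [generate_spikes()]
#' into the session container used by [write_session()] / [read_session()].
#'
#' @param config a [session_config()]
#' @param tuning a [neuron_tuning()]
#' @param session_id,monkey_id metadata strings
#' @return list of class `cs_session` with `trace`, `trials`, `cs`, `ss`,
#'   `metadata`, plus a `truth` element (ground truth, written separately and
#'   never read by the analysis functions)
#' @export
simulate_session <- function(config, tuning = neuron_tuning(),
                             session_id = "sim01", monkey_id = "simA") {
  beh <- generate_behavior(config)
  spk <- generate_spikes(tuning, beh$truth, seed = config$seed,
                         return_lambda = FALSE)
  structure(list(
    trace = beh$trace,
    trials = beh$trials,
    cs = spk$cs,
    ss = spk$ss,
    metadata = list(
      monkey_id = monkey_id, session_id = session_id,
      cf_direction = if (config$cf_direction > 0) "right" else "left",
      sampling_rate = config$sampling_rate
    ),
    truth = beh$truth
  ), class = "cs_session")
}
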