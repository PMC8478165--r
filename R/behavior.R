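#' Eye velocity from a position trace
#'
#' Central-difference derivative of the horizontal eye position, low-pass
#' filtered with a zero-phase (forward-backward) 2nd-order Butterworth filter.
#' Filtering and differentiation are both linear, so the filter is applied to
#' the position signal before differencing.
#'
#' @param trace data.frame with columns `t_ms` and `x_deg` (uniform sampling)
#' @param smoothing_cutoff low-pass cutoff (Hz)
#' @return numeric velocity (deg/s), same grid as the trace
#' @export
compute_velocity <- function(trace, smoothing_cutoff = 80) {
  stopifnot(all(c("t_ms", "x_deg") %in% names(trace)))
  dt <- diff(trace$t_ms[1:2])
  if (any(abs(diff(trace$t_ms) - dt) > 1e-6)) stop("trace must be uniformly sampled")
  fs <- 1000 / dt
  n <- nrow(trace)
  if (n < ceiling(6 * fs / smoothing_cutoff)) {
    stop("trace shorter than the filter warm-up")
  }
  x <- trace$x_deg
  if (smoothing_cutoff < fs / 2) {
    bf <- signal::butter(2, smoothing_cutoff / (fs / 2), type = "low")
    ## reflect-pad both ends so the forward-backward pass has no edge
    ## transients on non-zero-mean traces
    np <- min(n - 1L, ceiling(3 * fs / smoothing_cutoff))
    xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
    xf <- signal::filtfilt(bf, xp)
    x <- xf[(np + 1):(np + n)]
  }
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt) * 1000
  v[1] <- v[2]
  v[n] <- v[n - 1]
  v
}

## maximal runs of |v| >= threshold, with sub-gap merging; returns start/end
## sample indices (inclusive)
threshold_runs <- function(v, threshold, merge_gap_ms, dt) {
  above <- abs(v) >= threshold
  if (!any(above)) return(data.frame(i0 = integer(0), i1 = integer(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(i0 = starts[r$values], i1 = ends[r$values])
  if (nrow(runs) > 1) {
    gap <- (runs$i0[-1] - runs$i1[-nrow(runs)] - 1L) * dt
    keep_new <- c(TRUE, gap >= merge_gap_ms)
    grp <- cumsum(keep_new)
    runs <- data.frame(
      i0 = tapply(runs$i0, grp, min),
      i1 = tapply(runs$i1, grp, max)
    )
  }
  runs
}

runs_to_events <- function(runs, trace, v, type) {
  n <- nrow(trace)
  ## discard runs clipped at the trace boundaries
  ok <- runs$i0 > 1L & runs$i1 < n
  runs <- runs[ok, , drop = FALSE]
  if (!nrow(runs)) return(empty_events())
  onset <- trace$t_ms[runs$i0]
  offset <- trace$t_ms[runs$i1]
  start_pos <- trace$x_deg[runs$i0]
  end_pos <- trace$x_deg[runs$i1]
  pk <- vapply(seq_len(nrow(runs)),
               function(k) max(abs(v[runs$i0[k]:runs$i1[k]])), numeric(1))
  data.frame(
    onset = onset, offset = offset, duration = offset - onset,
    amplitude = abs(end_pos - start_pos),
    peak_velocity = pk,
    direction = sign(end_pos - start_pos),
    type = type, subtype = "none",
    start_pos = start_pos, end_pos = end_pos,
    signed_error = NA_real_, assoc_trial = NA_integer_,
    stringsAsFactors = FALSE
  )
}

empty_events <- function() {
  data.frame(onset = numeric(0), offset = numeric(0), duration = numeric(0),
             amplitude = numeric(0), peak_velocity = numeric(0),
             direction = numeric(0), type = character(0),
             subtype = character(0), start_pos = numeric(0),
             end_pos = numeric(0), signed_error = numeric(0),
             assoc_trial = integer(0), stringsAsFactors = FALSE)
}

#' Detect primary saccades
#'
#' Maximal runs of `|velocity| >= 30` deg/s (runs separated by less than 10 ms
#' are merged); onset/offset are the first/last suprathreshold samples; only
#' events with horizontal amplitude between 13 and 17 deg are retained.
#'
#' @param velocity velocity series from [compute_velocity()]
#' @param trace the eye trace the velocity was computed from
#' @param threshold velocity criterion (deg/s)
#' @param amplitude_range retained amplitude range (deg)
#' @param merge_gap_ms runs closer than this are merged
#' @return data.frame of saccade events (possibly empty)
#' @export
detect_primary_saccades <- function(velocity, trace, threshold = 30,
                                    amplitude_range = c(13, 17),
                                    merge_gap_ms = 10) {
  dt <- diff(trace$t_ms[1:2])
  runs <- threshold_runs(velocity, threshold, merge_gap_ms, dt)
  ev <- runs_to_events(runs, trace, velocity, "primary")
  ev[ev$amplitude >= amplitude_range[1] & ev$amplitude <= amplitude_range[2], ,
     drop = FALSE]
}

#' Detect corrective saccades
#'
#' Runs at the more lenient 10 deg/s threshold with duration longer than 10 ms
#' and amplitude between 0.2 and 2 deg, occurring between a primary-saccade
#' offset and the next primary-saccade onset; runs overlapping a primary event
#' are excluded.
#'
#' @param velocity velocity series
#' @param trace the eye trace
#' @param primary_events output of [detect_primary_saccades()]
#' @param threshold velocity criterion (deg/s)
#' @param min_duration minimum run duration (ms, exclusive)
#' @param amplitude_range retained amplitude range (deg)
#' @param merge_gap_ms runs closer than this are merged
#' @return data.frame of corrective saccade events
#' @export
detect_corrective_saccades <- function(velocity, trace, primary_events,
                                       threshold = 10, min_duration = 10,
                                       amplitude_range = c(0.2, 2),
                                       merge_gap_ms = 10) {
  dt <- diff(trace$t_ms[1:2])
  runs <- threshold_runs(velocity, threshold, merge_gap_ms, dt)
  ev <- runs_to_events(runs, trace, velocity, "corrective")
  ev <- ev[ev$duration > min_duration &
             ev$amplitude >= amplitude_range[1] &
             ev$amplitude <= amplitude_range[2], , drop = FALSE]
  if (!nrow(ev) || !nrow(primary_events)) return(ev[integer(0), , drop = FALSE])
  keep <- vapply(seq_len(nrow(ev)), function(k) {
    on <- ev$onset[k]; off <- ev$offset[k]
    ## must not overlap any primary event
    if (any(on < primary_events$offset & off > primary_events$onset)) return(FALSE)
    ## must lie between a primary offset and the next primary onset
    prev <- primary_events$offset[primary_events$offset <= on]
    if (!length(prev)) return(FALSE)
    nxt <- primary_events$onset[primary_events$onset >= off]
    lo <- max(prev)
    hi <- if (length(nxt)) min(nxt) else Inf
    on >= lo && off <= hi
  }, logical(1))
  ev[keep, , drop = FALSE]
}

#' Label saccades as CF/CP and compute signed retinal errors
#'
#' Primary saccades made after the target jump toward the eccentric target are
#' labeled CF; saccades returning to the central fixation dot are labeled CP.
#' The signed error is `active target position - end position` (the vector
#' from the saccade endpoint to the target), rightward positive. Corrective
#' saccades inherit the trial and the signed error of the preceding primary
#' saccade.
#'
#' @param events saccade events (primary and/or corrective rows)
#' @param trials trial table with `trial_onset_ms`, `target_jump_ms`,
#'   `target_off_ms`, `target_pos_deg`, `fixation_pos_deg`
#' @return the events with `subtype`, `assoc_trial`, `signed_error` filled in
#' @export
classify_and_error <- function(events, trials) {
  if (!nrow(events)) return(events)
  prim <- which(events$type == "primary")
  for (k in prim) {
    on <- events$onset[k]
    i <- findInterval(on, trials$trial_onset_ms)
    if (i < 1) {
      events$subtype[k] <- "none"
      warning("primary saccade at ", round(on), " ms has no bracketing trial")
      next
    }
    events$assoc_trial[k] <- trials$trial[i]
    in_target <- on >= trials$target_jump_ms[i] & on < trials$target_off_ms[i]
    ## saccades launched between target offset / fixation reappearance and the
    ## next target jump are returns to the fixation dot
    target <- if (in_target) trials$target_pos_deg[i] else trials$fixation_pos_deg[i]
    toward <- sign(target - events$start_pos[k])
    if (toward != 0 && toward != events$direction[k]) {
      events$subtype[k] <- "none"
      warning("primary saccade at ", round(on),
              " ms moves away from the active target; labeled none")
      next
    }
    events$subtype[k] <- if (in_target) "CF" else "CP"
    events$signed_error[k] <- target - events$end_pos[k]
  }
  corr <- which(events$type == "corrective")
  prim_rows <- events[events$type == "primary", , drop = FALSE]
  for (k in corr) {
    prev <- which(prim_rows$offset <= events$onset[k])
    if (!length(prev)) next
    j <- prev[which.max(prim_rows$offset[prev])]
    events$assoc_trial[k] <- prim_rows$assoc_trial[j]
    events$signed_error[k] <- prim_rows$signed_error[j]
  }
  events
}

#' Detect and label all saccades in a session
#'
#' Convenience wrapper: velocity, primary and corrective detection, CF/CP
#' labeling and signed errors.
#'
#' @param session a session as returned by [simulate_session()] or
#'   [read_session()]
#' @param smoothing_cutoff velocity low-pass cutoff (Hz)
#' @return data.frame of labeled saccade events
#' @export
detect_saccades <- function(session, smoothing_cutoff = 80) {
  v <- compute_velocity(session$trace, smoothing_cutoff)
  prim <- detect_primary_saccades(v, session$trace)
  corr <- detect_corrective_saccades(v, session$trace, prim)
  ev <- rbind(prim, corr)
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  classify_and_error(ev, session$trials)
}

#' Early/late fatigue summary
#'
#' Compares the first and last `n_edge_trials` CF (and CP) saccades of each
#' session: medians of peak velocity, duration, and amplitude, and the percent
#' change `100 * (early - late) / early`, plus medians pooled across sessions.
#'
#' @param sessions_events list of labeled event data.frames (one per session)
#' @param n_edge_trials how many saccades define the early and late groups
#' @return list with `per_session` and `pooled` data.frames
#' @export
fatigue_summary <- function(sessions_events, n_edge_trials = 30) {
  if (is.data.frame(sessions_events)) sessions_events <- list(sessions_events)
  rows <- list()
  for (s in seq_along(sessions_events)) {
    ev <- sessions_events[[s]]
    for (sub in c("CF", "CP")) {
      e <- ev[ev$type == "primary" & ev$subtype == sub, , drop = FALSE]
      if (nrow(e) < 2 * n_edge_trials) {
        message("session ", s, " (", sub, "): fewer than ",
                2 * n_edge_trials, " saccades, skipped")
        next
      }
      e <- e[order(e$onset), ]
      early <- e[seq_len(n_edge_trials), ]
      late <- e[seq(nrow(e) - n_edge_trials + 1, nrow(e)), ]
      pc <- function(var) {
        a <- stats::median(early[[var]]); b <- stats::median(late[[var]])
        c(early = a, late = b, pct_change = 100 * (a - b) / a)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        session = s, subtype = sub,
        t(c(velocity = pc("peak_velocity"), duration = pc("duration"),
            amplitude = pc("amplitude")))
      )
    }
  }
  per_session <- do.call(rbind, rows)
  pooled <- NULL
  if (!is.null(per_session)) {
    pooled <- stats::aggregate(per_session[, -(1:2)],
                               by = list(subtype = per_session$subtype),
                               FUN = stats::median)
  }
  list(per_session = per_session, pooled = pooled)
}
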