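#' Gaussian-kernel firing-rate estimate
#'
#' Convolves spike times with a unit-area Gaussian kernel (default SD 5 ms,
#' truncated at 5 SD) and divides by the number of events, giving a mean rate
#' in spikes/s on the supplied grid. The integral of the rate over the grid for
#' an isolated spike equals `1 / n_events`. Spike times are binned at the grid
#' step before convolution.
#'
#' @param spike_times spike times (ms), pooled across events
#' @param grid uniform time grid (ms)
#' @param sd kernel standard deviation (ms)
#' @param n_events divisor when the spikes were pooled over several events
#' @return numeric rate (spikes/s), one value per grid point
#' @export
kernel_rate <- function(spike_times, grid, sd = 5, n_events = 1) {
  if (length(grid) < 2) stop("grid must have at least 2 points")
  stopifnot(sd > 0, n_events >= 1)
  dt <- grid[2] - grid[1]
  pad <- ceiling(5 * sd / dt)
  n <- length(grid)
  nx <- n + 2L * pad
  counts <- numeric(nx)
  if (length(spike_times)) {
    idx <- round((spike_times - grid[1]) / dt) + 1L + pad
    idx <- idx[idx >= 1L & idx <= nx]
    if (length(idx)) {
      tb <- tabulate(idx, nbins = nx)
      counts <- as.numeric(tb)
    }
  }
  if (all(counts == 0)) return(numeric(n) + 0)
  kern <- stats::dnorm(seq(-pad, pad) * dt, sd = sd) * dt
  kern <- kern / sum(kern)   # normalized kernel: exact unit mass per spike
  full <- stats::convolve(counts, rev(kern), type = "open")
  rate_ms <- full[(2L * pad + 1L):(2L * pad + n)] / dt
  rate_ms * 1000 / n_events
}

#' Align spikes to events
#'
#' Computes spike offsets relative to each alignment time, keeping offsets in
#' the half-open window `[start, end)`, and copies the per-event covariates.
#'
#' @param spike_times spike times (ms, session clock)
#' @param events labeled saccade events (from [detect_saccades()]) or, for
#'   `alignment = "trial_onset"`, ignored in favor of `trials`
#' @param alignment one of `"saccade_onset"`, `"saccade_offset"`,
#'   `"corrective_onset"`, `"corrective_offset"`, `"trial_onset"`
#' @param window length-2 ms window relative to the alignment time
#' @param trials trial table; required for `"trial_onset"`
#' @return object of class `aligned_spikes`: list with `offsets` (list of
#'   numeric vectors, one per event), `covariates` (data.frame, one row per
#'   event), `alignment`, `window`, `n_events`
#' @export
align_spikes <- function(spike_times, events, alignment, window, trials = NULL) {
  window <- check_window(window)
  alignment <- match.arg(alignment, c("saccade_onset", "saccade_offset",
                                      "corrective_onset", "corrective_offset",
                                      "trial_onset"))
  if (alignment == "trial_onset") {
    if (is.null(trials)) stop("trials table required for trial_onset alignment")
    times <- trials$trial_onset_ms
    ## arrival time of the return (CP) saccade at the fixation dot, relative
    ## to this trial's onset
    arrival <- rep(NA_real_, length(times))
    if (!is.null(events) && nrow(events)) {
      cp <- events[events$type == "primary" & events$subtype == "CP", ,
                   drop = FALSE]
      for (i in seq_along(times)) {
        hit <- which(cp$offset >= times[i] - 100 & cp$offset < times[i] + 400)
        if (length(hit)) arrival[i] <- cp$offset[hit[1]] - times[i]
      }
    }
    cov <- data.frame(trial = trials$trial, arrival_time = arrival)
  } else {
    kind <- if (grepl("^corrective", alignment)) "corrective" else "primary"
    ev <- events[events$type == kind, , drop = FALSE]
    times <- if (grepl("onset$", alignment)) ev$onset else ev$offset
    cov <- ev[, intersect(c("amplitude", "duration", "peak_velocity",
                            "direction", "signed_error", "subtype",
                            "assoc_trial"), names(ev)), drop = FALSE]
    rownames(cov) <- NULL
  }
  offs <- lapply(times, function(t0) {
    s <- spike_times - t0
    s[s >= window[1] & s < window[2]]
  })
  structure(list(offsets = offs, covariates = cov, alignment = alignment,
                 window = window, n_events = length(times)),
            class = "aligned_spikes")
}

#' @export
print.aligned_spikes <- function(x, ...) {
  cat("<aligned_spikes> ", x$n_events, " events, alignment=", x$alignment,
      ", window=[", x$window[1], ",", x$window[2], ") ms, ",
      sum(lengths(x$offsets)), " spikes\n", sep = "")
  invisible(x)
}

## subset an aligned_spikes object by event index
subset_aligned <- function(aligned, idx) {
  structure(list(offsets = aligned$offsets[idx],
                 covariates = aligned$covariates[idx, , drop = FALSE],
                 alignment = aligned$alignment, window = aligned$window,
                 n_events = length(idx)),
            class = "aligned_spikes")
}

## mean kernel rate profile of an aligned_spikes object
aligned_profile <- function(aligned, grid = NULL, sd = 5) {
  if (is.null(grid)) {
    grid <- seq(aligned$window[1], aligned$window[2] - 1, by = 1)
  }
  rate <- kernel_rate(unlist(aligned$offsets, use.names = FALSE), grid,
                      sd = sd, n_events = max(1L, aligned$n_events))
  data.frame(time = grid, rate = rate)
}

#' Window statistic of aligned spikes
#'
#' @param aligned an [align_spikes()] object
#' @param window ms window (half-open), inside the alignment window; defaults
#'   to the full alignment window
#' @param stat one of `"probability"` (spikes per event), `"mean_rate"`
#'   (spikes / (events x width)), `"peak_rate"` / `"peak_time"` (from the
#'   kernel-smoothed mean profile restricted to the window), `"count"`
#' @param sd kernel SD for the peak statistics (ms)
#' @return scalar; `NA` with attribute `reason` when there are no events
#' @export
window_stat <- function(aligned, window = NULL,
                        stat = c("probability", "mean_rate", "peak_rate",
                                 "peak_time", "count"),
                        sd = 5) {
  stat <- match.arg(stat)
  window <- check_window(window %||% aligned$window)
  if (aligned$n_events == 0) {
    return(structure(NA_real_, reason = "no events"))
  }
  offs <- unlist(aligned$offsets, use.names = FALSE)
  cnt <- sum(offs >= window[1] & offs < window[2])
  width_s <- (window[2] - window[1]) / 1000
  switch(stat,
    count = cnt,
    probability = cnt / aligned$n_events,
    mean_rate = cnt / (aligned$n_events * width_s),
    peak_rate = ,
    peak_time = {
      grid <- seq(window[1], window[2] - 1, by = 1)
      rate <- kernel_rate(offs, grid, sd = sd, n_events = aligned$n_events)
      if (stat == "peak_rate") max(rate) else grid[which.max(rate)]
    }
  )
}

#' Population average of rate profiles
#'
#' Pointwise mean and SEM (sd / sqrt(n)) across cells on a common grid.
#'
#' @param profiles list of data.frames with columns `time` and `rate`, all on
#'   the same grid
#' @return data.frame of class `rate_profile` with `time`, `mean`, `sem`, `n`
#' @export
population_average <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  grid <- profiles[[1]]$time
  for (p in profiles) {
    if (length(p$time) != length(grid) || any(abs(p$time - grid) > 1e-9)) {
      stop("profiles must share a common time grid")
    }
  }
  m <- vapply(profiles, function(p) p$rate, numeric(length(grid)))
  m <- matrix(m, nrow = length(grid))
  n <- length(profiles)
  mu <- rowMeans(m)
  sem <- if (n == 1) {
    rep(0, length(grid))  # by convention, flagged below
  } else {
    apply(m, 1, stats::sd) / sqrt(n)
  }
  out <- data.frame(time = grid, mean = mu, sem = sem, n = n)
  attr(out, "single_cell") <- n == 1
  class(out) <- c("rate_profile", class(out))
  out
}
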