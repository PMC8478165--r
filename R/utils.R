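clip01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Named analysis windows
#'
#' The peri-event analysis windows used throughout the package, in ms relative
#' to the alignment event, half-open `[start, end)`. `early_post` and
#' `late_post` are taken from the primary-saccade offset, `precorrective` from
#' the corrective-saccade onset, `postcorrective` from the corrective-saccade
#' offset, `trial_onset_win` from the reappearance of the central fixation dot,
#' and the two `regress_*` windows from the primary-saccade offset.
#'
#' @return Named list of length-2 numeric vectors (ms).
#' @export
analysis_windows <- function() {
  list(
    early_post      = c(0, 100),
    late_post       = c(50, 250),
    precorrective   = c(-200, 0),
    postcorrective  = c(0, 100),
    trial_onset_win = c(150, 250),
    regress_early   = c(40, 80),
    regress_late    = c(100, 250)
  )
}

check_window <- function(window) {
  stopifnot(is.numeric(window), length(window) == 2L, window[2] > window[1])
  window
}

#' Peak velocity of a minimum-jerk movement
#'
#' Closed form `1.875 * amplitude / duration` for the minimum-jerk position
#' profile; used both by the session simulator and as an analytic oracle in
#' tests.
#'
#' @param amplitude movement amplitude (deg)
#' @param duration movement duration (ms)
#' @return peak velocity in deg/s
#' @export
minjerk_peak_velocity <- function(amplitude, duration) {
  1.875 * amplitude / (duration / 1000)
}

## minimum-jerk unit displacement at normalized time tau in [0,1]
minjerk_pos <- function(tau) {
  tau <- pmin(1, pmax(0, tau))
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}
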