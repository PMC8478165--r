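#' Bootstrap estimate of the CS peak time per duration bin
#'
#' For each bootstrap replicate, samples `n_cells` cells with replacement from
#' the cells that have at least `min_trials` events in every duration bin,
#' averages their kernel rate profiles per bin, and takes the time of the peak
#' within `search_window`. Reports the mean and 2.5/97.5 percentiles over
#' replicates.
#'
#' @param cells list of [align_spikes()] objects (one per cell, aligned to
#'   saccade onset, carrying a `duration` covariate)
#' @param duration_bins bin edges in ms (bins are `[e_i, e_{i+1})`)
#' @param n_cells cells drawn per replicate
#' @param min_trials minimum events per cell per bin for eligibility
#' @param reps bootstrap replicates
#' @param seed integer seed
#' @param search_window ms window in which the peak is searched
#' @param sd kernel SD (ms)
#' @return data.frame with `bin_lo`, `bin_hi`, `peak_time_mean`, `ci_lo`,
#'   `ci_hi`, `reps_used`, `n_eligible`
#' @export
bootstrap_peak_time <- function(cells, duration_bins, n_cells = 50,
                                min_trials = 10, reps = 1000, seed = 1L,
                                search_window = c(0, 200), sd = 5) {
  stopifnot(length(duration_bins) >= 2)
  search_window <- check_window(search_window)
  grid <- seq(search_window[1], search_window[2] - 1, by = 1)
  nb <- length(duration_bins) - 1L

  ## per cell x bin mean profiles (NULL when below min_trials)
  prof <- vector("list", length(cells))
  for (ci in seq_along(cells)) {
    al <- cells[[ci]]
    b <- findInterval(al$covariates$duration, duration_bins,
                      rightmost.closed = FALSE)
    prof[[ci]] <- lapply(seq_len(nb), function(k) {
      idx <- which(b == k)
      if (length(idx) < min_trials) return(NULL)
      aligned_profile(subset_aligned(al, idx), grid, sd = sd)$rate
    })
  }
  eligible <- which(vapply(prof, function(p) !any(vapply(p, is.null, logical(1))),
                           logical(1)))
  out <- list()
  set.seed(seed)
  for (k in seq_len(nb)) {
    if (!length(eligible)) {
      message("duration bin [", duration_bins[k], ",", duration_bins[k + 1],
              "): no eligible cells, skipped")
      next
    }
    mat <- vapply(eligible, function(ci) prof[[ci]][[k]], numeric(length(grid)))
    mat <- matrix(mat, nrow = length(grid))
    peaks <- numeric(reps)
    for (r in seq_len(reps)) {
      take <- sample.int(ncol(mat), n_cells, replace = TRUE)
      avg <- rowMeans(mat[, take, drop = FALSE])
      peaks[r] <- grid[which.max(avg)]
    }
    out[[length(out) + 1L]] <- data.frame(
      bin_lo = duration_bins[k], bin_hi = duration_bins[k + 1],
      peak_time_mean = mean(peaks),
      ci_lo = unname(stats::quantile(peaks, 0.025)),
      ci_hi = unname(stats::quantile(peaks, 0.975)),
      reps_used = reps, n_eligible = length(eligible)
    )
  }
  do.call(rbind, out)
}

#' Trough (modulation-onset) time from a rate profile
#'
#' Fits a second-order polynomial to the baseline period and a straight line to
#' the `linear_span` ms leading up to the peak; the earliest intersection of
#' the line with the extrapolated quadratic that lies between the end of the
#' baseline window and the peak is the trough time. Both fits are solved on the
#' continuous fitted functions (quadratic roots), not on grid samples.
#'
#' @param profile data.frame with `time` (ms, aligned to saccade onset) and
#'   `rate` (or `mean`) columns
#' @param peak_time time of the peak rate (ms)
#' @param baseline_window ms window of the baseline fit
#' @param linear_span ms span of the linear fit, ending at the peak
#' @return list with `trough_time` (NA with `diagnostic` when no admissible
#'   intersection exists), `baseline_coef`, `line_coef`
#' @export
estimate_trough <- function(profile, peak_time, baseline_window = c(-200, 0),
                            linear_span = 45) {
  rate <- profile$rate %||% profile$mean
  tt <- profile$time
  bi <- tt >= baseline_window[1] & tt < baseline_window[2]
  if (sum(bi) < 3) stop("baseline window not populated")
  qf <- stats::lm(rate[bi] ~ tt[bi] + I(tt[bi]^2))
  q <- unname(stats::coef(qf))            # c0 + c1 t + c2 t^2
  li <- tt >= peak_time - linear_span & tt <= peak_time
  if (sum(li) < 2) stop("linear span not populated")
  lf <- stats::lm(rate[li] ~ tt[li])
  l <- unname(stats::coef(lf))            # b0 + b1 t
  ## intersection: q2 t^2 + (q1 - l1) t + (q0 - l0) = 0
  a <- q[3]; b <- q[2] - l[2]; cc <- q[1] - l[1]
  roots <- if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0)
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  adm <- roots[roots > baseline_window[2] & roots < peak_time]
  if (!length(adm)) {
    return(list(trough_time = NA_real_,
                diagnostic = "no intersection between baseline end and peak",
                baseline_coef = q, line_coef = l))
  }
  list(trough_time = min(adm), diagnostic = NULL,
       baseline_coef = q, line_coef = l)
}

#' Bootstrap estimate of the trough time per duration bin
#'
#' For each replicate, samples `n_trials` trials with replacement from the
#' bin's pool, computes the mean kernel rate, finds the peak in
#' `search_window`, and runs [estimate_trough()]. Reports the mean trough time
#' and its 95% CI over replicates.
#'
#' @param trials_by_bin named list; each element is a list of per-trial spike
#'   offset vectors (ms, aligned to saccade onset)
#' @param n_trials trials drawn per replicate
#' @param reps bootstrap replicates
#' @param seed integer seed
#' @param grid profile grid (ms, must cover baseline and search windows)
#' @param search_window ms window for the peak
#' @param baseline_window,linear_span passed to [estimate_trough()]
#' @param sd kernel SD (ms)
#' @return data.frame with one row per bin: `bin`, `trough_mean`, `ci_lo`,
#'   `ci_hi`, `reps_used`, `n_failed`
#' @export
bootstrap_trough <- function(trials_by_bin, n_trials = 1000, reps = 1000,
                             seed = 1L, grid = seq(-250, 249, by = 1),
                             search_window = c(0, 200),
                             baseline_window = c(-200, 0), linear_span = 45,
                             sd = 5) {
  set.seed(seed)
  out <- list()
  si <- grid >= search_window[1] & grid < search_window[2]
  for (bn in names(trials_by_bin)) {
    pool <- trials_by_bin[[bn]]
    if (!length(pool)) {
      message("bin ", bn, ": no trials, skipped")
      next
    }
    troughs <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      take <- sample.int(length(pool), n_trials, replace = TRUE)
      offs <- unlist(pool[take], use.names = FALSE)
      rate <- kernel_rate(offs, grid, sd = sd, n_events = n_trials)
      pk <- grid[si][which.max(rate[si])]
      est <- estimate_trough(data.frame(time = grid, rate = rate), pk,
                             baseline_window, linear_span)
      troughs[r] <- est$trough_time
    }
    okv <- troughs[!is.na(troughs)]
    out[[length(out) + 1L]] <- data.frame(
      bin = bn,
      trough_mean = if (length(okv)) mean(okv) else NA_real_,
      ci_lo = if (length(okv)) unname(stats::quantile(okv, 0.025)) else NA_real_,
      ci_hi = if (length(okv)) unname(stats::quantile(okv, 0.975)) else NA_real_,
      reps_used = reps, n_failed = sum(is.na(troughs))
    )
  }
  do.call(rbind, out)
}
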