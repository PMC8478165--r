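#' Running percent change in CS duration for one cell
#'
#' Sliding 50-ms bins (stepped at `step` ms) over CS offsets relative to the
#' alignment events; each bin's mean CS duration is expressed as a percent
#' change relative to the cell's overall mean CS duration. Empty bins are
#' missing.
#'
#' @param cs data.frame with `time_ms` and `duration_ms`
#' @param event_times alignment times (ms, session clock)
#' @param window ms span of the profile relative to the events
#' @param bin bin width (ms)
#' @param step bin step (ms); `step = bin` gives non-overlapping bins
#' @return data.frame with `time` (bin centers), `pct_change`, `n_cs`; the
#'   cell mean duration is attached as attribute `cell_mean`
#' @export
percent_change_series <- function(cs, event_times, window = c(-300, 500),
                                  bin = 50, step = 10) {
  if (!nrow(cs)) stop("cell has no CSs")
  cell_mean <- mean(cs$duration_ms)
  centers <- seq(window[1] + bin / 2, window[2] - bin / 2, by = step)
  ## all CS offsets relative to every event (a CS near two events contributes
  ## to both alignments); binary search over the sorted CS times
  ord <- order(cs$time_ms)
  cs_t <- cs$time_ms[ord]; cs_d <- cs$duration_ms[ord]
  i_lo <- findInterval(event_times + window[1], cs_t, left.open = TRUE) + 1L
  i_hi <- findInterval(event_times + window[2], cs_t, left.open = TRUE)
  ## left.open counts cs_t < x, so [i_lo, i_hi] covers cs_t in [x1, x2); shave
  ## exact right-edge hits
  offs <- numeric(0); durs <- numeric(0)
  for (k in seq_along(event_times)) {
    if (i_hi[k] < i_lo[k]) next
    idx <- i_lo[k]:i_hi[k]
    sel <- cs_t[idx] - event_times[k]
    keep <- sel < window[2]
    offs <- c(offs, sel[keep]); durs <- c(durs, cs_d[idx][keep])
  }
  pct <- rep(NA_real_, length(centers)); ncs <- integer(length(centers))
  for (i in seq_along(centers)) {
    inb <- offs >= centers[i] - bin / 2 & offs < centers[i] + bin / 2
    ncs[i] <- sum(inb)
    if (ncs[i] > 0) {
      pct[i] <- 100 * (mean(durs[inb]) - cell_mean) / cell_mean
    }
  }
  structure(data.frame(time = centers, pct_change = pct, n_cs = ncs),
            cell_mean = cell_mean)
}

#' Population CS-duration percent-change profile
#'
#' Pointwise mean and SEM of per-cell percent-change series; missing (empty)
#' bins are excluded from the mean cell-wise.
#'
#' @param series_list list of [percent_change_series()] outputs on a common
#'   grid
#' @return data.frame with `time`, `mean`, `sem`, `n`
#' @export
population_duration_profile <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  grid <- series_list[[1]]$time
  m <- vapply(series_list, function(s) {
    if (length(s$time) != length(grid) || any(abs(s$time - grid) > 1e-9)) {
      stop("series must share a common grid")
    }
    s$pct_change
  }, numeric(length(grid)))
  m <- matrix(m, nrow = length(grid))
  n_ok <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  sem <- apply(m, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2) return(NA_real_)
    stats::sd(r) / sqrt(length(r))
  })
  mu[n_ok == 0] <- NA_real_
  data.frame(time = grid, mean = mu, sem = sem, n = n_ok)
}

#' Threshold-crossing modulation epochs
#'
#' The baseline mean is computed over the profile bins inside `baseline`.
#' The threshold SD is the across-cell SEM of the population profile pooled
#' over the baseline bins when the profile carries a `sem` column (the SEM is
#' the sampling SD of the population mean, so `mean +/- k*SEM` is a calibrated
#' k-sigma rule); for a bare profile it falls back to the SD of the baseline
#' bin values. Decrease (below mean - k*SD) and increase (above mean + k*SD)
#' epochs are contiguous crossing runs lasting at least `min_run` ms; the
#' default (bin width + step) demands support from more than one independent
#' 50-ms data window, since every CS influences all sliding bins that cover it.
#'
#' @param profile data.frame with `time` and `mean` (or `pct_change`) columns,
#'   optionally `sem`
#' @param baseline ms window of the baseline
#' @param k threshold multiplier
#' @param min_run minimum epoch length (ms)
#' @return list with `baseline_mean`, `baseline_sd`, `threshold` (lo, hi), and
#'   `epochs` (data.frame: kind, start, end), empty when nothing crosses
#' @export
detect_epochs <- function(profile, baseline = c(-200, -100), k = 3,
                          min_run = 60) {
  y <- profile$mean %||% profile$pct_change
  tt <- profile$time
  bi <- tt >= baseline[1] & tt < baseline[2] & !is.na(y)
  if (!any(bi)) stop("baseline window empty")
  m <- mean(y[bi])
  s <- if (!is.null(profile$sem) && all(is.finite(profile$sem[bi]))) {
    sqrt(mean(profile$sem[bi]^2))
  } else {
    stats::sd(y[bi])
  }
  if (is.na(s)) stop("baseline needs at least 2 populated bins")
  lo <- m - k * s; hi <- m + k * s
  step <- if (length(tt) > 1) tt[2] - tt[1] else min_run
  find_runs <- function(flag, kind) {
    flag[is.na(flag)] <- FALSE
    r <- rle(flag)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values & (r$lengths * step >= min_run)
    if (!any(keep)) return(NULL)
    data.frame(kind = kind, start = tt[starts[keep]], end = tt[ends[keep]])
  }
  epochs <- rbind(find_runs(y < lo, "decrease"), find_runs(y > hi, "increase"))
  if (is.null(epochs)) {
    epochs <- data.frame(kind = character(0), start = numeric(0),
                         end = numeric(0))
  }
  list(baseline_mean = m, baseline_sd = s, threshold = c(lo = lo, hi = hi),
       epochs = epochs)
}

#' CS-duration tuning against a saccade covariate
#'
#' Pools CSs across cells (each CS's duration expressed as percent change
#' relative to its own cell's mean), assigns each CS to the event whose window
#' it falls in, bins by the event covariate, and fits a line per direction
#' class.
#'
#' @param cells list of per-cell lists with elements `cs` (data.frame
#'   `time_ms`, `duration_ms`) and `events` (labeled saccade events)
#' @param variable event covariate (`"amplitude"` or `"signed_error"`)
#' @param window ms window relative to the alignment time in which CSs are
#'   attributed to an event
#' @param alignment `"onset"` or `"offset"` of the events
#' @param event_type `"primary"` or `"corrective"`
#' @param bin_size covariate bin width
#' @param pd per-cell preferred direction used to split the direction classes
#'   (sign of the covariate direction for amplitude, sign of the error for
#'   signed_error), recycled
#' @param min_per_bin minimum CSs per bin
#' @return list with one `tuning`-style element per direction class (`pd` and
#'   `anti`), each holding `table` and `fit`
#' @export
duration_tuning <- function(cells, variable = c("amplitude", "signed_error"),
                            window, alignment = c("onset", "offset"),
                            event_type = c("primary", "corrective"),
                            bin_size = 1, pd = 1, min_per_bin = 10) {
  variable <- match.arg(variable)
  alignment <- match.arg(alignment)
  event_type <- match.arg(event_type)
  window <- check_window(window)
  pd <- rep_len(pd, length(cells))
  rows <- list()
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    if (!nrow(cell$cs)) next
    cm <- mean(cell$cs$duration_ms)
    ev <- cell$events[cell$events$type == event_type, , drop = FALSE]
    if (!nrow(ev)) next
    tref <- if (alignment == "onset") ev$onset else ev$offset
    x <- ev[[variable]]
    if (variable == "signed_error") x <- x * pd[ci]
    dirclass <- if (variable == "signed_error") {
      ifelse(x >= 0, "pd", "anti")
    } else {
      ifelse(ev$direction == pd[ci], "pd", "anti")
    }
    for (k in seq_len(nrow(ev))) {
      sel <- cell$cs$time_ms - tref[k]
      inw <- sel >= window[1] & sel < window[2]
      if (!any(inw)) next
      rows[[length(rows) + 1L]] <- data.frame(
        x = x[k], dirclass = dirclass[k],
        pct = 100 * (cell$cs$duration_ms[inw] - cm) / cm
      )
    }
  }
  dat <- do.call(rbind, rows)
  if (is.null(dat)) stop("no CSs fell in the window")
  out <- list()
  for (dc in c("pd", "anti")) {
    d <- dat[dat$dirclass == dc, , drop = FALSE]
    if (!nrow(d)) next
    edges <- seq(floor(min(d$x) / bin_size) * bin_size,
                 ceiling(max(d$x) / bin_size) * bin_size, by = bin_size)
    if (length(edges) < 3) next
    centers <- edges[-length(edges)] + bin_size / 2
    b <- findInterval(d$x, edges, rightmost.closed = FALSE)
    tab <- do.call(rbind, lapply(seq_along(centers), function(i) {
      idx <- which(b == i)
      if (length(idx) < min_per_bin) return(NULL)
      data.frame(bin_center = centers[i], response = mean(d$pct[idx]),
                 dispersion = stats::sd(d$pct[idx]) / sqrt(length(idx)),
                 n = length(idx))
    }))
    if (is.null(tab) || nrow(tab) < 2) next
    out[[dc]] <- list(table = tab, fit = linfit(tab$bin_center, tab$response))
  }
  if (!length(out)) stop("no direction class had 2 populated bins")
  out
}
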