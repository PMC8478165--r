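#' Error-magnitude tuning
#'
#' Bins the signed retinal error (positive toward the preferred error
#' direction) and computes the mean CS rate per bin in the chosen window, with
#' a linear fit across the signed bins.
#'
#' @param aligned an [align_spikes()] object with a `signed_error` covariate
#'   (aligned to corrective onset for the precorrective window or to primary
#'   offset for the late postsaccadic window)
#' @param pd_error preferred error direction (+1 / -1)
#' @param window ms window; default is the aligned object's own window
#' @param bin_size error bin width (deg)
#' @param range signed-error range (deg)
#' @param min_per_bin minimum events per bin
#' @return a `tuning_result` (see [binned_tuning()])
#' @export
error_magnitude_tuning <- function(aligned, pd_error = 1, window = NULL,
                                   bin_size = 0.5, range = c(-2, 2),
                                   min_per_bin = 10) {
  al <- aligned
  al$covariates$signed_error_pd <- al$covariates$signed_error * pd_error
  res <- binned_tuning(al, "signed_error_pd", bin_size, range = range,
                       response = "mean_rate", window = window,
                       min_per_bin = min_per_bin)
  if (nrow(res$table) < 3) stop("fewer than 3 populated error bins; fit refused")
  res
}

#' Pool saccades with comparable error vectors
#'
#' Groups events by signed-error bin regardless of saccade direction, type, or
#' amplitude, and reports a Kruskal-Wallis test of amplitude balance across the
#' groups (groups should be amplitude-indistinguishable if the pooling is to
#' isolate the error influence).
#'
#' @param events labeled saccade events carrying `signed_error` and `amplitude`
#' @param pd_error preferred error direction (+1 / -1)
#' @param edges signed-error bin edges (deg, toward `pd_error` positive)
#' @return list with `groups` (list of row-index vectors keyed by bin label),
#'   `table` (per-bin n, mean amplitude, mean signed error), and `balance`
#'   (Kruskal-Wallis statistic, df, p; NULL when < 2 groups)
#' @export
pool_comparable_errors <- function(events, pd_error = 1,
                                   edges = seq(-2, 2, by = 0.5)) {
  e <- events$signed_error * pd_error
  ok <- which(is.finite(e))
  bin <- findInterval(e[ok], edges, rightmost.closed = FALSE)
  centers <- edges[-length(edges)] + diff(edges) / 2
  groups <- list(); tab <- list()
  for (b in seq_along(centers)) {
    idx <- ok[bin == b]
    if (!length(idx)) next
    lab <- sprintf("%+.2f", centers[b])
    groups[[lab]] <- idx
    tab[[lab]] <- data.frame(bin_center = centers[b], n = length(idx),
                             mean_amplitude = mean(events$amplitude[idx]),
                             mean_signed_error = mean(e[idx]))
  }
  tab <- do.call(rbind, tab)
  balance <- NULL
  if (length(groups) >= 2) {
    amp <- unlist(lapply(groups, function(i) events$amplitude[i]))
    g <- factor(rep(names(groups), lengths(groups)))
    kw <- stats::kruskal.test(amp, g)
    balance <- list(statistic = unname(kw$statistic),
                    df = unname(kw$parameter), p_value = kw$p.value)
  } else {
    message("single populated error bin; balance test refused")
  }
  list(groups = groups, table = tab, balance = balance)
}

#' Pool similarly sized saccades with opposite errors
#'
#' Within each amplitude bin, subsamples (randomly, without replacement,
#' seeded) the events so that positive- and negative-error counts are equal,
#' canceling the error influence by construction. Bins with only one error
#' sign are excluded.
#'
#' @param events labeled saccade events with `amplitude` and `signed_error`
#' @param pd_error preferred error direction used to sign the errors
#' @param amplitude_bin_size bin width (deg)
#' @param range amplitude range; defaults to the data range
#' @param seed integer seed for the balancing subsample
#' @return list with `groups` (row indices per amplitude bin) and `table`
#'   (per-bin n, mean amplitude, mean signed error, mean error sign)
#' @export
pool_mixed_errors <- function(events, pd_error = 1, amplitude_bin_size = 0.5,
                              range = NULL, seed = 1L) {
  e <- events$signed_error * pd_error
  ok <- which(is.finite(e) & e != 0)
  a <- events$amplitude
  if (is.null(range)) {
    range <- c(floor(min(a[ok]) / amplitude_bin_size),
               ceiling(max(a[ok]) / amplitude_bin_size)) * amplitude_bin_size
  }
  edges <- seq(range[1], range[2], by = amplitude_bin_size)
  centers <- edges[-length(edges)] + amplitude_bin_size / 2
  bin <- findInterval(a[ok], edges, rightmost.closed = FALSE)
  set.seed(seed)
  groups <- list(); tab <- list()
  for (b in seq_along(centers)) {
    idx <- ok[bin == b]
    pos <- idx[e[idx] > 0]; neg <- idx[e[idx] < 0]
    m <- min(length(pos), length(neg))
    if (m == 0) {
      if (length(idx)) message("amplitude bin ", centers[b],
                               ": one error sign only, excluded")
      next
    }
    take <- c(if (length(pos) > m) sample(pos, m) else pos,
              if (length(neg) > m) sample(neg, m) else neg)
    lab <- sprintf("%.2f", centers[b])
    groups[[lab]] <- sort(take)
    tab[[lab]] <- data.frame(bin_center = centers[b], n = length(take),
                             mean_amplitude = mean(events$amplitude[take]),
                             mean_signed_error = mean(e[take]),
                             mean_error_sign = mean(sign(e[take])))
  }
  list(groups = groups, table = do.call(rbind, tab))
}

#' Peak- and mean-rate regressions over pooled groups
#'
#' For each pooled group, computes the peak and the mean CS rate in the window
#' from the group's kernel-smoothed profile, then fits both statistics against
#' the group bin centers. The peak rate captures the saccade-related transient;
#' the mean rate registers the tonic, error-related activity.
#'
#' @param aligned an [align_spikes()] object whose event rows the group indices
#'   refer to
#' @param pooling output of [pool_mixed_errors()] or [pool_comparable_errors()]
#' @param window ms window (default: the late postsaccadic window)
#' @return list with `table` (bin_center, peak_rate, mean_rate, n) and two fits
#'   `peak_fit`, `mean_fit` (slope, intercept, r_squared, p_value)
#' @export
peak_and_mean_regression <- function(aligned, pooling,
                                     window = analysis_windows()$late_post) {
  window <- check_window(window)
  if (length(pooling$groups) < 3) stop("need at least 3 pooled groups")
  rows <- lapply(names(pooling$groups), function(lab) {
    idx <- pooling$groups[[lab]]
    sub <- subset_aligned(aligned, idx)
    data.frame(bin_center = as.numeric(lab),
               peak_rate = window_stat(sub, window, "peak_rate"),
               mean_rate = window_stat(sub, window, "mean_rate"),
               n = length(idx))
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       peak_fit = linfit(tab$bin_center, tab$peak_rate),
       mean_fit = linfit(tab$bin_center, tab$mean_rate))
}

#' Per-cell multiple regression of CS counts on amplitude and error
#'
#' Ordinary least squares, per cell, of the CS count in the window on saccade
#' amplitude (A) and signed error (E, positive toward the cell's preferred
#' error direction): `Y = l*A + m*E + c`. Cells with fewer than `min_events`
#' saccades or a rank-deficient design are skipped with a flag.
#'
#' @param cells list of [align_spikes()] objects (aligned to primary-saccade
#'   offset, covariates `amplitude` and `signed_error`)
#' @param pd_error per-cell preferred error directions (+1/-1), recycled
#' @param window ms counting window (40-80 or 100-250 ms from offset)
#' @param min_events per-cell inclusion threshold
#' @return list with `fits` (data.frame: cell, l, m, c, p_l, p_m, r_squared,
#'   n), `skipped` (integer indices), and `population` (means of l, m, c)
#' @export
per_pc_multiple_regression <- function(cells, pd_error = 1,
                                       window = analysis_windows()$regress_late,
                                       min_events = 30) {
  window <- check_window(window)
  pd_error <- rep_len(pd_error, length(cells))
  rows <- list(); skipped <- integer(0)
  for (ci in seq_along(cells)) {
    al <- cells[[ci]]
    A <- al$covariates$amplitude
    E <- al$covariates$signed_error * pd_error[ci]
    Y <- vapply(al$offsets, function(o)
      sum(o >= window[1] & o < window[2]), numeric(1))
    keep <- is.finite(A) & is.finite(E)
    A <- A[keep]; E <- E[keep]; Y <- Y[keep]
    if (length(Y) < min_events || stats::sd(A) == 0 || stats::sd(E) == 0 ||
        abs(stats::cor(A, E)) > 0.999) {
      skipped <- c(skipped, ci)
      next
    }
    fit <- stats::lm(Y ~ A + E)
    sm <- summary(fit)
    co <- stats::coef(sm)
    rows[[length(rows) + 1L]] <- data.frame(
      cell = ci,
      l = unname(co["A", "Estimate"]), m = unname(co["E", "Estimate"]),
      c = unname(co["(Intercept)", "Estimate"]),
      p_l = unname(co["A", "Pr(>|t|)"]), p_m = unname(co["E", "Pr(>|t|)"]),
      r_squared = sm$r.squared, n = length(Y)
    )
  }
  fits <- do.call(rbind, rows)
  population <- if (!is.null(fits)) {
    c(l = mean(fits$l), m = mean(fits$m), c = mean(fits$c))
  } else NULL
  list(fits = fits, skipped = skipped, population = population,
       window = window)
}

#' Predicted CS-count surface from population regression coefficients
#'
#' @param population named vector with `l`, `m`, `c`
#' @param amplitudes,errors grid values (deg)
#' @return matrix of predicted counts, amplitudes in rows, errors in columns
#' @export
predicted_count_surface <- function(population,
                                    amplitudes = seq(13, 17, by = 0.25),
                                    errors = seq(-2, 2, by = 0.25)) {
  outer(amplitudes, errors,
        function(a, e) population["l"] * a + population["m"] * e +
          population["c"])
}
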