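#' Assign a preferred direction
#'
#' For `kind = "primary"` the statistic is the probability of CS firing in the
#' early postsaccadic window (0-100 ms from saccade offset); for
#' `kind = "corrective"` the mean rate in the postcorrective window (0-100 ms
#' from corrective offset); for `kind = "error"` the mean rate in the
#' precorrective window (-200-0 ms from corrective onset), with direction taken
#' from the sign of the retinal error. The direction with the higher statistic
#' wins; an exact tie yields +1 with `tie_flag` set.
#'
#' @param aligned an [align_spikes()] object aligned to the kind-appropriate
#'   event (primary offset / corrective offset / corrective onset)
#' @param kind `"primary"`, `"corrective"`, or `"error"`
#' @param window override the kind-specific window (ms)
#' @return list with `pd`, `anti`, `stat_used`, `window`, `by_direction`,
#'   `tie_flag`
#' @export
assign_pd <- function(aligned, kind = c("primary", "corrective", "error"),
                      window = NULL) {
  kind <- match.arg(kind)
  wins <- analysis_windows()
  spec <- switch(kind,
    primary = list(window = wins$early_post, stat = "probability",
                   dirvar = "direction"),
    corrective = list(window = wins$postcorrective, stat = "mean_rate",
                      dirvar = "direction"),
    error = list(window = wins$precorrective, stat = "mean_rate",
                 dirvar = "signed_error")
  )
  window <- check_window(window %||% spec$window)
  dirs <- if (spec$dirvar == "direction") aligned$covariates$direction
          else sign(aligned$covariates$signed_error)
  vals <- vapply(c(right = 1, left = -1), function(d) {
    idx <- which(dirs == d)
    if (!length(idx)) return(NA_real_)
    window_stat(subset_aligned(aligned, idx), window, spec$stat)
  }, numeric(1))
  if (anyNA(vals)) {
    return(structure(list(pd = NA, anti = NA, stat_used = spec$stat,
                          window = window, by_direction = vals,
                          tie_flag = FALSE, refused = TRUE,
                          reason = "a direction has zero events"),
                     class = "pd_assignment"))
  }
  tie <- vals["right"] == vals["left"]
  pd <- if (tie) 1 else if (vals["right"] > vals["left"]) 1 else -1
  structure(list(pd = pd, anti = -pd, stat_used = spec$stat, window = window,
                 by_direction = vals, tie_flag = tie, refused = FALSE),
            class = "pd_assignment")
}

#' @export
print.pd_assignment <- function(x, ...) {
  if (isTRUE(x$refused)) {
    cat("<pd_assignment> refused:", x$reason, "\n")
  } else {
    cat("<pd_assignment> pd=", x$pd, " (", x$stat_used, " right=",
        signif(x$by_direction["right"], 3), ", left=",
        signif(x$by_direction["left"], 3),
        if (x$tie_flag) ", TIE" else "", ")\n", sep = "")
  }
  invisible(x)
}

#' Binned tuning curve with a linear fit
#'
#' Sorts events into bins of a covariate, computes a window statistic per bin,
#' and fits an ordinary least-squares line through the bin centers. Bins with
#' fewer than `min_per_bin` events are dropped.
#'
#' @param aligned an [align_spikes()] object
#' @param variable covariate name (`"amplitude"`, `"duration"`,
#'   `"peak_velocity"`, `"signed_error"`, `"arrival_time"`)
#' @param bin_size bin width in the covariate's unit
#' @param range length-2 covariate range; defaults to the data range
#' @param response window statistic per bin (see [window_stat()])
#' @param window ms window for the response
#' @param min_per_bin minimum events per retained bin
#' @return object of class `tuning_result`: list with `table` (bin_center,
#'   response, dispersion, n) and `fit` (slope, intercept, r_squared, p_value)
#' @export
binned_tuning <- function(aligned, variable, bin_size, range = NULL,
                          response = c("peak_rate", "mean_rate", "probability",
                                       "peak_time"),
                          window = NULL, min_per_bin = 10) {
  response <- match.arg(response)
  x <- aligned$covariates[[variable]]
  if (is.null(x)) stop("unknown covariate: ", variable)
  ok <- which(is.finite(x))
  if (is.null(range)) {
    range <- c(floor(min(x[ok]) / bin_size), ceiling(max(x[ok]) / bin_size)) *
      bin_size
  }
  edges <- seq(range[1], range[2], by = bin_size)
  if (length(edges) < 3) stop("need at least 2 bins")
  centers <- edges[-length(edges)] + bin_size / 2
  bin <- findInterval(x, edges, rightmost.closed = FALSE)
  rows <- lapply(seq_along(centers), function(b) {
    idx <- intersect(which(bin == b), ok)
    if (length(idx) < min_per_bin) return(NULL)
    sub <- subset_aligned(aligned, idx)
    resp <- window_stat(sub, window, response)
    disp <- dispersion_stat(sub, window, response)
    data.frame(bin_center = centers[b], response = resp, dispersion = disp,
               n = length(idx))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 2) {
    stop("fewer than 2 populated bins; fit refused")
  }
  fit <- linfit(tab$bin_center, tab$response)
  structure(list(table = tab, fit = fit, variable = variable,
                 response = response, window = window, bin_size = bin_size),
            class = "tuning_result")
}

## SEM-style dispersion matching the response statistic
dispersion_stat <- function(sub, window, response) {
  window <- check_window(window %||% sub$window)
  width_s <- (window[2] - window[1]) / 1000
  per_event <- vapply(sub$offsets, function(o)
    sum(o >= window[1] & o < window[2]), numeric(1))
  n <- length(per_event)
  if (n < 2) return(NA_real_)
  se_count <- stats::sd(per_event) / sqrt(n)
  switch(response,
         probability = se_count,
         mean_rate = se_count / width_s,
         peak_rate = se_count / width_s,   # proxy; peak SEM needs a bootstrap
         peak_time = NA_real_)
}

## OLS line with R^2 and slope p-value
linfit <- function(x, y) {
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- stats::coef(sm)
  list(slope = unname(co["x", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r_squared = sm$r.squared,
       p_value = if (nrow(co) > 1) unname(co["x", "Pr(>|t|)"]) else NA_real_,
       slope_se = unname(co["x", "Std. Error"]),
       df = fit$df.residual)
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("<tuning_result> ", x$response, " vs ", x$variable, ": slope=",
      signif(x$fit$slope, 3), ", R2=", signif(x$fit$r_squared, 3),
      ", p=", signif(x$fit$p_value, 3), " (", nrow(x$table), " bins)\n",
      sep = "")
  invisible(x)
}
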