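## one-tailed paired Wilcoxon signed-rank p: group "hi" hypothesized to have
## higher rates. Groups are truncated to equal size and paired in event order.
paired_signed_rank <- function(hi, lo) {
  n <- min(length(hi), length(lo))
  if (n < 1) return(NA_real_)
  suppressWarnings(
    stats::wilcox.test(hi[seq_len(n)], lo[seq_len(n)], paired = TRUE,
                       alternative = "greater")$p.value
  )
}

encoding_result <- function(cell, parameter, window_label, p, flag,
                            reason = NA_character_) {
  data.frame(cell = cell, parameter = parameter, window = window_label,
             p_value = p, flag = flag, reason = reason,
             stringsAsFactors = FALSE)
}

#' Median-split encoding test
#'
#' Splits the events at the median of a task parameter (ties go to the lower
#' group), computes per-event CS rates in the window, pairs the two groups in
#' event order after truncation to equal size, and runs a one-tailed Wilcoxon
#' signed-rank test with the upper-median group hypothesized to fire more.
#' Cells with fewer than `min_cs` CSs in the window are not compared.
#'
#' @param values per-event parameter values
#' @param counts per-event CS counts in the window
#' @param width_s window width in seconds (rates = counts / width)
#' @param parameter parameter label
#' @param cell cell id
#' @param window_label window label for the result row
#' @param min_cs minimum total CSs in the window
#' @param alpha significance level
#' @return one-row data.frame: cell, parameter, window, p_value, flag, reason
#' @export
median_split_test <- function(values, counts, width_s, parameter = "param",
                              cell = 1L, window_label = "", min_cs = 10,
                              alpha = 0.05) {
  stopifnot(length(values) == length(counts))
  if (sum(counts) < min_cs) {
    return(encoding_result(cell, parameter, window_label, NA_real_,
                           "not_compared", "fewer than min_cs CSs in window"))
  }
  med <- stats::median(values)
  lo_idx <- which(values <= med)
  hi_idx <- which(values > med)
  if (!length(lo_idx) || !length(hi_idx)) {
    return(encoding_result(cell, parameter, window_label, NA_real_,
                           "not_compared", "degenerate median split"))
  }
  rates <- counts / width_s
  p <- paired_signed_rank(rates[hi_idx], rates[lo_idx])
  if (is.na(p)) {
    return(encoding_result(cell, parameter, window_label, NA_real_,
                           "not_compared", "test undefined"))
  }
  encoding_result(cell, parameter, window_label, p,
                  if (p < alpha) "significant" else "nonsignificant")
}

#' Direction encoding test
#'
#' Compares per-event CS rates between the two movement directions with the
#' same paired one-tailed signed-rank scheme as [median_split_test()]; the
#' preferred direction is hypothesized to fire more (note the circularity when
#' the preferred direction was chosen from the same data).
#'
#' @param directions per-event directions (+1 / -1)
#' @param counts per-event CS counts in the window
#' @param width_s window width (s)
#' @param pd the preferred direction (+1 / -1)
#' @param parameter,cell,window_label,min_cs,alpha see [median_split_test()]
#' @return one-row data.frame as in [median_split_test()]
#' @export
direction_test <- function(directions, counts, width_s, pd = 1,
                           parameter = "direction", cell = 1L,
                           window_label = "", min_cs = 10, alpha = 0.05) {
  stopifnot(length(directions) == length(counts))
  if (sum(counts) < min_cs) {
    return(encoding_result(cell, parameter, window_label, NA_real_,
                           "not_compared", "fewer than min_cs CSs in window"))
  }
  hi_idx <- which(directions == pd)
  lo_idx <- which(directions == -pd)
  if (!length(hi_idx) || !length(lo_idx)) {
    return(encoding_result(cell, parameter, window_label, NA_real_,
                           "not_compared", "a direction has no events"))
  }
  rates <- counts / width_s
  p <- paired_signed_rank(rates[hi_idx], rates[lo_idx])
  if (is.na(p)) {
    return(encoding_result(cell, parameter, window_label, NA_real_,
                           "not_compared", "test undefined"))
  }
  encoding_result(cell, parameter, window_label, p,
                  if (p < alpha) "significant" else "nonsignificant")
}

#' Build the cell x parameter encoding matrix
#'
#' @param results data.frame of stacked test rows (from [median_split_test()] /
#'   [direction_test()]); one row per (cell, parameter)
#' @return list with `binary` (1 = significant, 0 = nonsignificant, NA = not
#'   compared), `p_values`, both cells x parameters
#' @export
build_encoding_matrix <- function(results) {
  if (anyDuplicated(results[, c("cell", "parameter")])) {
    stop("duplicate (cell, parameter) rows")
  }
  cells <- sort(unique(results$cell))
  params <- unique(results$parameter)
  bin <- matrix(NA_real_, length(cells), length(params),
                dimnames = list(cells, params))
  pv <- bin
  for (r in seq_len(nrow(results))) {
    i <- match(results$cell[r], cells)
    j <- match(results$parameter[r], params)
    pv[i, j] <- results$p_value[r]
    bin[i, j] <- switch(results$flag[r],
                        significant = 1, nonsignificant = 0, NA_real_)
  }
  list(binary = bin, p_values = pv)
}

#' Cross-correlation between encoded parameters
#'
#' Pearson correlation between the binary columns of the encoding matrix,
#' computed pairwise over the cells compared for both parameters. Zero-variance
#' columns give NA entries.
#'
#' @param binary cells x parameters binary matrix (NA = not compared)
#' @return symmetric correlation matrix with unit diagonal
#' @export
cross_correlate <- function(binary) {
  p <- ncol(binary)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(binary),
                                                colnames(binary)))
  diag(out) <- 1
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (j <= i) next
      ok <- stats::complete.cases(binary[, c(i, j)])
      if (sum(ok) < 2) next
      x <- binary[ok, i]; y <- binary[ok, j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      out[i, j] <- out[j, i] <- stats::cor(x, y)
    }
  }
  out
}

#' Run the full encoding battery for one cell
#'
#' Computes the seven per-cell tests of the encoding matrix: trial onset
#' (median split on return-saccade arrival time, 150-250 ms from trial onset),
#' primary amplitude and direction (0-100 ms from primary offset), corrective
#' amplitude and direction (0-100 ms from corrective offset), error magnitude
#' and direction (50-250 ms from primary offset).
#'
#' @param cs_times CS times (ms)
#' @param events labeled saccade events
#' @param trials trial table
#' @param cell cell id
#' @param alpha significance level
#' @return data.frame of seven test rows
#' @export
encode_cell <- function(cs_times, events, trials, cell = 1L, alpha = 0.05) {
  wins <- analysis_windows()
  res <- list()
  count_in <- function(al) vapply(al$offsets, length, numeric(1))

  al <- align_spikes(cs_times, events, "trial_onset", wins$trial_onset_win,
                     trials = trials)
  res$trial_onset <- median_split_test(
    ifelse(is.na(al$covariates$arrival_time), 0, al$covariates$arrival_time),
    count_in(al), 0.1, "trial_onset", cell, "trial_onset_win", alpha = alpha)

  al <- align_spikes(cs_times, events, "saccade_offset", wins$early_post)
  cnt <- count_in(al)
  res$ps_amplitude <- median_split_test(al$covariates$amplitude, cnt, 0.1,
                                        "ps_amplitude", cell, "early_post",
                                        alpha = alpha)
  pd <- assign_pd(al, "primary")
  res$ps_direction <- direction_test(al$covariates$direction, cnt, 0.1,
                                     pd = if (isTRUE(pd$refused)) 1 else pd$pd,
                                     parameter = "ps_direction", cell = cell,
                                     window_label = "early_post", alpha = alpha)

  al <- align_spikes(cs_times, events, "corrective_offset", wins$postcorrective)
  cnt <- count_in(al)
  res$corr_amplitude <- median_split_test(al$covariates$amplitude, cnt, 0.1,
                                          "corr_amplitude", cell,
                                          "postcorrective", alpha = alpha)
  pdc <- assign_pd(al, "corrective")
  res$corr_direction <- direction_test(al$covariates$direction, cnt, 0.1,
                                       pd = if (isTRUE(pdc$refused)) 1 else pdc$pd,
                                       parameter = "corr_direction",
                                       cell = cell,
                                       window_label = "postcorrective",
                                       alpha = alpha)

  al <- align_spikes(cs_times, events, "saccade_offset", wins$late_post)
  cnt <- count_in(al)
  res$error_magnitude <- median_split_test(abs(al$covariates$signed_error),
                                           cnt, 0.2, "error_magnitude", cell,
                                           "late_post", alpha = alpha)
  esign <- sign(al$covariates$signed_error)
  pd_err <- if (all(c(-1, 1) %in% esign)) {
    rr <- vapply(c(1, -1), function(d) {
      idx <- which(esign == d)
      sum(cnt[idx]) / length(idx)
    }, numeric(1))
    if (rr[1] >= rr[2]) 1 else -1
  } else 1
  res$error_direction <- direction_test(esign, cnt,
                                        0.2, pd = pd_err,
                                        parameter = "error_direction",
                                        cell = cell, window_label = "late_post",
                                        alpha = alpha)
  do.call(rbind, res)
}
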