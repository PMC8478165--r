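make_events <- function(amplitude, signed_error, direction = 1) {
  n <- length(amplitude)
  data.frame(onset = seq_len(n) * 1000, offset = seq_len(n) * 1000 + 40,
             duration = 40, amplitude = amplitude, peak_velocity = 700,
             direction = rep_len(direction, n), type = "primary",
             subtype = "CF", start_pos = 0, end_pos = amplitude,
             signed_error = signed_error, assoc_trial = seq_len(n))
}

test_that("error-sign flip exactly negates the error-tuning slope", {
  set.seed(7)
  e <- runif(400, -2, 2)
  offs <- lapply(e, function(x) runif(max(0, rpois(1, 2 + x)), 50, 250))
  al <- make_aligned(offs, data.frame(signed_error = e), window = c(-100, 300))
  t1 <- error_magnitude_tuning(al, pd_error = 1, window = c(50, 250))
  t2 <- error_magnitude_tuning(al, pd_error = -1, window = c(50, 250))
  expect_equal(t1$fit$slope, -t2$fit$slope, tolerance = 1e-9)
})

test_that("generator error gain is recovered and a null generator is flat", {
  cfg <- session_config(n_trials = 600, seed = 22)
  beh <- generate_behavior(cfg)
  ev <- beh$truth$saccades[beh$truth$saccades$kind %in% c("CF", "CP"), ]
  ev$type <- "primary"; ev$subtype <- ev$kind
  gain <- 1
  tun <- neuron_tuning(error_tonic_gain = gain, burst_gain_preferred = 0,
                       burst_gain_anti = 0, amplitude_slope = 0,
                       corrective_burst_gain = 0, trial_onset_gain = 0,
                       suppression_depth = 0, cs_baseline_rate = 3)
  offs <- list(); errs <- numeric(0)
  for (s in 1:4) {
    spk <- generate_spikes(tun, beh$truth, seed = 80 + s, return_lambda = FALSE)
    al <- align_spikes(spk$cs$time_ms, ev, "saccade_offset", c(-100, 300))
    offs <- c(offs, al$offsets); errs <- c(errs, al$covariates$signed_error)
  }
  al <- make_aligned(offs, data.frame(signed_error = errs),
                     window = c(-100, 300))
  tr <- error_magnitude_tuning(al, pd_error = 1, window = c(50, 250),
                               range = c(-1.5, 1.5))
  expect_lt(abs(tr$fit$slope - gain) / gain, 0.2)
  ## null: no error coupling
  tun0 <- neuron_tuning(error_tonic_gain = 0, burst_gain_preferred = 0,
                        burst_gain_anti = 0, amplitude_slope = 0,
                        corrective_burst_gain = 0, trial_onset_gain = 0,
                        suppression_depth = 0, cs_baseline_rate = 3)
  offs0 <- list()
  for (s in 1:4) {
    spk <- generate_spikes(tun0, beh$truth, seed = 90 + s, return_lambda = FALSE)
    al0 <- align_spikes(spk$cs$time_ms, ev, "saccade_offset", c(-100, 300))
    offs0 <- c(offs0, al0$offsets)
  }
  al0 <- make_aligned(offs0, data.frame(signed_error = errs),
                      window = c(-100, 300))
  tr0 <- error_magnitude_tuning(al0, pd_error = 1, window = c(50, 250),
                                range = c(-1.5, 1.5))
  ci <- tr0$fit$slope + c(-3, 3) * tr0$fit$slope_se
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("comparable-error pooling balances amplitudes by construction", {
  ## each bin mixes one over- and one undershoot of equal |amplitude - 15|
  e <- rep(c(-1.1, -0.6, 0.6, 1.1), each = 2)
  a <- 15 + c(0.3, -0.3, 0.2, -0.2, 0.2, -0.2, 0.3, -0.3)
  pool <- pool_comparable_errors(make_events(a, e), edges = seq(-2, 2, 0.5))
  expect_true(all(abs(pool$table$mean_amplitude - 15) < 1e-12))
  expect_equal(pool$balance$p_value, 1)
  ## single bin refuses the balance test
  p1 <- pool_comparable_errors(make_events(c(15, 15.1), c(0.3, 0.4)),
                               edges = seq(-2, 2, 0.5))
  expect_null(p1$balance)
})

test_that("error pooling leaves per-bin mean amplitudes balanced on generated sessions", {
  ## pool left- and right-CF sessions, as the comparable-error analysis does
  for (s in 1:5) {
    ev <- do.call(rbind, lapply(c(1, -1), function(d) {
      cfg <- session_config(n_trials = 300, seed = 100 + s + (d == -1) * 1000,
                            cf_direction = d)
      beh <- generate_behavior(cfg)
      beh$truth$saccades[beh$truth$saccades$kind %in% c("CF", "CP"), ]
    }))
    pool <- pool_comparable_errors(ev, edges = seq(-2, 2, 0.5))
    ## mean amplitude per well-populated error bin stays near the grand mean
    tab <- pool$table[pool$table$n >= 30, ]
    expect_lt(max(abs(tab$mean_amplitude - mean(ev$amplitude, na.rm = TRUE))),
              0.5)
    expect_true(is.finite(pool$balance$statistic))
  }
})

test_that("mixed-error pooling balances error signs exactly", {
  set.seed(8)
  a <- runif(300, 13, 17)
  e <- runif(300, -2, 2)
  pool <- pool_mixed_errors(make_events(a, e), amplitude_bin_size = 0.5,
                            seed = 3)
  expect_true(all(abs(pool$table$mean_error_sign) < 1e-12))
  ## a balanced fixture gives mean signed error exactly 0
  a2 <- rep(c(14.2, 15.2), each = 2)
  e2 <- c(0.5, -0.5, 0.8, -0.8)
  p2 <- pool_mixed_errors(make_events(a2, e2), amplitude_bin_size = 1, seed = 1)
  expect_true(all(abs(p2$table$mean_signed_error) < 1e-12))
  ## single-sign bins are excluded
  p3 <- pool_mixed_errors(make_events(c(14.1, 14.2), c(0.5, 0.7)),
                          amplitude_bin_size = 1, seed = 1)
  expect_identical(length(p3$groups), 0L)
})

test_that("constructed profiles separate peak and mean regressions", {
  ## constant peak, rising tonic across 4 amplitude bins
  set.seed(9)
  mk <- function(bin, n = 80) {
    ## every event: one spike exactly at +60 (constant peak) plus tonic spikes
    ## in [120, 250) whose count grows with the bin (rising mean rate)
    lapply(seq_len(n), function(i) c(60, runif(rpois(1, bin), 120, 250)))
  }
  offs <- c(mk(1), mk(2), mk(3), mk(4))
  a <- rep(c(13.25, 13.75, 14.25, 14.75), each = 80)
  al <- make_aligned(offs, data.frame(amplitude = a,
                                      signed_error = rep(c(-1, 1), 160)),
                     window = c(-100, 300))
  groups <- split(seq_along(offs), rep(c("13.25", "13.75", "14.25", "14.75"),
                                       each = 80))
  reg <- peak_and_mean_regression(al, list(groups = groups), window = c(50, 250))
  ## mean rate rises ~1 spike / 0.2 s per bin = 5 / 0.5 deg = 10 per deg
  expect_gt(reg$mean_fit$slope, 5)
  ## the peak (the delta at +60) is constant across bins
  expect_lt(abs(reg$peak_fit$slope), reg$mean_fit$slope / 2)
  ## identical groups: slope ~0
  offs2 <- c(mk(2), mk(2), mk(2), mk(2))
  al2 <- make_aligned(offs2, data.frame(amplitude = a), window = c(-100, 300))
  reg2 <- peak_and_mean_regression(al2, list(groups = groups),
                                   window = c(50, 250))
  expect_lt(abs(reg2$mean_fit$slope), 5)
})

test_that("per-cell regression recovers exact coefficients and matches normal equations", {
  ## noiseless counts Y = 0.01*A + 0.03*E + 0.2 cannot be made from integer
  ## spikes, so check the algebra against a brute-force normal-equations oracle
  set.seed(10)
  A <- runif(60, 13, 17); E <- runif(60, -2, 2)
  Y <- round(2 + 0.8 * A + 1.5 * E + rpois(60, 2))
  offs <- lapply(Y, function(y) runif(y, 100, 250))
  al <- make_aligned(offs, data.frame(amplitude = A, signed_error = E),
                     window = c(-100, 300))
  out <- per_pc_multiple_regression(list(al), window = c(100, 250),
                                    min_events = 30)
  X <- cbind(1, A, E)
  beta <- solve(t(X) %*% X, t(X) %*% vapply(offs, length, numeric(1)))
  expect_equal(out$fits$c, beta[1], tolerance = 1e-8)
  expect_equal(out$fits$l, beta[2], tolerance = 1e-8)
  expect_equal(out$fits$m, beta[3], tolerance = 1e-8)
  ## exact recovery when counts are exactly linear in A and E
  A2 <- rep(13:17, each = 8); E2 <- rep(c(-2, -1, 1, 2), 10)
  Y2 <- 2 * A2 + 3 * E2 + 10
  offs2 <- lapply(Y2, function(y) seq(100, 240, length.out = y))
  al2 <- make_aligned(offs2, data.frame(amplitude = A2, signed_error = E2),
                      window = c(-100, 300))
  out2 <- per_pc_multiple_regression(list(al2), window = c(100, 250),
                                     min_events = 30)
  expect_equal(out2$fits$l, 2, tolerance = 1e-8)
  expect_equal(out2$fits$m, 3, tolerance = 1e-8)
  expect_equal(out2$fits$c, 10, tolerance = 1e-8)
})

test_that("collinear designs and small cells are skipped with a flag", {
  A <- runif(40, 13, 17)
  al <- make_aligned(lapply(1:40, function(i) 150),
                     data.frame(amplitude = A, signed_error = 15 - A))
  out <- per_pc_multiple_regression(list(al), window = c(100, 250))
  expect_identical(out$skipped, 1L)
  al2 <- make_aligned(lapply(1:10, function(i) 150),
                      data.frame(amplitude = runif(10, 13, 17),
                                 signed_error = runif(10, -1, 1)))
  expect_identical(per_pc_multiple_regression(list(al2))$skipped, 1L)
})
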