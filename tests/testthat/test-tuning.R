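make_dir_aligned <- function(n_right = 150, n_left = 150, p_right = 0.2,
                             p_left = 0.05, seed = 1) {
  set.seed(seed)
  offs <- c(lapply(seq_len(n_right), function(i)
    if (runif(1) < p_right) runif(1, 0, 100) else numeric(0)),
    lapply(seq_len(n_left), function(i)
      if (runif(1) < p_left) runif(1, 0, 100) else numeric(0)))
  make_aligned(offs, data.frame(direction = rep(c(1, -1), c(n_right, n_left))),
               window = c(-200, 300))
}

test_that("the direction with the higher firing probability wins", {
  al <- make_dir_aligned(p_right = 0.20, p_left = 0.05)
  pd <- assign_pd(al, "primary")
  expect_identical(pd$pd, 1)
  expect_identical(pd$stat_used, "probability")
  expect_false(pd$tie_flag)
  ## flip all directions: pd flips (relabeling invariance)
  al2 <- al
  al2$covariates$direction <- -al2$covariates$direction
  expect_identical(assign_pd(al2, "primary")$pd, -1)
})

test_that("exact ties resolve to +1 with a flag and missing directions refuse", {
  offs <- list(50, 50, numeric(0), numeric(0))
  al <- make_aligned(offs, data.frame(direction = c(1, -1, 1, -1)))
  pd <- assign_pd(al, "primary")
  expect_identical(pd$pd, 1)
  expect_true(pd$tie_flag)
  al1 <- make_aligned(list(50, 60), data.frame(direction = c(1, 1)))
  expect_true(assign_pd(al1, "primary")$refused)
})

test_that("corrective and error assignments use their windows and statistics", {
  ## corrective: mean rate 0-100 ms from corrective offset
  offs <- c(lapply(1:50, function(i) c(20, 60)), lapply(1:50, function(i) 20))
  al <- make_aligned(offs, data.frame(direction = rep(c(-1, 1), each = 50)),
                     window = c(-200, 200), alignment = "corrective_offset")
  pd <- assign_pd(al, "corrective")
  expect_identical(pd$pd, -1)
  expect_identical(pd$stat_used, "mean_rate")
  ## error: precorrective window, direction from the error sign
  offs2 <- c(lapply(1:50, function(i) -100), lapply(1:50, function(i) numeric(0)))
  al2 <- make_aligned(offs2, data.frame(signed_error = rep(c(0.8, -0.8),
                                                           each = 50)),
                      window = c(-250, 100), alignment = "corrective_onset")
  pd2 <- assign_pd(al2, "error")
  expect_identical(pd2$pd, 1)
})

test_that("an exactly linear response gives slope and R^2 of the construction", {
  ## counts deterministic in amplitude: mean_rate per bin exactly linear
  amp <- rep(seq(13.25, 15.75, by = 0.5), each = 20)
  offs <- lapply(amp, function(a) runif(20 * a, 0, 100))  # 20*a is integer here
  al <- make_aligned(offs, data.frame(amplitude = amp), window = c(-100, 200))
  tr <- binned_tuning(al, "amplitude", 0.5, range = c(13, 16),
                      response = "mean_rate", window = c(0, 100))
  ## mean_rate per bin = 20*a / 0.1 s = 200*a
  expect_equal(tr$fit$slope, 200, tolerance = 1e-6)
  expect_gt(tr$fit$r_squared, 0.9999)
  ## flat response
  offs2 <- lapply(amp, function(a) runif(50, 0, 100))
  al2 <- make_aligned(offs2, data.frame(amplitude = amp), window = c(-100, 200))
  tr2 <- binned_tuning(al2, "amplitude", 0.5, range = c(13, 16),
                       response = "mean_rate", window = c(0, 100))
  expect_lt(abs(tr2$fit$slope), 2)
  expect_lt(tr2$fit$r_squared, 0.5)
})

test_that("bins below the minimum count are dropped and sparse fits refuse", {
  amp <- c(rep(13.2, 20), rep(14.2, 20), 15.2)   # last bin has 1 event
  offs <- lapply(amp, function(a) 50)
  al <- make_aligned(offs, data.frame(amplitude = amp), window = c(-100, 200))
  tr <- binned_tuning(al, "amplitude", 1, range = c(13, 16),
                      response = "probability", window = c(0, 100))
  expect_identical(nrow(tr$table), 2L)
  ## all events in one bin: refused
  al1 <- make_aligned(lapply(rep(14, 30), function(a) 50),
                      data.frame(amplitude = rep(14, 30)),
                      window = c(-100, 200))
  expect_error(binned_tuning(al1, "amplitude", 1, range = c(13, 16),
                             response = "probability", window = c(0, 100)),
               "fewer than 2")
})

test_that("generator amplitude gain is recovered by binned tuning", {
  cfg <- session_config(n_trials = 500, endpoint_noise_sd = 0.75, seed = 6)
  beh <- generate_behavior(cfg)
  tun <- neuron_tuning(amplitude_slope = 0.6, burst_gain_preferred = 5,
                       burst_gain_anti = 5, error_tonic_gain = 0,
                       trial_onset_gain = 0, corrective_burst_gain = 0)
  ## pool 12 simulated cells on the same behavior for event count
  ev <- beh$truth$saccades[beh$truth$saccades$kind %in% c("CF", "CP"), ]
  ev$type <- "primary"; ev$subtype <- ev$kind
  offs <- list(); amps <- numeric(0)
  for (s in 1:12) {
    spk <- generate_spikes(tun, beh$truth, seed = 60 + s, return_lambda = FALSE)
    al <- align_spikes(spk$cs$time_ms, ev, "saccade_offset", c(-200, 300))
    offs <- c(offs, al$offsets)
    amps <- c(amps, al$covariates$amplitude)
  }
  al <- make_aligned(offs, data.frame(amplitude = amps), window = c(-200, 300))
  tr <- binned_tuning(al, "amplitude", 0.5, range = c(13, 16),
                      response = "mean_rate", window = c(0, 100))
  ## analytic oracle: slope of the early-window mean rate per deg equals the
  ## configured gain times the burst mass falling in [0, 100) ms
  mass <- (pnorm(100, 50, 15) - pnorm(0, 50, 15)) * 15 * sqrt(2 * pi) / 1000
  expected <- 0.6 * mass / 0.1
  expect_lt(abs(tr$fit$slope - expected) / expected, 0.2)
  expect_gt(tr$fit$r_squared, 0.9)
})

test_that("peak time grows monotonically with duration for offset-locked bursts", {
  cfg <- session_config(n_trials = 500, fatigue_velocity_ratio = 0.6, seed = 16)
  beh <- generate_behavior(cfg)
  ev <- beh$truth$saccades[beh$truth$saccades$kind %in% c("CF", "CP"), ]
  ev$type <- "primary"; ev$subtype <- ev$kind
  cells <- lapply(1:20, function(s) {
    spk <- generate_spikes(neuron_tuning(burst_gain_anti = 5,
                                         error_tonic_gain = 0,
                                         trial_onset_gain = 0),
                           beh$truth, seed = 70 + s, return_lambda = FALSE)
    align_spikes(spk$cs$time_ms, ev, "saccade_onset", c(-200, 400))
  })
  out <- bootstrap_peak_time(cells, seq(45, 80, by = 5), n_cells = 15,
                             min_trials = 20, reps = 50, seed = 4,
                             search_window = c(0, 250))
  expect_gte(nrow(out), 5)
  expect_equal(cor(out$bin_lo, out$peak_time_mean, method = "spearman"), 1)
  ## offset-locked burst: onset-aligned peak sits near bin duration + latency
  mid <- (out$bin_lo + out$bin_hi) / 2
  expect_lt(max(abs(out$peak_time_mean - (mid + 50))), 10)
})
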