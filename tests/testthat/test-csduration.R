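test_that("constant durations give a flat percent-change profile", {
  cs <- data.frame(time_ms = seq(100, 10000, by = 50), duration_ms = 5)
  ser <- percent_change_series(cs, c(2000, 5000, 8000))
  expect_true(all(ser$pct_change[!is.na(ser$pct_change)] == 0))
})

test_that("a window of lengthened CSs shows up at its percent change", {
  ## durations 5 ms everywhere, 6 ms (+20% of the 5-ms mode) in [100, 150)
  ## after the single event; with most CSs unchanged the cell mean stays ~5
  cs_t <- seq(-2000, 2000, by = 10) + 5000
  dur <- rep(5, length(cs_t))
  bump <- cs_t - 5000 >= 100 & cs_t - 5000 < 150
  dur[bump] <- 6
  cs <- data.frame(time_ms = cs_t, duration_ms = dur)
  ser <- percent_change_series(cs, 5000, window = c(-300, 500), bin = 50,
                               step = 50)
  cm <- attr(ser, "cell_mean")
  expected <- 100 * (6 - cm) / cm
  i <- which(ser$time == 125)
  expect_equal(ser$pct_change[i], expected, tolerance = 1e-9)
  expect_gt(ser$pct_change[i], 15)
})

test_that("epoch detection is exact on injected modulations and quiet on flats", {
  grid <- seq(-275, 475, by = 10)
  flat <- data.frame(time = grid, mean = rnorm(length(grid), 0, 0.5))
  set.seed(11)
  ## flat profile: no epochs at k = 3 (threshold from its own baseline)
  ep0 <- detect_epochs(data.frame(time = grid, mean = rep(0, length(grid))))
  expect_identical(nrow(ep0$epochs), 0L)
  ## injected rectangular dip of 5 SD in [-50, 50)
  set.seed(12)
  y <- rnorm(length(grid), 0, 0.5)
  base_sd <- sd(y[grid >= -200 & grid < -100])
  y[grid >= -50 & grid < 50] <- y[grid >= -50 & grid < 50] - 5 * base_sd
  ep <- detect_epochs(data.frame(time = grid, mean = y))
  dec <- ep$epochs[ep$epochs$kind == "decrease", ]
  expect_identical(nrow(dec), 1L)
  expect_lte(abs(dec$start - (-50)), 50)
  expect_lte(abs(dec$end - 50), 50)
  ## k -> infinity: no epochs
  epInf <- detect_epochs(data.frame(time = grid, mean = y), k = 1e6)
  expect_identical(nrow(epInf$epochs), 0L)
  ## deterministic: same input, same epochs
  ep2 <- detect_epochs(data.frame(time = grid, mean = y))
  expect_identical(ep, ep2)
})

test_that("rate-yoked spikelet probability produces the expected duration epochs", {
  cfg <- session_config(n_trials = 400, seed = 33)
  beh <- generate_behavior(cfg)
  prim <- beh$truth$saccades[beh$truth$saccades$kind %in% c("CF", "CP"), ]
  tun <- neuron_tuning(burst_gain_anti = 5, spikelet_prob_gain = 0.45,
                       error_tonic_gain = 0, trial_onset_gain = 0,
                       corrective_burst_gain = 0)
  series <- lapply(1:12, function(s) {
    spk <- generate_spikes(tun, beh$truth, seed = 200 + s,
                           return_lambda = FALSE)
    percent_change_series(spk$cs, prim$onset)
  })
  prof <- population_duration_profile(series)
  ep <- detect_epochs(prof)
  ## the burst (offset + ~50 ms, i.e. ~100 ms from onset) lengthens CSs
  inc <- ep$epochs[ep$epochs$kind == "increase", ]
  expect_gte(nrow(inc), 1)
  expect_true(any(inc$start > 0 & inc$start < 250))
  ## perisaccadic suppression removes long CSs: a decrease epoch near onset
  dec <- ep$epochs[ep$epochs$kind == "decrease", ]
  expect_gte(nrow(dec), 1)
})

test_that("duration-shuffled trains show no epochs in most shuffles", {
  cfg <- session_config(n_trials = 300, seed = 34)
  beh <- generate_behavior(cfg)
  prim <- beh$truth$saccades[beh$truth$saccades$kind %in% c("CF", "CP"), ]
  tun <- neuron_tuning(burst_gain_anti = 5, spikelet_prob_gain = 0.45,
                       error_tonic_gain = 0, trial_onset_gain = 0)
  cells <- lapply(1:15, function(s)
    generate_spikes(tun, beh$truth, seed = 300 + s, return_lambda = FALSE)$cs)
  set.seed(13)
  hits <- vapply(1:100, function(r) {
    series <- lapply(cells, function(cs) {
      cs$duration_ms <- sample(cs$duration_ms)
      percent_change_series(cs, prim$onset)
    })
    nrow(detect_epochs(population_duration_profile(series))$epochs) > 0
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("duration tuning tracks the generator coupling and flips with error sign", {
  cfg <- session_config(n_trials = 500, endpoint_noise_sd = 0.75, seed = 35)
  beh <- generate_behavior(cfg)
  ev <- beh$truth$saccades[beh$truth$saccades$kind %in% c("CF", "CP"), ]
  ev$type <- "primary"; ev$subtype <- ev$kind
  tun <- neuron_tuning(burst_gain_anti = 5, amplitude_slope = 1,
                       spikelet_prob_gain = 0.45, error_tonic_gain = 0,
                       trial_onset_gain = 0, corrective_burst_gain = 0)
  cells <- lapply(1:8, function(s) list(
    cs = generate_spikes(tun, beh$truth, seed = 400 + s,
                         return_lambda = FALSE)$cs,
    events = ev))
  dt <- duration_tuning(cells, "amplitude", window = c(100, 200),
                        alignment = "onset", bin_size = 1)
  ## duration is yoked to rate: amplitude raises the burst, so the duration
  ## slope is positive in both direction classes
  expect_gt(dt$pd$fit$slope, 0)
  ## no coupling: slope CI contains 0
  tun0 <- neuron_tuning(burst_gain_anti = 5, amplitude_slope = 1,
                        spikelet_prob_gain = 0, spikelet_base_prob = 0.4,
                        error_tonic_gain = 0, trial_onset_gain = 0,
                        corrective_burst_gain = 0)
  cells0 <- lapply(1:8, function(s) list(
    cs = generate_spikes(tun0, beh$truth, seed = 500 + s,
                         return_lambda = FALSE)$cs,
    events = ev))
  dt0 <- duration_tuning(cells0, "amplitude", window = c(100, 200),
                         alignment = "onset", bin_size = 1)
  ci <- dt0$pd$fit$slope + c(-2, 2) * dt0$pd$fit$slope_se
  expect_true(ci[1] < 0 && ci[2] > 0)
  ## error-sign antisymmetry
  tun_e <- neuron_tuning(burst_gain_preferred = 0, burst_gain_anti = 0,
                         amplitude_slope = 0, error_tonic_gain = 1.5,
                         spikelet_prob_gain = 0.45, trial_onset_gain = 0,
                         corrective_burst_gain = 0, suppression_depth = 0,
                         cs_baseline_rate = 3)
  cells_e <- lapply(1:6, function(s) list(
    cs = generate_spikes(tun_e, beh$truth, seed = 600 + s,
                         return_lambda = FALSE)$cs,
    events = ev))
  d1 <- duration_tuning(cells_e, "signed_error", window = c(50, 250),
                        alignment = "offset", bin_size = 0.5, pd = 1)
  ev_f <- ev; ev_f$signed_error <- -ev_f$signed_error
  cells_f <- lapply(cells_e, function(cl) list(cs = cl$cs, events = ev_f))
  d2 <- duration_tuning(cells_f, "signed_error", window = c(50, 250),
                        alignment = "offset", bin_size = 0.5, pd = 1)
  expect_equal(d1$pd$fit$slope, -d2$anti$fit$slope, tolerance = 1e-9)
})
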