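## shared fixture builders (all generated in code; no files)

## a noiseless trace containing one minimum-jerk saccade
minjerk_trace <- function(amplitude = 15, duration = 40, onset = 500,
                          len = 1500, start_pos = 0, fs = 1000) {
  t <- seq(0, len, by = 1000 / fs)
  x <- start_pos + amplitude * csmux:::minjerk_pos((t - onset) / duration)
  data.frame(t_ms = t, x_deg = x, y_deg = 0)
}

## an aligned_spikes object built by hand
make_aligned <- function(offsets, covariates, window = c(-200, 300),
                         alignment = "saccade_offset") {
  structure(list(offsets = offsets, covariates = covariates,
                 alignment = alignment, window = window,
                 n_events = length(offsets)),
            class = "aligned_spikes")
}

## small standard session used by several tests
small_session <- function(n_trials = 60, seed = 42, ...) {
  session_config(n_trials = n_trials, seed = seed, ...)
}

## exact one-tailed signed-rank p by enumeration over all 2^n sign patterns
## (independent oracle; continuous data assumed, no ties or zeros)
exact_signed_rank_p <- function(hi, lo) {
  d <- hi - lo
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  mean(w_all >= w_obs)
}
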