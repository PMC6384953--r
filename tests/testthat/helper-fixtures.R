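# Shared fixtures: everything is generated in code at test time.

# a small but complete session (short LFP keeps the suite fast)
tiny_session <- function(seed = 7, duration = 60, ...) {
  cfg <- sim_config(duration = duration, seed = seed,
                    n_som_pos = 2, n_excited = 2, n_unaffected = 4, ...)
  simulate_session(cfg)
}

# membership of times in half-open epochs
in_epochs_test <- function(times, epochs) {
  res <- rep(FALSE, length(times))
  for (i in seq_len(nrow(epochs)))
    res <- res | (times >= epochs$onset[i] & times < epochs$offset[i])
  res
}

# generative oscillation phase at spike times falling inside true events
true_event_phases <- function(ts, events) {
  ph <- numeric(0)
  for (i in seq_len(nrow(events))) {
    s <- ts[ts >= events$onset[i] & ts < events$end[i]]
    if (length(s))
      ph <- c(ph, (2 * pi * events$freq[i] * (s - events$onset[i]) +
                     events$phase0[i]) %% (2 * pi))
  }
  ph
}

# Poisson spike train helper (homogeneous, for null constructions)
poisson_train <- function(rate, duration, id = "p1") {
  n <- stats::rpois(1, rate * duration)
  spike_train(id, sort(stats::runif(n, 0, duration)), duration)
}

# pink-noise LFP with bursts injected at explicit times/amps/durs
inject_bursts <- function(duration, fs, onsets, amps, durs, freqs = 30,
                          seed = 1, noise_exponent = 1) {
  withr::with_seed(seed, {
    n <- round(duration * fs)
    wn <- stats::rnorm(n)
    X <- stats::fft(wn)
    f <- (0:(n - 1)) * fs / n
    f2 <- pmin(f, fs - f)
    shape <- ifelse(f2 > 0, f2^(-noise_exponent / 2), 0)
    bg <- Re(stats::fft(X * shape, inverse = TRUE)) / n
    bg <- bg / stats::sd(bg)
    amp_spec <- Mod(stats::fft(bg)) / n
    sigma_band <- sqrt(sum(amp_spec[f2 >= 20 & f2 <= 80]^2))
    tvec <- (0:(n - 1)) / fs
    freqs <- rep_len(freqs, length(onsets))
    for (i in seq_along(onsets)) {
      idx <- which(tvec >= onsets[i] & tvec < onsets[i] + durs[i])
      tt <- tvec[idx] - onsets[i]
      # raised-cosine ramps over the first/last 12.5% of the burst
      env <- sin(pi / 2 * pmin(1, pmin(tt, durs[i] - tt) / (0.125 * durs[i])))^2
      bg[idx] <- bg[idx] + amps[i] * sigma_band * env * sin(2 * pi * freqs[i] * tt)
    }
    list(lfp = lfp_signal(bg, fs), sigma_band = sigma_band)
  })
}
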