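test_that("degenerate and invalid inputs are handled", {
  # zero-variance signal: no events, no error
  z <- lfp_signal(rep(0, 5000), 500)
  expect_equal(nrow(detect_gamma_events(z)), 0)
  # too-short signal names the minimum length
  expect_error(detect_gamma_events(lfp_signal(rnorm(100), 500)), "at least")
  # sampling rate below Nyquist for the band
  expect_error(detect_gamma_events(lfp_signal(rnorm(1000), 120)), "Nyquist")
})

test_that("a single injected burst is recovered with its frequency", {
  fx <- inject_bursts(20, 500, onsets = 10, amps = 4, durs = 0.3,
                      freqs = 30, seed = 41)
  ev <- detect_gamma_events(fx$lfp)
  # exactly one detected event overlaps the injection (background envelope
  # excursions in pink noise are counted by the false-rate test below)
  hit <- ev[ev$end > 10 & ev$onset < 10.3, ]
  expect_equal(nrow(hit), 1)
  expect_lt(abs(hit$onset - 10), 0.03)
  expect_lt(abs(hit$mean_frequency - 30), 2)
  expect_gte(hit$amplitude, 2)
  expect_gte(hit$duration, 0.15)
})

test_that("noise-floor event rate on pure pink noise stays in its band", {
  # frozen regression bound: mean rate 0.285/s (sd 0.045) measured over 20
  # seeds at these parameters
  rates <- vapply(1:3, function(s) {
    fx <- inject_bursts(60, 500, numeric(0), numeric(0), numeric(0), seed = s)
    nrow(detect_gamma_events(fx$lfp)) / 60
  }, numeric(1))
  expect_true(all(rates > 0.1 & rates < 0.5))
})

test_that("bursts separated by less than the refractory window merge", {
  # nominal gap 80 ms; the 1 SD envelope boundaries leave a sub-refractory
  # gap, so the merge rule concatenates the two bursts
  fx <- inject_bursts(20, 500, onsets = c(8, 8.38), amps = c(4, 4),
                      durs = c(0.3, 0.3), seed = 42)
  ev <- detect_gamma_events(fx$lfp)
  hit <- ev[ev$end > 8 & ev$onset < 8.7, ]
  expect_equal(nrow(hit), 1)
  expect_lt(hit$onset, 8.1)
  expect_gt(hit$end, 8.58)
  # same bursts wide apart stay separate
  fx2 <- inject_bursts(20, 500, onsets = c(8, 10), amps = c(4, 4),
                       durs = c(0.3, 0.3), seed = 42)
  ev2 <- detect_gamma_events(fx2$lfp)
  expect_equal(nrow(ev2[ev2$end > 8 & ev2$onset < 8.3, ]), 1)
  expect_equal(nrow(ev2[ev2$end > 10 & ev2$onset < 10.3, ]), 1)
})

test_that("detector is invariant to signal scaling", {
  fx <- inject_bursts(20, 500, onsets = c(5, 12), amps = c(4, 3.5),
                      durs = c(0.3, 0.25), seed = 43)
  ev1 <- detect_gamma_events(fx$lfp)
  lfp10 <- lfp_signal(fx$lfp$samples * 10, fx$lfp$fs)
  ev2 <- detect_gamma_events(lfp10)
  expect_equal(ev1, ev2, tolerance = 1e-8)
})

test_that("time-reversing the input time-reverses event boundaries", {
  fx <- inject_bursts(20, 500, onsets = c(5, 12), amps = c(4, 4),
                      durs = c(0.3, 0.3), seed = 44)
  ev <- detect_gamma_events(fx$lfp)
  rev_lfp <- lfp_signal(rev(drop(fx$lfp$samples)), fx$lfp$fs)
  ev_r <- detect_gamma_events(rev_lfp)
  T <- (nrow(fx$lfp$samples) - 1) / fx$lfp$fs
  expect_equal(nrow(ev), nrow(ev_r))
  expect_equal(sort(T - ev_r$end), sort(ev$onset), tolerance = 3 / 500)
  expect_equal(sort(T - ev_r$onset), sort(ev$end), tolerance = 3 / 500)
})

test_that("every emitted event satisfies the advertised contracts", {
  sim <- tiny_session(seed = 45, duration = 120)
  p <- gamma_detection_params()
  ev <- detect_gamma_events(sim$session$lfp, p)
  expect_gt(nrow(ev), 3)
  expect_true(all(ev$amplitude >= p$thresh_sd))
  expect_true(all(ev$duration >= p$min_duration))
  expect_true(all(ev$end > ev$onset))
  expect_true(all(ev$peak_time >= ev$onset & ev$peak_time <= ev$end))
  # sorted, non-overlapping
  expect_true(!is.unsorted(ev$onset))
  expect_true(all(ev$onset[-1] >= ev$end[-nrow(ev)]))
  # event duration equals end - onset by definition
  expect_equal(ev$duration, ev$end - ev$onset)
})

test_that("characterize_event matches analytic segments", {
  fs <- 500
  t <- (0:(20 * fs - 1)) / fs
  p <- gamma_detection_params()
  tone <- lfp_signal(sin(2 * pi * 30 * t), fs)
  ch <- characterize_event(tone, list(onset = 5, end = 6), p)
  expect_lt(abs(ch$mean_frequency - 30), 1)
  expect_equal(ch$duration, 1)
  # linear chirp 25 -> 35 Hz across the event: amplitude-weighted mean ~ 30
  f_inst <- 25 + (35 - 25) * (t - 5) / 2
  chirp <- sin(2 * pi * cumsum(ifelse(t >= 5 & t < 7, f_inst, 25)) / fs)
  ch2 <- characterize_event(lfp_signal(chirp, fs), list(onset = 5, end = 7), p)
  expect_lt(abs(ch2$mean_frequency - 30), 2)
  # zero-amplitude segment flags undefined frequency
  zl <- lfp_signal(c(rep(0, 10 * fs), sin(2 * pi * 30 * t[1:(10 * fs)])), fs)
  ch3 <- characterize_event(zl, list(onset = 2, end = 3), p)
  expect_true(is.na(ch3$mean_frequency))
  # out-of-bounds event errors
  expect_error(characterize_event(tone, list(onset = 19, end = 21), p),
               "bounds")
})

test_that("gamma_event_density does the paired arithmetic", {
  # 30 ON epochs of 5 s (150 s) and 30 paired OFF windows of 5 s
  on <- data.frame(onset = seq(15, by = 20, length.out = 30))
  on$offset <- on$onset + 5
  off <- data.frame(onset = on$onset - 5, offset = on$onset, trial = 1:30)
  withr::with_seed(50, {
    peaks_off <- runif(45, 0, 1) * 5 + off$onset[sample(30, 45, TRUE)]
    peaks_on <- runif(6, 0, 1) * 5 + on$onset[sample(30, 6, TRUE)]
  })
  ev <- data.frame(peak_time = c(peaks_off, peaks_on))
  d <- gamma_event_density(ev, on, off)
  expect_equal(d$density_off, 45 / 150)
  expect_equal(d$density_on, 6 / 150)
  expect_equal(sum(d$trials$off * 5), 45)
  # no events
  d0 <- gamma_event_density(data.frame(peak_time = numeric()), on, off)
  expect_equal(d0$density_on, 0)
  expect_equal(d0$density_off, 0)
  expect_error(gamma_event_density(ev, on[0, ], off), "epoch time")
})
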