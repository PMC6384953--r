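# helper: laser-modulated Bernoulli-thinned train at 1 ms resolution
modulated_train <- function(rate_off, rate_on, laser, duration, seed,
                            onset_delay = 0, id = "u") {
  withr::with_seed(seed, {
    dt <- 1e-3
    tt <- seq(0, duration - dt, by = dt)
    r <- rep(rate_off, length(tt))
    for (i in seq_len(nrow(laser$epochs))) {
      on <- laser$epochs$onset[i] + onset_delay
      r[tt >= on & tt < laser$epochs$offset[i]] <- rate_on
    }
    ts <- tt[stats::runif(length(tt)) < r * dt] + stats::runif(1, 0, dt)
    spike_train(id, ts, duration)
  })
}

test_that("peri_event_histogram does the count/bin-width arithmetic", {
  dur <- 32 * 31
  onsets <- seq(16, by = 31, length.out = 32)
  sp <- spike_train("u1", onsets + 0.25, dur)
  h <- peri_event_histogram(sp, onsets, window = 15, bin = 0.5)
  b0 <- which(h$lag == 0.25)         # bin [0, 0.5)
  expect_equal(h$rate[b0], 2)        # 1 spike / 0.5 s per trial
  expect_true(all(h$rate[-b0] == 0))
  expect_equal(unique(h$n_trials), 32)
})

test_that("peri_event_histogram is flat for a stationary train and handles edges", {
  withr::with_seed(60, {
    sp <- poisson_train(20, 2000)
    onsets <- seq(50, 1950, by = 40)
    h <- peri_event_histogram(sp, onsets, 15, 0.5)
    expect_lt(abs(mean(h$rate) - 20), 1.5)
    expect_lt(max(abs(h$rate - 20)) / 20, 0.35)   # sampling error only
  })
  # truncated window at session end: out-of-session bins have no valid trials
  sp2 <- spike_train("u2", c(5, 9.75), 12)
  h2 <- peri_event_histogram(sp2, onsets = 9.5, window = 15, bin = 0.5)
  expect_equal(h2$n_trials[h2$lag > 2.5], rep(0, sum(h2$lag > 2.5)))
  expect_equal(h2$rate[h2$lag == 0.25], 2)        # spike at +0.25, 1 valid trial
  # empty train: all-zero histogram with flag
  h3 <- peri_event_histogram(spike_train("e", numeric(), 100), 50, 15, 0.5)
  expect_true(all(h3$rate == 0))
  expect_true(attr(h3, "empty"))
})

test_that("sliding_sweeps template is calibrated and powerful", {
  dur <- 600
  las <- sim_laser_continuous(dur)
  onsets <- las$epochs$onset
  # fully suppressed unit: bins over [0, 5 s] flagged as depressed
  sp <- modulated_train(10, 0, las, dur, seed = 61)
  ss <- sliding_sweeps(sp, onsets)
  on_bins <- ss$lag > 0 & ss$lag < 5
  expect_true(all(ss$significant[on_bins]))
  expect_true(all(ss$template[on_bins] < 0.5))
  # stationary unit: near-uniform template, few significant bins
  sp0 <- modulated_train(10, 10, las, dur, seed = 62)
  ss0 <- sliding_sweeps(sp0, onsets)
  expect_lt(mean(abs(ss0$template - 1)), 0.15)
  expect_lte(sum(ss0$significant), 3)
  # degenerate inputs
  expect_error(sliding_sweeps_params(n_shuffles = 0), "n_shuffles")
  ssu <- sliding_sweeps(spike_train("e", 1, dur), onsets)
  expect_true(ssu$undefined)
  expect_error(sliding_sweeps(sp, onsets,
                              sliding_sweeps_params(window = 400)),
               "window")
})

test_that("interval shuffling preserves the ISI multiset exactly", {
  withr::with_seed(63, {
    ts <- sort(runif(200, 0, 100))
    for (k in 1:5) {
      sh <- bfgamma:::shuffle_intervals(ts)
      expect_equal(sort(diff(sh)), sort(diff(ts)), tolerance = 1e-12)
      expect_equal(sh[1], ts[1])
      expect_equal(max(sh), max(ts), tolerance = 1e-9)
    }
  })
})

test_that("classify_unit recovers constructed response classes", {
  dur <- 600
  las <- sim_laser_continuous(dur)   # 30 trials
  supp <- classify_unit(modulated_train(10, 5, las, dur, seed = 64), las)
  expect_identical(supp$label, "suppressed")
  expect_lt(abs(supp$modulation_pct - 50), 12)
  # near-complete suppression also yields a defined latency
  hard <- classify_unit(modulated_train(20, 0.5, las, dur, seed = 71), las)
  expect_identical(hard$label, "suppressed")
  expect_lte(hard$latency, 0.05)
  exc <- classify_unit(modulated_train(5, 10, las, dur, seed = 65), las)
  expect_identical(exc$label, "excited")
  expect_lt(abs(exc$modulation_pct - 100), 30)
  flat <- classify_unit(modulated_train(8, 8, las, dur, seed = 66), las)
  expect_identical(flat$label, "unaffected")
  expect_true(is.na(flat$modulation_pct))
  # silent OFF condition: modulation undefined, flagged unaffected
  sil <- classify_unit(modulated_train(0, 4, las, dur, seed = 67), las)
  expect_identical(sil$label, "unaffected")
  expect_identical(sil$flag, "no OFF-epoch spikes: modulation undefined")
})

test_that("classify_unit keeps its type-I error at or below nominal", {
  dur <- 600
  las <- sim_laser_continuous(dur)
  hits <- sum(vapply(1:100, function(s) {
    cl <- classify_unit(modulated_train(8, 8, las, dur, seed = 1000 + s), las)
    cl$label != "unaffected"
  }, logical(1)))
  # binomial(100, 0.05) upper tail: P(X > 11) < 0.003
  expect_lte(hits, 11)
})

test_that("suppression_latency recovers constructed delays", {
  dur <- 600
  las <- sim_laser_continuous(dur)
  sp0 <- modulated_train(30, 0, las, dur, seed = 68)
  expect_lte(suppression_latency(sp0, las$epochs$onset, bin = 0.01,
                                 .checked = TRUE), 0.02)
  sp2 <- modulated_train(30, 0, las, dur, seed = 69, onset_delay = 0.2)
  lat <- suppression_latency(sp2, las$epochs$onset, bin = 0.01, .checked = TRUE)
  expect_lt(abs(lat - 0.2), 0.03)
  # unchanged unit: never crosses, and the public path rejects it
  sp3 <- modulated_train(30, 30, las, dur, seed = 70)
  expect_true(is.na(suppression_latency(sp3, las$epochs$onset, .checked = TRUE)))
  expect_error(suppression_latency(sp3, las$epochs$onset), "not suppressed")
})

test_that("population_summary reproduces the reference proportions", {
  mk <- function(label) structure(list(label = label), class = "unit_classification")
  cls <- c(replicate(29, mk("suppressed"), simplify = FALSE),
           replicate(56, mk("excited"), simplify = FALSE),
           replicate(245, mk("unaffected"), simplify = FALSE))
  tab <- population_summary(cls)
  expect_equal(tab$pct, c(8.8, 17.0, 74.2))
  expect_equal(sum(tab$n), 330)
  one <- population_summary(list(mk("excited")))
  expect_equal(one$pct[one$label == "excited"], 100)
  expect_error(population_summary(list()), ">= 1")
})
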