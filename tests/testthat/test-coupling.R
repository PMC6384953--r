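test_that("ppc matches hand-enumerated and brute-force values", {
  expect_equal(ppc(rep(1.3, 10)), 1)
  expect_equal(ppc(c(0, pi)), -1)
  # pairs of {0, pi/2, pi}: cos(pi/2)=0, cos(pi)=-1, cos(pi/2)=0 -> -1/3
  expect_equal(ppc(c(0, pi / 2, pi)), -1 / 3)
  # closed form equals the explicit pairwise sum
  brute <- function(th) {
    n <- length(th); s <- 0
    for (j in 1:(n - 1)) for (k in (j + 1):n) s <- s + cos(th[j] - th[k])
    2 * s / (n * (n - 1))
  }
  withr::with_seed(80, {
    for (n in c(2, 3, 17, 101, 200)) {
      th <- runif(n, 0, 2 * pi)
      expect_equal(ppc(th), brute(th), tolerance = 1e-12)
    }
  })
  # fewer than 2 phases: undefined, flagged
  expect_true(is.na(ppc(0.5)))
  expect_true(attr(ppc(0.5), "undefined"))
})

test_that("ppc is rotation invariant and unbiased under uniform phases", {
  withr::with_seed(81, {
    th <- runif(50, 0, 2 * pi)
    for (c0 in c(-2, 0.7, pi)) expect_equal(ppc(th + c0), ppc(th))
    # unbiased near zero for any N, unlike the resultant length (PLV)
    for (n in c(10, 100)) {
      vals <- replicate(300, ppc(runif(n, 0, 2 * pi)))
      plv <- replicate(300, Mod(mean(exp(1i * runif(n, 0, 2 * pi)))))
      expect_lt(abs(mean(vals)), 0.02)
      expect_gt(mean(plv), 0.05)  # PLV positively biased at small N
    }
  })
})

test_that("spike_gamma_xcorr flags constructed locking and degenerate inputs", {
  dur <- 300
  withr::with_seed(82, {
    peaks <- sort(runif(60, 5, dur - 5))
    peaks <- peaks[c(TRUE, diff(peaks) > 1)]
  })
  events <- data.frame(peak_time = peaks)
  # spikes exactly at event peaks: maximal central bin, coupled at any n
  sp <- spike_train("locked", peaks, dur)
  cp <- coupling_params(n_event_shuffles = 100)
  xc <- spike_gamma_xcorr(sp, events, cp)
  ctr <- which.min(abs(xc$lag))
  expect_equal(xc$prob[ctr], max(xc$prob))
  expect_true(xc$coupled)
  expect_lte(xc$p, 0.05)
  # empty train: flat flagged correlogram
  xc0 <- spike_gamma_xcorr(spike_train("e", numeric(), dur), events, cp)
  expect_true(all(xc0$prob == 0))
  expect_identical(xc0$flag, "empty spike train")
  expect_error(spike_gamma_xcorr(sp, events[0, , drop = FALSE], cp),
               "no events")
})

test_that("ppc_spectrum detects constructed phase locking", {
  fs <- 500; dur <- 120
  t <- (0:(dur * fs - 1)) / fs
  lfp <- lfp_signal(sin(2 * pi * 30 * t), fs)
  cp <- coupling_params(ppc_freq_grid = c(20, 30, 40), min_spikes_ppc = 20)
  # spikes at successive oscillation peaks
  pk <- seq(1 / 120, dur - 1, by = 1 / 30) + (1 / 30) * 0.25
  sp <- spike_train("pk", pk[pk > 1 & pk < dur - 1], dur)
  psp <- ppc_spectrum(sp, lfp, cp)
  expect_gte(psp$ppc["all", "30"], 0.95)
  # independent spikes on a noise LFP: PPC near zero
  withr::with_seed(83, {
    lfp2 <- lfp_signal(rnorm(dur * fs), fs)
    sp2 <- poisson_train(8, dur)
  })
  psp2 <- ppc_spectrum(sp2, lfp2, cp)
  n <- psp2$n_spikes["all"]
  expect_lt(abs(psp2$ppc["all", "30"]), 4 / sqrt(n * (n - 1) / 2))
  # too few spikes: flagged undefined
  psp3 <- ppc_spectrum(spike_train("s", c(1, 2, 3), dur), lfp, cp)
  expect_true(all(is.na(psp3$ppc)))
})

test_that("ppc is stable under spike subsampling (bias-free)", {
  fs <- 500; dur <- 60
  t <- (0:(dur * fs - 1)) / fs
  lfp <- lfp_signal(sin(2 * pi * 30 * t), fs)
  cp <- coupling_params(ppc_freq_grid = 30, min_spikes_ppc = 10)
  withr::with_seed(84, {
    # partially locked train: oscillation peaks + jitter
    pk <- seq(1, dur - 1, by = 1 / 30) + rnorm(length(seq(1, dur - 1, by = 1 / 30)), 0, 0.006)
    sp <- spike_train("j", sort(pk), dur)
    full <- ppc_spectrum(sp, lfp, cp)$ppc["all", "30"]
    subs <- replicate(50, {
      keep <- sort(sample(length(sp$timestamps), length(sp$timestamps) %/% 2))
      ppc_spectrum(spike_train("h", sp$timestamps[keep], dur), lfp, cp)$ppc["all", "30"]
    })
    expect_lt(abs(mean(subs) - full), 0.02)
  })
})

test_that("rate_vs_gamma_amplitude behaves under independence and bad input", {
  dur <- 1200
  withr::with_seed(85, {
    onset <- sort(runif(1500, 1, dur - 2))
    onset <- onset[c(TRUE, diff(onset) > 1)]
    events <- data.frame(onset = onset, end = onset + 0.3,
                         amplitude = runif(length(onset), 2, 6))
    units <- lapply(1:6, function(i) poisson_train(8, dur, paste0("u", i)))
  })
  res <- rate_vs_gamma_amplitude(units, events)
  expect_lt(abs(res$r), 0.1)
  expect_gte(res$n_events, 400)
  expect_error(rate_vs_gamma_amplitude(units, events[1:2, ]), ">= 3 events")
})

test_that("su_mu_coherence picks up a common oscillatory drive", {
  dur <- 600; fs <- 1000
  las <- sim_laser_continuous(dur)
  withr::with_seed(86, {
    # both trains rate-modulated by a common 30 Hz oscillation
    tt <- seq(0, dur - 1e-3, by = 1e-3)
    lam <- 40 * (1 + 0.9 * sin(2 * pi * 30 * tt)) / 1000
    mk <- function(id) spike_train(id, tt[runif(length(tt)) < lam] +
                                     runif(1, 0, 1e-3), dur)
    ref <- mk("ref")
    others <- lapply(1:6, function(i) mk(paste0("o", i)))
  })
  off <- epoch_complement(las, 5)
  res <- su_mu_coherence(ref, others, las$epochs, off)
  pk <- res$freqs > 28 & res$freqs < 32
  expect_gt(mean(res$coh_off[pk]), 3 * stats::median(res$coh_off))
  # excluding the reference from the sum matters: including it changes coherence
  res2 <- su_mu_coherence(ref, c(others, list(ref)), las$epochs, off)
  expect_false(isTRUE(all.equal(res$coh_off, res2$coh_off)))
  expect_error(su_mu_coherence(ref, list(), las$epochs, off), "2 simultaneously")
})

test_that("su_mu_coherence stays flat for independent trains", {
  dur <- 600
  las <- sim_laser_continuous(dur)
  off <- epoch_complement(las, 5)
  withr::with_seed(87, {
    ref <- poisson_train(15, dur, "ref")
    others <- lapply(1:3, function(i) poisson_train(15, dur, paste0("o", i)))
  })
  res <- su_mu_coherence(ref, others, las$epochs, off)
  expect_false(any(res$fdr_mask))
})
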