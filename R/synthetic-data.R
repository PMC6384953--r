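# Synthetic recording sessions with known ground truth. The generator states
# the world the analyses are tested against: a 10-minute anesthetized-style
# session, pink-noise LFP carrying transient gamma bursts around 30 Hz, laser
# protocols of 5 s ON / 15 s OFF (recording) or trains of 10 one-second pulses
# (behavior), units that are laser-suppressed (SOM+), laser-excited or
# unaffected, von-Mises phase locking of SOM+ spikes to the burst oscillation,
# and open-field / Y-maze behavioral traces.

#' Simulation configuration
#'
#' Defaults follow the recording regimes the analyses assume: 10-minute
#' sessions sampled at 500 Hz, laser ON for 5 s every 20 s, gamma bursts with
#' mean frequency 30 Hz (the anesthetized band), about 50% photosuppression of
#' SOM+ units. Burst amplitude is expressed in units of the 20-80 Hz
#' background SD (the quantity the envelope detector thresholds); duration and
#' rate defaults are free parameters of the stated world (no quantitative
#' distributions are published) chosen to give clearly visible, sparse bursts.
#'
#' @param duration session length (s)
#' @param fs LFP sampling rate (Hz)
#' @param noise_exponent 1/f slope of the background (power ~ 1/f^exponent)
#' @param lfp_sd broadband background SD (mV)
#' @param gamma_rate_off burst rate off-laser (events/s)
#' @param gamma_rate_on_factor multiplicative burst-rate change during laser ON
#' @param gamma_freq_mean,gamma_freq_sd per-burst frequency distribution (Hz)
#' @param gamma_dur_mean,gamma_dur_min burst duration: `min + Exp(mean - min)` (s)
#' @param gamma_amp_sd_units burst plateau amplitude in units of the 20-80 Hz
#'   background SD; per-burst amplitudes jitter around this by 25%
#' @param gamma_ongoing_sd amplitude of the continuous narrowband gamma
#'   component (units of the 20-80 Hz background SD); the band shows a
#'   sustained spectral shoulder beyond the discrete bursts
#' @param gamma_ongoing_on_factor multiplicative amplitude change of the
#'   ongoing gamma component during laser ON (0.7 halves its power)
#' @param n_som_pos,n_excited,n_unaffected unit counts per response class
#' @param som_suppression fractional rate decrease of SOM+ units during ON
#' @param excited_gain rate multiplier of excited units during ON
#' @param phase_kappa von-Mises concentration of SOM+ spike phases inside bursts
#' @param base_rate mean basal firing rate (Hz); per-unit rates jitter lognormally
#' @param rate_amp_r target generative Pearson correlation between the shared
#'   per-burst rate modulation and burst amplitude (0 disables)
#' @param speed_step laser-evoked speed increment at rest (cm/s)
#' @param alternation_p probability of a correct Y-maze alternation
#' @param seed integer seed; every generator is deterministic given it
#' @return list of class `sim_config`
#' @export
sim_config <- function(duration = 600, fs = 500, noise_exponent = 1,
                       lfp_sd = 0.15,
                       gamma_rate_off = 0.4, gamma_rate_on_factor = 0.5,
                       gamma_freq_mean = 30, gamma_freq_sd = 3,
                       gamma_dur_mean = 0.30, gamma_dur_min = 0.15,
                       gamma_amp_sd_units = 4,
                       gamma_ongoing_sd = 1.5, gamma_ongoing_on_factor = 0.7,
                       n_som_pos = 3, n_excited = 5, n_unaffected = 12,
                       som_suppression = 0.5, excited_gain = 1.5,
                       phase_kappa = 1.5, base_rate = 8,
                       rate_amp_r = 0.25,
                       speed_step = 4, alternation_p = 0.7, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(duration > 0, fs > 0, gamma_rate_off >= 0,
            gamma_rate_on_factor >= 0, gamma_dur_min > 0,
            gamma_dur_mean >= gamma_dur_min,
            som_suppression >= 0, som_suppression <= 1,
            excited_gain >= 0, phase_kappa >= 0, base_rate >= 0,
            alternation_p >= 0, alternation_p <= 1)
  if (duration * fs > 5e8) stop("duration x fs too large")
  class(cfg) <- "sim_config"
  cfg
}

#' Standard laser protocols
#'
#' `sim_laser_continuous()` builds the recording protocol (ON for `on_s`
#' seconds every `period_s`, first onset after one full OFF period).
#' `sim_laser_train()` builds the behavioral protocol: trains of
#' `n_pulses` 1-s pulses at 0.5 Hz, delivered randomly every 2-3 minutes.
#'
#' @param duration session length (s)
#' @param on_s,period_s ON duration and cycle period (s)
#' @return a [laser_protocol()]
#' @export
sim_laser_continuous <- function(duration, on_s = 5, period_s = 20) {
  off_s <- period_s - on_s
  onsets <- seq(off_s, duration - on_s, by = period_s)
  laser_protocol(data.frame(onset = onsets, offset = onsets + on_s),
                 kind = "continuous_pulse", power_label = "10-15 mW")
}

#' @rdname sim_laser_continuous
#' @param n_pulses pulses per train
#' @param pulse_on,pulse_period pulse ON time and period within a train (s)
#' @param gap_range_s uniform range of inter-train gaps (s)
#' @param seed integer seed
#' @export
sim_laser_train <- function(duration, n_pulses = 10, pulse_on = 1,
                            pulse_period = 2, gap_range_s = c(120, 180),
                            seed = 1L) {
  withr::with_seed(seed, {
    span <- (n_pulses - 1) * pulse_period + pulse_on
    starts <- numeric()
    t <- stats::runif(1, 30, 60)
    while (t + span < duration) {
      starts <- c(starts, t)
      t <- t + stats::runif(1, gap_range_s[1], gap_range_s[2])
    }
    ep <- do.call(rbind, lapply(starts, function(s)
      data.frame(onset = s + pulse_period * (0:(n_pulses - 1)),
                 offset = s + pulse_period * (0:(n_pulses - 1)) + pulse_on)))
    if (is.null(ep)) ep <- data.frame(onset = numeric(), offset = numeric())
    laser_protocol(ep, kind = "pulse_train", power_label = "15-20 mW")
  })
}

#' First-pulse onsets of each pulse train
#'
#' Groups the epochs of a pulse-train protocol into trains (gaps above 3 s
#' separate trains) and returns each train's first onset.
#'
#' @param laser a [laser_protocol()]
#' @return numeric vector of train onset times (s)
#' @export
train_onsets <- function(laser) {
  on <- laser$epochs$onset
  if (!length(on)) return(numeric())
  on[c(TRUE, diff(on) > 3 + 1e-9)]
}

#' Simulate a pink-noise LFP with embedded gamma bursts
#'
#' Background is 1/f^`noise_exponent` noise (spectral shaping of white noise)
#' plus a continuous narrowband gamma component (Gaussian spectral profile
#' centered on `gamma_freq_mean`) whose amplitude is scaled by
#' `gamma_ongoing_on_factor` during laser ON. Burst onsets form a Poisson
#' process with rate `gamma_rate_off` off-laser and
#' `gamma_rate_off * gamma_rate_on_factor` during ON epochs; bursts closer than
#' 0.3 s to the preceding burst are thinned so that true events stay separable.
#' Each burst is an amplitude-enveloped (Tukey window) sinusoid with its own
#' frequency, duration and amplitude.
#'
#' @param config a [sim_config()]
#' @param laser optional [laser_protocol()]; omitted means no ON epochs
#' @return list: `lfp` ([lfp_signal()]) and `events` (data.frame of true
#'   bursts: onset, end, peak_time, duration, freq, amp_sd, phase0)
#' @export
simulate_lfp <- function(config, laser = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed * 13L + 1L, {
    n <- round(config$duration * config$fs)
    fs <- config$fs
    # spectrally shaped white noise
    wn <- stats::rnorm(n)
    X <- stats::fft(wn)
    f <- (0:(n - 1)) * fs / n
    f2 <- pmin(f, fs - f)                       # symmetric frequency axis
    shape <- ifelse(f2 > 0, f2^(-config$noise_exponent / 2), 0)
    bg <- Re(stats::fft(X * shape, inverse = TRUE)) / n
    bg <- bg / stats::sd(bg) * config$lfp_sd
    # band SD of the pink background alone (brickwall 20-80 Hz)
    amp_spec <- Mod(stats::fft(bg)) / n
    band <- f2 >= 20 & f2 <= 80
    sigma_pink <- sqrt(sum(amp_spec[band]^2))
    sig <- bg
    tvec <- (0:(n - 1)) / fs
    # continuous narrowband gamma component, amplitude-scaled during laser ON
    if (config$gamma_ongoing_sd > 0) {
      K <- exp(-((f2 - config$gamma_freq_mean)^2) /
                 (2 * config$gamma_freq_sd^2))
      ong <- Re(stats::fft(stats::fft(stats::rnorm(n)) * K, inverse = TRUE)) / n
      ong <- ong / stats::sd(ong) * config$gamma_ongoing_sd * sigma_pink
      gain <- rep(1, n)
      if (!is.null(laser) && nrow(laser$epochs))
        for (i in seq_len(nrow(laser$epochs))) {
          i0 <- floor(laser$epochs$onset[i] * fs) + 1
          i1 <- min(n, ceiling(laser$epochs$offset[i] * fs))
          gain[i0:i1] <- config$gamma_ongoing_on_factor
        }
      sig <- sig + ong * gain
    }
    # burst amplitude is expressed relative to the total band background
    # (pink + ongoing) so detectability does not depend on the ongoing level
    sigma_band <- sigma_pink *
      sqrt(1 + (config$gamma_ongoing_sd * mean(c(1, config$gamma_ongoing_on_factor)))^2)
    # Poisson burst onsets, piecewise rate over laser epochs
    ev <- sim_burst_times(config, laser)
    if (nrow(ev)) {
      for (i in seq_len(nrow(ev))) {
        i0 <- floor(ev$onset[i] * fs) + 1
        i1 <- min(n, ceiling(ev$end[i] * fs))
        tt <- tvec[i0:i1] - ev$onset[i]
        env <- tukey_window(length(tt), 0.25)
        sig[i0:i1] <- sig[i0:i1] +
          ev$amp_sd[i] * sigma_band * env *
          sin(2 * pi * ev$freq[i] * tt + ev$phase0[i])
      }
    }
    list(lfp = lfp_signal(sig, fs, t0 = 0, channel_ids = "sim"),
         events = ev, sigma_band = sigma_band)
  })
}

# Poisson burst schedule with laser-dependent rate; called inside with_seed
sim_burst_times <- function(config, laser) {
  dur <- config$duration
  segs <- data.frame(onset = 0, offset = dur, on = FALSE)
  if (!is.null(laser) && nrow(laser$epochs)) {
    ep <- laser$epochs
    br <- sort(unique(c(0, ep$onset, ep$offset, dur)))
    segs <- data.frame(onset = br[-length(br)], offset = br[-1])
    segs$on <- vapply(segs$onset, function(s)
      any(s >= ep$onset & s < ep$offset), logical(1))
  }
  onsets <- numeric()
  for (i in seq_len(nrow(segs))) {
    rate <- config$gamma_rate_off *
      if (segs$on[i]) config$gamma_rate_on_factor else 1
    len <- segs$offset[i] - segs$onset[i]
    k <- stats::rpois(1, rate * len)
    if (k) onsets <- c(onsets, sort(stats::runif(k, segs$onset[i], segs$offset[i])))
  }
  onsets <- sort(onsets)
  if (!length(onsets))
    return(data.frame(onset = numeric(), end = numeric(), peak_time = numeric(),
                      duration = numeric(), freq = numeric(), amp_sd = numeric(),
                      phase0 = numeric()))
  durs <- config$gamma_dur_min +
    stats::rexp(length(onsets), 1 / max(config$gamma_dur_mean - config$gamma_dur_min, 1e-6))
  durs <- pmin(durs, 2)
  # thin bursts that would start before the previous burst has cleared
  keep <- logical(length(onsets)); last_end <- -Inf
  for (i in seq_along(onsets)) {
    if (onsets[i] > last_end + 0.3 && onsets[i] + durs[i] < dur) {
      keep[i] <- TRUE; last_end <- onsets[i] + durs[i]
    }
  }
  onsets <- onsets[keep]; durs <- durs[keep]
  k <- length(onsets)
  freq <- pmin(pmax(stats::rnorm(k, config$gamma_freq_mean, config$gamma_freq_sd),
                    21), 79)
  amp <- pmax(stats::rnorm(k, config$gamma_amp_sd_units,
                           0.25 * config$gamma_amp_sd_units), 2)
  data.frame(onset = onsets, end = onsets + durs,
             peak_time = onsets + durs / 2, duration = durs,
             freq = freq, amp_sd = amp,
             phase0 = stats::runif(k, 0, 2 * pi))
}

tukey_window <- function(n, alpha = 0.25) {
  if (n == 1) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / alpha - 1)))
  w
}

#' Simulate single-unit spike trains with known response classes
#'
#' Spikes come from an inhomogeneous point process (Bernoulli thinning on the
#' LFP sample grid): SOM+ units fire at `base * (1 - som_suppression)` during
#' laser ON and are von-Mises phase-locked (concentration `phase_kappa`,
#' mean-rate preserving) to the burst oscillation while inside a true event;
#' excited units scale by `excited_gain` during ON; unaffected units are
#' stationary. When `rate_amp_r > 0`, a per-event rate modulation shared by
#' all units is correlated with burst amplitude at that target Pearson r.
#'
#' @param config a [sim_config()]
#' @param lfp the [lfp_signal()] from [simulate_lfp()] (defines the time grid)
#' @param true_events true burst table from [simulate_lfp()]
#' @param laser a [laser_protocol()]
#' @return list: `units` (list of [spike_train()]) and `truth` (ground-truth
#'   list: per-unit labels, base rates, preferred phases, per-event rate
#'   modulation and its realized correlation with amplitude)
#' @export
simulate_units <- function(config, lfp, true_events, laser) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed * 13L + 2L, {
    n <- nrow(lfp$samples)
    fs <- lfp$fs
    dur <- n / fs
    tvec <- (0:(n - 1)) / fs
    on_mask <- rep(FALSE, n)
    if (nrow(laser$epochs))
      for (i in seq_len(nrow(laser$epochs))) {
        i0 <- floor(laser$epochs$onset[i] * fs) + 1
        i1 <- min(n, ceiling(laser$epochs$offset[i] * fs))
        on_mask[i0:i1] <- TRUE
      }
    nev <- nrow(true_events)
    # shared per-event rate modulation correlated with amplitude
    if (nev && config$rate_amp_r > 0) {
      # modulation scale (across-event rate CV); large enough that the
      # structured component dominates Poisson counting noise when the
      # correlation is estimated from finite spike counts
      s <- 0.6
      r <- config$rate_amp_r
      z <- as.numeric(scale(true_events$amp_sd))
      if (any(!is.finite(z))) z <- rep(0, nev)
      m_e <- 1 + r * s * z + stats::rnorm(nev, 0, s * sqrt(1 - r^2))
      m_e <- pmax(m_e, 0.1)
    } else m_e <- rep(1, nev)
    labels <- c(rep("suppressed", config$n_som_pos),
                rep("excited", config$n_excited),
                rep("unaffected", config$n_unaffected))
    nu <- length(labels)
    base <- config$base_rate * stats::rlnorm(nu, -0.045, 0.3)
    pref <- stats::runif(nu, 0, 2 * pi)
    kap <- config$phase_kappa
    i0k <- besselI(kap, 0)
    units <- vector("list", nu)
    for (u in seq_len(nu)) {
      rate <- rep(base[u], n)
      if (labels[u] == "suppressed") rate[on_mask] <- base[u] * (1 - config$som_suppression)
      if (labels[u] == "excited") rate[on_mask] <- base[u] * config$excited_gain
      if (nev) {
        for (e in seq_len(nev)) {
          i0 <- floor(true_events$onset[e] * fs) + 1
          i1 <- min(n, ceiling(true_events$end[e] * fs))
          seg <- i0:i1
          mod <- m_e[e]
          if (labels[u] == "suppressed" && kap > 0) {
            ph <- 2 * pi * true_events$freq[e] * (tvec[seg] - true_events$onset[e]) +
              true_events$phase0[e]
            mod <- mod * exp(kap * cos(ph - pref[u])) / i0k
          }
          rate[seg] <- rate[seg] * mod
        }
      }
      p <- pmin(rate / fs, 1)
      hit <- which(stats::runif(n) < p)
      ts <- sort(tvec[hit] + stats::runif(length(hit), 0, 1 / fs))
      ts <- ts[ts < dur]
      units[[u]] <- spike_train(sprintf("u%02d", u), ts, dur)
    }
    truth <- list(labels = labels, base_rates = base, pref_phases = pref,
                  som_suppression = config$som_suppression,
                  excited_gain = config$excited_gain,
                  event_mod = m_e,
                  rate_amp_r_realized = if (nev > 2 && stats::sd(m_e) > 0 &&
                                            stats::sd(true_events$amp_sd) > 0)
                    stats::cor(m_e, true_events$amp_sd) else NA_real_,
                  events = true_events)
    list(units = units, truth = truth)
  })
}

#' Simulate an open-field tracking trace
#'
#' Speed follows a mean-reverting (OU) process whose target switches between
#' rest (~0.3 cm/s) and run (~8 cm/s) bouts with exponential durations
#' (memoryless, hence time-reversible: pre/post averages around a random
#' trigger are symmetric under the null). `speed_step` is added for the span
#' of each pulse train whose first pulse falls in a rest bout. Positions are
#' integrated from speed with a slowly drifting heading at 30 FPS.
#'
#' @param config a [sim_config()]
#' @param laser a pulse-train [laser_protocol()]
#' @param duration trace length (s); default covers the protocol plus a minute
#' @return a [behavior_track()]; attributes `state` (per-frame "rest"/"run")
#'   and `speed_true` carry the generative ground truth
#' @export
simulate_open_field <- function(config, laser, duration = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (laser$kind != "pulse_train")
    stop("simulate_open_field requires a pulse_train laser protocol")
  if (is.null(duration))
    duration <- (if (nrow(laser$epochs)) max(laser$epochs$offset) else 540) + 60
  withr::with_seed(config$seed * 13L + 3L, {
    fps <- 30
    dt <- 1 / fps
    n <- round(duration * fps)
    t <- (0:(n - 1)) * dt
    # exponential rest/run bouts
    state <- character(0); st <- sample(c("rest", "run"), 1, prob = c(0.6, 0.4))
    while (length(state) < n) {
      len <- stats::rexp(1, 1 / if (st == "rest") 15 else 10)
      state <- c(state, rep(st, max(1, round(len * fps))))
      st <- if (st == "rest") "run" else "rest"
    }
    state <- state[1:n]
    target <- ifelse(state == "rest", 0.3, 8)
    # laser step during trains starting at rest
    tr_on <- train_onsets(laser)
    if (length(tr_on) && config$speed_step != 0) {
      ep <- laser$epochs
      for (s in tr_on) {
        fr <- min(n, floor(s * fps) + 1)
        if (state[fr] == "rest") {
          span_end <- max(ep$offset[ep$onset >= s - 1e-9 &
                                      ep$onset < s + 25])
          idx <- which(t >= s & t < span_end)
          target[idx] <- target[idx] + config$speed_step
        }
      }
    }
    tau <- 1; sig <- 0.5
    v <- numeric(n); v[1] <- target[1]
    for (i in 2:n)
      v[i] <- max(0, v[i - 1] + (dt / tau) * (target[i] - v[i - 1]) +
                    sig * sqrt(dt) * stats::rnorm(1))
    heading <- cumsum(stats::rnorm(n, 0, 0.4 * sqrt(dt)))
    x <- 25 + cumsum(v * cos(heading) * dt)
    y <- 15 + cumsum(v * sin(heading) * dt)
    structure(behavior_track(t, x, y, fps), state = state, speed_true = v)
  })
}

#' Simulate a Y-maze arm-entry sequence
#'
#' Markov choice rule: with probability `alternation_p` the animal enters the
#' arm not visited in the last two entries (a correct alternation), otherwise
#' it returns to the previous arm. Inter-entry intervals are exponential.
#'
#' @param config a [sim_config()]
#' @param laser unused; kept for API symmetry with the other generators
#' @param n_entries number of entries (default fills a 5-minute session)
#' @param mean_interval mean inter-entry interval (s)
#' @return an [arm_entries()] sequence
#' @export
simulate_ymaze <- function(config, laser = NULL, n_entries = NULL,
                           mean_interval = 8) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed * 13L + 4L, {
    if (is.null(n_entries)) n_entries <- max(3, round(300 / mean_interval))
    arms <- c("A", "B", "C")
    seq_arms <- character(n_entries)
    seq_arms[1] <- sample(arms, 1)
    seq_arms[2] <- sample(setdiff(arms, seq_arms[1]), 1)
    for (i in 3:n_entries) {
      third <- setdiff(arms, c(seq_arms[i - 2], seq_arms[i - 1]))
      seq_arms[i] <- if (stats::runif(1) < config$alternation_p) third
                     else seq_arms[i - 2]
    }
    tt <- cumsum(stats::rexp(n_entries, 1 / mean_interval))
    arm_entries(tt, seq_arms)
  })
}

#' Simulate a complete recording session
#'
#' Builds the continuous-pulse laser protocol, the LFP with embedded bursts
#' and the unit population, and assembles a validated [recording_session()].
#'
#' @param config a [sim_config()]
#' @param region "VP" or "MS" (metadata label only; the physiology is set by
#'   the config — see [fixture_configs()])
#' @return list: `session`, `truth`
#' @export
simulate_session <- function(config, region = "VP") {
  laser <- sim_laser_continuous(config$duration)
  lf <- simulate_lfp(config, laser)
  un <- simulate_units(config, lf$lfp, lf$events, laser)
  session <- recording_session(lf$lfp, un$units, laser,
                               meta = list(region = region, genotype = "NpHR+"))
  list(session = session, truth = un$truth, sigma_band = lf$sigma_band)
}

#' Configurations of the two reference fixtures
#'
#' The VP-like session has gamma-locked SOM+ units, laser-halved burst rate
#' and amplitude-correlated firing; the MS-like session has the same response
#' classes but no spike-gamma locking and no laser effect on the bursts.
#'
#' @param seed integer seed
#' @param ... overrides passed to [sim_config()] (both fixtures)
#' @return list with elements `vp` and `ms`, each a [sim_config()]
#' @export
fixture_configs <- function(seed = 1L, ...) {
  list(vp = sim_config(seed = seed, ...),
       ms = sim_config(gamma_rate_on_factor = 1, gamma_ongoing_on_factor = 1,
                       phase_kappa = 0, rate_amp_r = 0,
                       seed = seed + 1000L, ...))
}
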