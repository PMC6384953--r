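# Envelope-threshold detection of transient gamma-band events in the LFP,
# after the modified fast-oscillation detector: downsample to 500 Hz,
# zero-phase 20-80 Hz FIR band-pass, rectify, 4th-order Butterworth low-pass
# at 20 Hz, z-score over the whole signal, 2 SD threshold with 1 SD boundary
# extension, 150 ms refractory merging, Morlet (7-cycle) characterization and
# a 150 ms minimum-duration criterion.

#' Parameters of the gamma-event detector
#'
#' @param target_fs working sampling rate after downsampling (Hz)
#' @param band detection band (lo, hi) in Hz
#' @param rolloff FIR transition width (Hz)
#' @param envelope_lp envelope low-pass cutoff (Hz)
#' @param envelope_order Butterworth order of the envelope low-pass
#' @param thresh_sd detection threshold (z units)
#' @param bound_sd boundary-extension threshold (z units)
#' @param refractory merge window between events (s)
#' @param min_duration minimum event duration (s)
#' @param wavelet_cycles Morlet wavelet width (cycles)
#' @return list of class `gamma_detection_params`
#' @export
gamma_detection_params <- function(target_fs = 500, band = c(20, 80),
                                   rolloff = 0.5, envelope_lp = 20,
                                   envelope_order = 4, thresh_sd = 2,
                                   bound_sd = 1, refractory = 0.150,
                                   min_duration = 0.150, wavelet_cycles = 7) {
  stopifnot(band[1] < band[2], thresh_sd > bound_sd, bound_sd > 0,
            refractory > 0, min_duration > 0, wavelet_cycles > 0)
  structure(as.list(environment()), class = "gamma_detection_params")
}

#' Detect gamma-band events in an LFP channel
#'
#' Pipeline: downsample -> zero-phase two-way least-squares FIR band-pass ->
#' rectify -> zero-phase Butterworth low-pass (smooth envelope) -> z-score
#' using the mean and SD of the whole signal -> threshold crossings at
#' `thresh_sd` extended to the first `bound_sd` crossing on each side ->
#' merge events separated by less than `refractory` -> Morlet
#' characterization -> drop events shorter than `min_duration`.
#'
#' A zero-variance envelope (e.g. an all-zero signal) yields no events.
#'
#' @param lfp an [lfp_signal()]
#' @param params a [gamma_detection_params()]
#' @param channel channel index or id
#' @return data.frame of class `gamma_events` with columns `onset`, `end`,
#'   `peak_time`, `duration`, `mean_frequency`, `amplitude` (envelope z at
#'   peak, also the event magnitude used downstream)
#' @export
detect_gamma_events <- function(lfp, params = gamma_detection_params(),
                                channel = 1) {
  stopifnot(inherits(lfp, "lfp_signal"))
  fs0 <- lfp$fs
  fs <- min(params$target_fs, fs0)
  if (fs < 2 * params$band[2])
    stop("sampling rate ", fs, " Hz below Nyquist for band hi = ",
         params$band[2], " Hz")
  x <- decimate_signal(lfp_channel(lfp, channel), fs0, fs)
  min_len <- 3 * (3L * round(fs / params$band[1]) + 1L)
  if (length(x) < min_len)
    stop("signal too short: need at least ", min_len, " samples at ", fs, " Hz")
  bp <- bandpass_fir(x, fs, params$band[1], params$band[2], params$rolloff)
  env <- lowpass_butter(abs(bp), fs, params$envelope_lp, params$envelope_order)
  mu <- mean(env); sdv <- stats::sd(env)
  empty <- data.frame(onset = numeric(), end = numeric(), peak_time = numeric(),
                      duration = numeric(), mean_frequency = numeric(),
                      amplitude = numeric())
  class(empty) <- c("gamma_events", "data.frame")
  if (!is.finite(sdv) || sdv == 0) return(empty)
  z <- (env - mu) / sdv
  above <- z > params$thresh_sd
  if (!any(above)) return(empty)
  r <- rle(above)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1
  reg <- cbind(starts_i[r$values], ends_i[r$values])
  # extend each region to the first bound_sd crossing on either side
  below_idx <- which(z <= params$bound_sd)
  ext <- t(apply(reg, 1, function(rg) {
    k <- findInterval(rg[1], below_idx)
    on_i <- if (k >= 1) below_idx[k] else 1L
    k2 <- findInterval(rg[2], below_idx) + 1L
    end_i <- if (k2 <= length(below_idx)) below_idx[k2] else length(z)
    c(on_i, end_i)
  }))
  # extension can make neighbours coincide; collapse overlaps, then merge
  # events whose gap is below the refractory window
  ord <- order(ext[, 1])
  ext <- ext[ord, , drop = FALSE]
  gap_samp <- params$refractory * fs
  merged <- list(); cur <- ext[1, ]
  for (i in seq_len(nrow(ext))[-1]) {
    if (ext[i, 1] - cur[2] < gap_samp) cur[2] <- max(cur[2], ext[i, 2])
    else { merged[[length(merged) + 1]] <- cur; cur <- ext[i, ] }
  }
  merged[[length(merged) + 1]] <- cur
  m <- do.call(rbind, merged)
  t_of <- function(i) (i - 1) / fs  # time of sample i on the decimated grid
  freqs <- seq(params$band[1], params$band[2], by = 1)
  out <- lapply(seq_len(nrow(m)), function(i) {
    i0 <- m[i, 1]; i1 <- m[i, 2]
    dur <- t_of(i1) - t_of(i0)
    if (dur < params$min_duration) return(NULL)
    pk <- i0 - 1 + which.max(z[i0:i1])
    ch <- characterize_segment(bp, fs, i0, i1, freqs, params$wavelet_cycles)
    data.frame(onset = t_of(i0), end = t_of(i1), peak_time = t_of(pk),
               duration = dur, mean_frequency = ch$mean_frequency,
               amplitude = z[pk])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  class(out) <- c("gamma_events", "data.frame")
  attr(out, "fs") <- fs
  out
}

# Morlet ridge characterization of one event span within a band-passed signal.
# The wavelet transform is computed on a locally padded window for speed.
characterize_segment <- function(bp, fs, i0, i1, freqs, cycles) {
  pad <- round(fs)  # 1 s of context on each side
  a <- max(1, i0 - pad); b <- min(length(bp), i1 + pad)
  pw <- morlet_power(bp[a:b], fs, freqs, cycles)
  span <- (i0 - a + 1):(i1 - a + 1)
  ridge_i <- apply(pw[, span, drop = FALSE], 2, which.max)
  ridge_p <- pw[cbind(ridge_i, span)]
  if (sum(ridge_p) <= 0)
    return(list(mean_frequency = NA_real_, amplitude = NA_real_))
  list(mean_frequency = sum(freqs[ridge_i] * ridge_p) / sum(ridge_p),
       amplitude = sqrt(max(ridge_p)))
}

#' Morlet characterization of a single event
#'
#' Computes the amplitude-weighted mean of the wavelet-power ridge frequency
#' over the event span, plus the peak wavelet amplitude. Zero-power segments
#' are flagged with `NA` frequency.
#'
#' @param lfp_bandpassed band-passed [lfp_signal()] (or the full-band signal;
#'   characterization is restricted to the wavelet grid)
#' @param event list or one-row data.frame with `onset` and `end` (s)
#' @param params a [gamma_detection_params()]
#' @param channel channel index
#' @return list: `mean_frequency` (Hz), `amplitude`, `duration` (s)
#' @export
characterize_event <- function(lfp_bandpassed, event,
                               params = gamma_detection_params(), channel = 1) {
  x <- lfp_channel(lfp_bandpassed, channel)
  fs <- lfp_bandpassed$fs
  i0 <- floor((event$onset - lfp_bandpassed$t0) * fs) + 1
  i1 <- ceiling((event$end - lfp_bandpassed$t0) * fs)
  if (i0 < 1 || i1 > length(x) || i1 <= i0)
    stop("event [", event$onset, ", ", event$end, "] outside signal bounds")
  freqs <- seq(params$band[1], params$band[2], by = 1)
  ch <- characterize_segment(x, fs, i0, i1, freqs, params$wavelet_cycles)
  list(mean_frequency = ch$mean_frequency, amplitude = ch$amplitude,
       duration = event$end - event$onset)
}

#' Gamma-event density during laser ON vs paired OFF windows
#'
#' Events are assigned to epochs by `peak_time` membership (half-open
#' intervals). OFF windows are the pre-onset complements of the ON epochs,
#' so each trial contributes a paired (off, on) density.
#'
#' @param events a `gamma_events` data.frame
#' @param epochs_on data.frame of ON epochs (`onset`, `offset`)
#' @param epochs_off data.frame of paired OFF windows, as from
#'   [epoch_complement()] (a `trial` column pairs rows to ON epochs)
#' @return list: `density_on`, `density_off` (events/s, pooled), and `trials`
#'   (per-trial paired densities ready for a paired test)
#' @export
gamma_event_density <- function(events, epochs_on, epochs_off) {
  tot_on <- epoch_total(epochs_on); tot_off <- epoch_total(epochs_off)
  if (tot_on <= 0 || tot_off <= 0) stop("zero total epoch time")
  c_on <- count_in_epochs(events$peak_time, epochs_on)
  c_off <- count_in_epochs(events$peak_time, epochs_off)
  trial_of <- if ("trial" %in% names(epochs_off)) epochs_off$trial
              else seq_len(nrow(epochs_off))
  trials <- data.frame(
    trial = trial_of,
    off = c_off / (epochs_off$offset - epochs_off$onset),
    on = (c_on / (epochs_on$offset - epochs_on$onset))[trial_of])
  list(density_on = sum(c_on) / tot_on, density_off = sum(c_off) / tot_off,
       trials = trials)
}
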