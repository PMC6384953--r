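# Multitaper spectral estimation on 5-s laser epochs: Slepian-tapered PSDs,
# 1/f normalization, ON/OFF ratio spectra with per-frequency Wilcoxon tests
# under Benjamini-Hochberg FDR control, and gamma-band power comparisons.

#' Multitaper parameters
#'
#' The taper count and half bandwidth are tied to the time-bandwidth product:
#' `K = 2*TW - 1` and `W = TW / epoch`; both identities are asserted at
#' construction (for TW = 3 and 5-s epochs: K = 5 tapers, W = 0.6 Hz).
#'
#' @param TW time-bandwidth product
#' @param epoch analysis epoch length (s)
#' @param target_fs working sampling rate (Hz)
#' @param notch mains frequency whose bins are excised from ratio spectra (Hz)
#' @param notch_halfwidth excision half-width (Hz)
#' @param gamma_band band used for gamma power (Hz)
#' @param K,W optional overrides; must satisfy the identities
#' @return list of class `spectral_params`
#' @export
spectral_params <- function(TW = 3, epoch = 5, target_fs = 500, notch = 50,
                            notch_halfwidth = 2, gamma_band = c(20, 40),
                            K = 2 * TW - 1, W = TW / epoch) {
  if (K != 2 * TW - 1) stop("spectral_params: K must equal 2*TW - 1")
  if (abs(W - TW / epoch) > 1e-12) stop("spectral_params: W must equal TW/epoch")
  structure(as.list(environment()), class = "spectral_params")
}

#' Multitaper power spectral density of one epoch
#'
#' Average of `K` Slepian eigenspectra; one-sided density so that
#' `sum(psd) * df` approximates the segment variance (Parseval, up to taper
#' leakage and the dropped DC/Nyquist bins). Frequency resolution is
#' `1/epoch`.
#'
#' @param segment numeric vector of exactly `epoch * target_fs` samples
#' @param sp a [spectral_params()]
#' @param fs sampling rate of `segment`; must equal `sp$target_fs`
#' @param demean subtract the segment mean first
#' @return data.frame: `freq` (Hz, > 0 up to Nyquist), `power`
#' @export
multitaper_psd <- function(segment, sp = spectral_params(),
                           fs = sp$target_fs, demean = TRUE) {
  n <- round(sp$epoch * fs)
  if (length(segment) != n)
    stop("multitaper_psd: segment must have ", n, " samples (got ",
         length(segment), ")")
  if (demean) segment <- segment - mean(segment)
  V <- dpss_tapers(n, sp$TW, sp$K)
  Fk <- stats::mvfft(V * segment)
  S <- rowMeans(Mod(Fk)^2) / fs
  freqs <- (0:(n - 1)) * fs / n
  # one-sided density over 0 < f < Nyquist (the half-weight Nyquist bin is
  # dropped so white noise is flat across the returned grid)
  sel <- freqs > 0 & freqs < fs / 2 - 1e-9
  data.frame(freq = freqs[sel], power = 2 * S[sel])
}

#' 1/f normalization of a PSD
#'
#' Multiplies each power value by its frequency to correct for the power law
#' of field-potential spectra; the f = 0 bin (if present) is dropped.
#'
#' @param psd data.frame with `freq`, `power`
#' @return data.frame with normalized `power`
#' @export
normalize_1overf <- function(psd) {
  psd <- psd[psd$freq > 0, , drop = FALSE]
  psd$power <- psd$power * psd$freq
  psd
}

# PSDs of all ON epochs and their paired pre-onset OFF windows
paired_epoch_psds <- function(lfp, laser, sp, channel = 1) {
  x <- decimate_signal(lfp_channel(lfp, channel), lfp$fs, sp$target_fs)
  fs <- sp$target_fs
  n <- round(sp$epoch * fs)
  ep_on <- laser$epochs
  ep_off <- epoch_complement(laser, sp$epoch)
  full <- ep_off$offset - ep_off$onset >= sp$epoch - 1e-9
  ep_off <- ep_off[full, , drop = FALSE]
  if (nrow(ep_off) < 5) stop("need >= 5 matched ON/OFF trial pairs")
  seg <- function(t0) {
    i0 <- floor((t0 - lfp$t0) * fs) + 1
    x[i0:(i0 + n - 1)]
  }
  nb <- n %/% 2 - 1  # PSD grid excludes DC and Nyquist
  P_on <- vapply(ep_off$trial, function(i) multitaper_psd(seg(ep_on$onset[i]), sp)$power,
                 numeric(nb))
  P_off <- vapply(seq_len(nrow(ep_off)), function(i) multitaper_psd(seg(ep_off$onset[i]), sp)$power,
                  numeric(nb))
  freqs <- multitaper_psd(seg(ep_off$onset[1]), sp)$freq
  list(freqs = freqs, on = P_on, off = P_off, n_pairs = nrow(ep_off))
}

#' ON/OFF PSD ratio spectrum with FDR-masked per-frequency tests
#'
#' Per trial pair, multitaper PSDs on the 5-s ON epoch and the preceding 5-s
#' OFF window; the ratio spectrum is the trial average of ON/OFF per
#' frequency bin. A two-sided Wilcoxon signed-rank test compares conditions
#' per bin, masked by Benjamini-Hochberg FDR at `q`. Bins within
#' `notch_halfwidth` of the mains frequency are excised from the output.
#'
#' @param lfp an [lfp_signal()]
#' @param laser a [laser_protocol()] (continuous-pulse protocol)
#' @param sp a [spectral_params()]
#' @param q FDR level
#' @param fmax highest frequency retained (Hz); the default restricts the
#'   comparison to the sub-60 Hz range in which the gamma hypothesis lives
#' @param channel LFP channel
#' @return list: `freqs`, `ratio`, `p`, `fdr_mask`, `n_pairs`
#' @export
psd_ratio_on_off <- function(lfp, laser, sp = spectral_params(), q = 0.05,
                             fmax = 60, channel = 1) {
  pp <- paired_epoch_psds(lfp, laser, sp, channel)
  keep <- pp$freqs <= fmax & abs(pp$freqs - sp$notch) > sp$notch_halfwidth
  freqs <- pp$freqs[keep]
  on <- pp$on[keep, , drop = FALSE]; off <- pp$off[keep, , drop = FALSE]
  ratio <- rowMeans(on / off)
  p <- vapply(seq_along(freqs), function(j) {
    if (all(on[j, ] == off[j, ])) return(1)
    suppressWarnings(stats::wilcox.test(on[j, ], off[j, ], paired = TRUE,
                                        exact = FALSE)$p.value)
  }, numeric(1))
  list(freqs = freqs, ratio = ratio, p = p, fdr_mask = bh_fdr(p, q),
       n_pairs = pp$n_pairs)
}

#' Gamma-band power during laser ON vs OFF
#'
#' Per epoch, band power is the variance of the 20-40 Hz band-passed signal
#' (two-way least-squares FIR). Paired comparison across trials through the
#' normality gate: Kolmogorov-Smirnov, then paired t-test or Wilcoxon.
#'
#' @param lfp an [lfp_signal()]
#' @param laser a [laser_protocol()]
#' @param sp a [spectral_params()]
#' @param channel LFP channel
#' @return list: `power_on`, `power_off` (per-trial vectors), `report`
#'   (a [test_report()]), `ratio` (mean ON / mean OFF)
#' @export
gamma_band_power <- function(lfp, laser, sp = spectral_params(), channel = 1) {
  x <- decimate_signal(lfp_channel(lfp, channel), lfp$fs, sp$target_fs)
  fs <- sp$target_fs
  bp <- bandpass_fir(x, fs, sp$gamma_band[1], sp$gamma_band[2])
  ep_on <- laser$epochs
  ep_off <- epoch_complement(laser, sp$epoch)
  full <- ep_off$offset - ep_off$onset >= sp$epoch - 1e-9
  ep_off <- ep_off[full, , drop = FALSE]
  if (nrow(ep_off) < 5) stop("need >= 5 matched ON/OFF trial pairs")
  bandvar <- function(t0, len) {
    i0 <- floor((t0 - lfp$t0) * fs) + 1
    i1 <- i0 + round(len * fs) - 1
    mean(bp[i0:i1]^2)
  }
  p_on <- vapply(ep_off$trial, function(i)
    bandvar(ep_on$onset[i], sp$epoch), numeric(1))
  p_off <- vapply(seq_len(nrow(ep_off)), function(i)
    bandvar(ep_off$onset[i], sp$epoch), numeric(1))
  list(power_on = p_on, power_off = p_off,
       report = paired_compare(p_on, p_off),
       ratio = mean(p_on) / mean(p_off))
}
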