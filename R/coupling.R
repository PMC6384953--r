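# Spike-gamma coupling statistics: event-triggered correlograms with
# circular-shift shuffle nulls, pairwise phase consistency (PPC) and its
# spectrum, the per-event firing-rate vs gamma-magnitude correlation, and
# single-unit vs multi-unit multitaper coherence.

#' Parameters of the coupling analyses
#'
#' @param xcorr_window half-width of the event-triggered correlogram (s)
#' @param xcorr_bin correlogram bin (s)
#' @param n_event_shuffles surrogate count for the correlogram null
#' @param min_basal_rate basal-rate floor for the rate-vs-magnitude analysis (Hz)
#' @param ppc_freq_grid frequencies of the PPC spectrum (Hz)
#' @param ppc_halfwidth half-width of the per-frequency band-pass (Hz)
#' @param min_spikes_ppc minimum spikes per condition for a defined PPC
#' @return list of class `coupling_params`
#' @export
coupling_params <- function(xcorr_window = 0.5, xcorr_bin = 0.02,
                            n_event_shuffles = 500, min_basal_rate = 0.8,
                            ppc_freq_grid = seq(10, 60, by = 2),
                            ppc_halfwidth = 2, min_spikes_ppc = 50) {
  stopifnot(n_event_shuffles >= 1, min_basal_rate >= 0, xcorr_window > xcorr_bin)
  structure(as.list(environment()), class = "coupling_params")
}

#' Pairwise phase consistency
#'
#' PPC is the average cosine of the phase difference over all distinct spike
#' pairs, `2/(N(N-1)) * sum_{j<k} cos(theta_j - theta_k)`, computed through
#' the O(N) closed form `(|sum exp(i theta)|^2 - N) / (N (N-1))`. Unlike the
#' resultant length it is unbiased by spike count.
#'
#' @param phases spike phases (radians)
#' @return scalar in [-1, 1]; `NA` (flagged via attribute) when fewer than 2
#'   phases are supplied
#' @export
ppc <- function(phases) {
  n <- length(phases)
  if (n < 2) return(structure(NA_real_, undefined = TRUE))
  R2 <- Mod(sum(exp(1i * phases)))^2
  (R2 - n) / (n * (n - 1))
}

#' Event-triggered spike correlogram with a circular-shift null
#'
#' Discharge probability (spikes per trigger per bin) around gamma-event
#' reference times (event envelope peaks). The null is built from
#' `n_event_shuffles` surrogates in which all event references are circularly
#' shifted by a common uniform offset modulo the session length, preserving
#' event spacing and the spike train's autostructure. The unit is flagged
#' `coupled` when the observed central-bin probability exceeds the surrogate
#' distribution at `alpha` (one-sided empirical rank).
#'
#' @param spikes a [spike_train()]
#' @param events `gamma_events` data.frame (uses `peak_time`)
#' @param params a [coupling_params()]
#' @param alpha significance level for the coupled flag
#' @return list: `lag`, `prob` (discharge probability per bin), `coupled`,
#'   `p` (central-bin empirical p), `flag`
#' @export
spike_gamma_xcorr <- function(spikes, events, params = coupling_params(),
                              alpha = 0.05) {
  if (is.null(events) || !nrow(events)) stop("spike_gamma_xcorr: no events")
  refs <- events$peak_time
  dur <- spikes$session_duration
  w <- params$xcorr_window; b <- params$xcorr_bin
  centers <- seq(-w, w, by = b)       # one bin centered on lag 0
  nb <- length(centers)
  ts <- spikes$timestamps
  if (!length(ts)) {
    return(list(lag = centers, prob = rep(0, nb), coupled = FALSE,
                p = NA_real_, flag = "empty spike train"))
  }
  cgram <- function(ref) {
    counts <- numeric(nb)
    for (on in ref) {
      lo <- findInterval(on - w - b / 2, ts) + 1
      hi <- findInterval(on + w + b / 2 - 1e-12, ts)
      if (hi >= lo) {
        k <- floor((ts[lo:hi] - on + w + b / 2) / b) + 1
        counts <- counts + tabulate(k[k >= 1 & k <= nb], nbins = nb)
      }
    }
    counts / length(ref)              # spikes per trigger per bin
  }
  central <- function(ref) {          # central-bin probability only
    sum(findInterval(ref + b / 2 - 1e-12, ts) -
          findInterval(ref - b / 2, ts)) / length(ref)
  }
  obs <- cgram(refs)
  ctr <- which.min(abs(centers))
  sur_ctr <- numeric(params$n_event_shuffles)
  for (s in seq_len(params$n_event_shuffles)) {
    shift <- stats::runif(1, 0, dur)
    sur_ctr[s] <- central(sort((refs + shift) %% dur))
  }
  p <- (1 + sum(sur_ctr >= obs[ctr])) / (params$n_event_shuffles + 1)
  list(lag = centers, prob = obs, coupled = p <= alpha, p = p, flag = NULL)
}

#' PPC spectrum of a unit against the LFP
#'
#' For each grid frequency the LFP is zero-phase band-passed to
#' `f +/- ppc_halfwidth`, the instantaneous (analytic-signal) phase is
#' interpolated at the spike times, and the PPC of those phases is computed.
#' When ON/OFF epochs are supplied the spectrum is computed separately for
#' the spikes falling in each condition.
#'
#' @param spikes a [spike_train()]
#' @param lfp an [lfp_signal()]
#' @param params a [coupling_params()]
#' @param epochs_on,epochs_off optional epoch tables (`onset`, `offset`)
#' @param channel LFP channel
#' @return list of class `ppc_spectrum`: `freqs`, `ppc` (matrix
#'   condition x frequency with rows "all" or "off"/"on"), `n_spikes`
#' @export
ppc_spectrum <- function(spikes, lfp, params = coupling_params(),
                         epochs_on = NULL, epochs_off = NULL, channel = 1) {
  x <- lfp_channel(lfp, channel)
  fs <- lfp$fs
  ts <- spikes$timestamps
  sets <- if (is.null(epochs_on)) list(all = ts)
          else list(off = ts[in_epochs(ts, epochs_off)],
                    on = ts[in_epochs(ts, epochs_on)])
  nf <- length(params$ppc_freq_grid)
  out <- matrix(NA_real_, length(sets), nf,
                dimnames = list(names(sets), params$ppc_freq_grid))
  for (i in seq_along(params$ppc_freq_grid)) {
    f <- params$ppc_freq_grid[i]
    bp <- bandpass_fir(x, fs, max(0.5, f - params$ppc_halfwidth),
                       f + params$ppc_halfwidth, rolloff = 0.5,
                       order = 3L * round(fs / max(0.5, f - params$ppc_halfwidth)))
    phase_at <- instantaneous_phase(bp, fs, lfp$t0)
    for (k in seq_along(sets)) {
      if (length(sets[[k]]) >= max(2, params$min_spikes_ppc))
        out[k, i] <- ppc(phase_at(sets[[k]]))
    }
  }
  structure(list(freqs = params$ppc_freq_grid, ppc = out,
                 n_spikes = vapply(sets, length, integer(1))),
            class = "ppc_spectrum")
}

in_epochs <- function(times, epochs) {
  if (is.null(epochs) || !nrow(epochs)) return(rep(FALSE, length(times)))
  res <- rep(FALSE, length(times))
  for (i in seq_len(nrow(epochs)))
    res <- res | (times >= epochs$onset[i] & times < epochs$offset[i])
  res
}

#' Per-event firing rate vs gamma magnitude
#'
#' Pools the spikes of qualifying units (basal rate above `min_basal_rate`
#' and inside the population interquartile range) within each gamma event
#' `[onset, end)` and correlates the per-event rate with the event magnitude
#' (peak envelope z-score) across events (Pearson).
#'
#' @param units list of [spike_train()]
#' @param events `gamma_events` data.frame (uses `amplitude` as magnitude)
#' @param params a [coupling_params()]
#' @return list: `r`, `p`, `n_events`, `n_units`, and the per-event table
#'   `per_event` (`magnitude`, `rate`)
#' @export
rate_vs_gamma_amplitude <- function(units, events, params = coupling_params()) {
  if (nrow(events) < 3) stop("rate_vs_gamma_amplitude: need >= 3 events")
  rates <- vapply(units, `[[`, numeric(1), "basal_rate")
  q <- stats::quantile(rates, c(0.25, 0.75), names = FALSE)
  keep <- rates > params$min_basal_rate & rates >= q[1] & rates <= q[2]
  if (!any(keep)) stop("rate_vs_gamma_amplitude: no qualifying units")
  ts <- sort(unlist(lapply(units[keep], `[[`, "timestamps")))
  ep <- data.frame(onset = events$onset, offset = events$end)
  cnt <- count_in_epochs(ts, ep)
  rate <- cnt / (events$end - events$onset) / sum(keep)
  ok <- cnt > 0  # events during which qualifying neurons were active
  if (sum(ok) < 3) stop("rate_vs_gamma_amplitude: fewer than 3 active events")
  ct <- stats::cor.test(events$amplitude[ok], rate[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n_events = sum(ok),
       n_units = sum(keep),
       per_event = data.frame(magnitude = events$amplitude[ok],
                              rate = rate[ok]))
}

#' Single-unit vs multi-unit multitaper coherence
#'
#' Multi-unit activity is the summed spiking of all simultaneously recorded
#' units except the reference. Both trains are binned at `bin_fs`, coherence
#' is computed per 5-s epoch with Slepian tapers (TW = 3, 5 tapers) and
#' averaged within laser ON and paired OFF conditions; a Wilcoxon
#' signed-rank test compares conditions per frequency.
#'
#' @param unit reference [spike_train()]
#' @param other_units remaining [spike_train()] list (>= 1)
#' @param epochs_on,epochs_off paired epoch tables of equal epoch length
#' @param sp a [spectral_params()]
#' @param fmax highest frequency returned (Hz)
#' @return list: `freqs`, `coh_on`, `coh_off` (mean coherence spectra),
#'   `p` (per-frequency Wilcoxon), `fdr_mask`, `n_pairs`
#' @export
su_mu_coherence <- function(unit, other_units, epochs_on, epochs_off,
                            sp = spectral_params(), fmax = 100) {
  if (!length(other_units))
    stop("su_mu_coherence: need at least 2 simultaneously recorded units")
  bin_fs <- sp$target_fs
  epoch_len <- sp$epoch
  nseg <- round(epoch_len * bin_fs)
  bin_train <- function(ts, t0) {
    idx <- floor((ts - t0) * bin_fs) + 1
    idx <- idx[idx >= 1 & idx <= nseg]
    tabulate(idx, nbins = nseg)
  }
  mu_ts <- sort(unlist(lapply(other_units, `[[`, "timestamps")))
  V <- dpss_tapers(nseg, sp$TW, sp$K)
  freqs <- (0:(nseg - 1)) * bin_fs / nseg
  sel <- freqs > 0 & freqs <= fmax
  spectra <- function(ep) {
    lapply(seq_len(nrow(ep)), function(i) {
      a <- bin_train(unit$timestamps, ep$onset[i])
      b <- bin_train(mu_ts, ep$onset[i])
      a <- a - mean(a); b <- b - mean(b)
      Fa <- stats::mvfft(V * a); Fb <- stats::mvfft(V * b)
      list(Sab = rowMeans(Fa * Conj(Fb))[sel],
           Saa = rowMeans(Mod(Fa)^2)[sel],
           Sbb = rowMeans(Mod(Fb)^2)[sel])
    })
  }
  coh_of <- function(s) {
    den <- s$Saa * s$Sbb
    ifelse(den > 0, Mod(s$Sab)^2 / den, NA_real_)
  }
  # condition-level spectra: cross/auto spectra averaged over epochs first
  # (reduces the 1/K small-sample bias of per-epoch coherence)
  pool <- function(sl) {
    coh_of(list(Sab = Reduce(`+`, lapply(sl, `[[`, "Sab")) / length(sl),
                Saa = Reduce(`+`, lapply(sl, `[[`, "Saa")) / length(sl),
                Sbb = Reduce(`+`, lapply(sl, `[[`, "Sbb")) / length(sl)))
  }
  trial <- if ("trial" %in% names(epochs_off)) epochs_off$trial
           else seq_len(nrow(epochs_off))
  S_on <- spectra(epochs_on[trial, , drop = FALSE])
  S_off <- spectra(epochs_off)
  C_on <- do.call(rbind, lapply(S_on, coh_of))    # per-epoch, for the test
  C_off <- do.call(rbind, lapply(S_off, coh_of))
  p <- vapply(seq_len(ncol(C_on)), function(j) {
    a <- C_on[, j]; b <- C_off[, j]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3 || all(a[ok] == b[ok])) return(NA_real_)
    suppressWarnings(stats::wilcox.test(a[ok], b[ok], paired = TRUE,
                                        exact = FALSE)$p.value)
  }, numeric(1))
  list(freqs = freqs[sel], coh_on = pool(S_on), coh_off = pool(S_off),
       coh_on_epochs = C_on, coh_off_epochs = C_off, p = p,
       fdr_mask = bh_fdr(ifelse(is.na(p), 1, p), 0.05), n_pairs = nrow(C_on))
}
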