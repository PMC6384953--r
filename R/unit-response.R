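# Classification of single units by their photostimulation response:
# peri-event time histograms, the sliding-sweeps permutation test (basal-rate
# normalized event-aligned template against interval-shuffled surrogates),
# paired ON/OFF rate comparison, photoinhibition latency, and population
# summaries.

#' Parameters of the sliding-sweeps analysis
#'
#' @param window half-width of the event-aligned window (s)
#' @param bin bin width (s)
#' @param n_shuffles surrogate count
#' @param alpha per-bin significance level
#' @return list of class `sliding_sweeps_params`
#' @export
sliding_sweeps_params <- function(window = 15, bin = 0.5, n_shuffles = 100,
                                  alpha = 0.01) {
  stopifnot(window > bin, bin > 0, n_shuffles >= 1, alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "sliding_sweeps_params")
}

#' Peri-event time histogram
#'
#' Per-bin spike counts averaged over trials and converted to Hz. Lag 0 sits
#' at the event onset; bins are half-open. Windows truncated by the session
#' edges contribute only to the bins they cover (per-bin valid-trial
#' normalization).
#'
#' @param spikes a [spike_train()]
#' @param onsets event/stimulus onset times (s)
#' @param window half-width (s)
#' @param bin bin width (s)
#' @return data.frame `lag` (bin centers, s), `rate` (Hz), `n_trials`
#'   (valid trials per bin); attribute `empty` flags an empty spike train
#' @export
peri_event_histogram <- function(spikes, onsets, window = 15, bin = 0.5) {
  if (!length(onsets)) stop("peri_event_histogram: need at least one onset")
  edges <- seq(-window, window, by = bin)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  dur <- spikes$session_duration
  ts <- spikes$timestamps
  for (on in onsets) {
    lo <- findInterval(on - window, ts) + 1          # first spike >= on - window
    hi <- findInterval(on + window - 1e-12, ts)      # last spike  <  on + window
    if (hi >= lo) {
      b <- floor((ts[lo:hi] - on + window) / bin) + 1
      counts <- counts + tabulate(b[b >= 1 & b <= nb], nbins = nb)
    }
  }
  # a bin is valid for a trial if it lies fully inside the session
  valid <- colSums(outer(onsets, edges[-1], `+`) <= dur + 1e-12 &
                     outer(onsets, edges[-nb - 1], `+`) >= -1e-12)
  rate <- ifelse(valid > 0, counts / (valid * bin), 0)
  structure(data.frame(lag = edges[-1] - bin / 2, rate = rate, n_trials = valid),
            empty = length(spikes$timestamps) == 0)
}

# randomized exchange of inter-event intervals, anchored at the first time
shuffle_intervals <- function(times) {
  if (length(times) < 3) return(times)
  isi <- diff(times)
  times[1] + c(0, cumsum(sample(isi)))
}

#' Sliding-sweeps event-aligned template with permutation significance
#'
#' The template is the event-aligned spike rate in `bin`-wide bins over a
#' +/- `window` span, normalized to the unit's basal firing rate. The null is
#' built by shuffling the inter-spike intervals of the train and the
#' inter-onset intervals of the stimulus sequence (both by randomized
#' exchange of the original intervals) `n_shuffles` times. A bin is
#' significant when its observed value is more extreme than all surrogates
#' in absolute deviation from the surrogate median (two-sided empirical rank;
#' with 100 surrogates the attained level is 1/101 < 0.01).
#'
#' @param spikes a [spike_train()]
#' @param onsets stimulus onset times (s)
#' @param params a [sliding_sweeps_params()]
#' @return list: `lag`, `template` (rate ratio per bin), `significant`
#'   (logical mask), `p` (per-bin empirical p), `undefined` flag
#' @export
sliding_sweeps <- function(spikes, onsets, params = sliding_sweeps_params()) {
  stopifnot(inherits(params, "sliding_sweeps_params"))
  if (spikes$session_duration < 2 * params$window)
    stop("session shorter than the sliding-sweeps window")
  peth <- peri_event_histogram(spikes, onsets, params$window, params$bin)
  if (length(spikes$timestamps) < 2 || spikes$basal_rate == 0)
    return(list(lag = peth$lag, template = rep(NA_real_, nrow(peth)),
                significant = rep(FALSE, nrow(peth)),
                p = rep(NA_real_, nrow(peth)), undefined = TRUE))
  obs <- peth$rate / spikes$basal_rate
  nb <- length(obs)
  sur <- matrix(0, params$n_shuffles, nb)
  for (s in seq_len(params$n_shuffles)) {
    st <- shuffle_intervals(spikes$timestamps)
    ot <- sort(shuffle_intervals(onsets))
    sp <- spike_train(spikes$unit_id, sort(st), spikes$session_duration)
    sur[s, ] <- peri_event_histogram(sp, ot, params$window, params$bin)$rate /
      spikes$basal_rate
  }
  med <- apply(sur, 2, stats::median)
  dev_obs <- abs(obs - med)
  dev_sur <- abs(sweep(sur, 2, med))
  p <- vapply(seq_len(nb), function(j)
    (1 + sum(dev_sur[, j] >= dev_obs[j])) / (params$n_shuffles + 1), numeric(1))
  list(lag = peth$lag, template = obs, significant = p <= params$alpha, p = p,
       undefined = FALSE)
}

#' Classify a unit's photostimulation response
#'
#' Per-trial spike counts during laser ON epochs are compared with counts in
#' the paired pre-onset OFF windows (two-sided Wilcoxon signed-rank at
#' `alpha`). A significant decrease labels the unit `suppressed` (SOM+ by
#' photoinhibition), a significant increase `excited`, otherwise
#' `unaffected`. Modulation is `100 * (rate_off - rate_on) / rate_off` for
#' suppressed units and `100 * (rate_on - rate_off) / rate_off` for excited
#' units; a silent OFF condition leaves it undefined and the unit flagged.
#'
#' @param spikes a [spike_train()]
#' @param laser a [laser_protocol()]
#' @param alpha test level
#' @param latency_bin bin width for the latency estimate (s)
#' @return list of class `unit_classification`: `unit_id`, `label`,
#'   `modulation_pct`, `latency`, `p`, `rate_on`, `rate_off`, `n_trials`,
#'   `flag`
#' @export
classify_unit <- function(spikes, laser, alpha = 0.05, latency_bin = 0.01) {
  ep_on <- laser$epochs
  if (!nrow(ep_on)) stop("classify_unit: no laser epochs")
  pre <- min(ep_on$offset - ep_on$onset)
  ep_off <- epoch_complement(laser, pre)
  keep <- ep_off$trial
  if (length(keep) < 10)
    warning("classify_unit: fewer than 10 usable laser trials")
  c_on <- count_in_epochs(spikes$timestamps, ep_on[keep, , drop = FALSE])
  c_off <- count_in_epochs(spikes$timestamps, ep_off)
  # normalize to rates in case clipped OFF windows differ in length
  r_on <- c_on / (ep_on$offset - ep_on$onset)[keep]
  r_off <- c_off / (ep_off$offset - ep_off$onset)
  rate_on <- mean(r_on); rate_off <- mean(r_off)
  rep <- paired_compare(r_on, r_off)
  flag <- NULL
  if (rate_off == 0 && rate_on == 0) {
    label <- "unaffected"; mod <- NA_real_; flag <- "silent unit"
  } else if (rate_off == 0) {
    label <- "unaffected"; mod <- NA_real_
    flag <- "no OFF-epoch spikes: modulation undefined"
  } else if (rep$p < alpha && rate_on < rate_off) {
    label <- "suppressed"; mod <- 100 * (rate_off - rate_on) / rate_off
  } else if (rep$p < alpha && rate_on > rate_off) {
    label <- "excited"; mod <- 100 * (rate_on - rate_off) / rate_off
  } else {
    label <- "unaffected"; mod <- NA_real_
  }
  lat <- if (label == "suppressed")
    suppression_latency(spikes, ep_on$onset[keep], bin = latency_bin,
                        .checked = TRUE)
  else NA_real_
  structure(list(unit_id = spikes$unit_id, label = label,
                 modulation_pct = mod, latency = lat, p = rep$p,
                 rate_on = rate_on, rate_off = rate_off,
                 n_trials = length(keep), flag = flag),
            class = "unit_classification")
}

#' Latency of photoinhibition
#'
#' Fine-binned PETH around laser onsets; the latency is the first post-onset
#' time at which the rate stays below `baseline mean - 2 SD` for at least 3
#' consecutive bins (baseline = the pre-onset half of the window). `NA` if
#' the threshold is never crossed.
#'
#' @param spikes a [spike_train()]
#' @param onsets laser onset times (s)
#' @param bin bin width (s)
#' @param window half-width (s) of the PETH
#' @param .checked internal: skip the suppressed-unit precondition
#' @return latency (s) or `NA`
#' @export
suppression_latency <- function(spikes, onsets, bin = 0.01, window = 2,
                                .checked = FALSE) {
  if (!.checked) {
    cl <- tryCatch(classify_unit(spikes,
                                 laser_protocol(data.frame(onset = onsets,
                                                           offset = onsets + window),
                                                "continuous_pulse")),
                   error = function(e) NULL)
    if (is.null(cl) || cl$label != "suppressed")
      stop("suppression_latency: unit is not suppressed")
  }
  peth <- peri_event_histogram(spikes, onsets, window, bin)
  base <- peth$rate[peth$lag < 0]
  thr <- mean(base) - 2 * stats::sd(base)
  post <- which(peth$lag > 0)
  below <- peth$rate[post] < thr
  run <- rle(below)
  ends <- cumsum(run$lengths)
  hit <- which(run$values & run$lengths >= 3)
  if (!length(hit)) return(NA_real_)
  first <- ends[hit[1]] - run$lengths[hit[1]] + 1
  peth$lag[post[first]] - bin / 2  # left edge of the first sub-threshold bin
}

#' Population summary of unit classifications
#'
#' @param classifications list of [classify_unit()] results
#' @return data.frame: `label`, `n`, `pct` (percentages sum to 100 up to
#'   rounding)
#' @export
population_summary <- function(classifications) {
  if (!length(classifications)) stop("population_summary: need >= 1 unit")
  lab <- vapply(classifications, `[[`, "", "label")
  lev <- c("suppressed", "excited", "unaffected")
  n <- vapply(lev, function(l) sum(lab == l), numeric(1))
  data.frame(label = lev, n = as.integer(n),
             pct = round(100 * n / sum(n), 1), row.names = NULL)
}
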