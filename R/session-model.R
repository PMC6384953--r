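# Data model for a recording session: continuous LFP, sorted spike trains,
# laser stimulation epochs and optional behavioral streams. All times are in
# seconds, zero-based at session start; intervals are half-open [onset, offset)
# so spike-in-epoch membership is unambiguous.

#' Continuous LFP signal
#'
#' @param samples numeric matrix (samples x channels) or vector, in mV
#' @param fs sampling rate (Hz), > 0
#' @param t0 time of the first sample (s)
#' @param channel_ids optional channel labels
#' @return an object of class `lfp_signal`
#' @export
lfp_signal <- function(samples, fs, t0 = 0, channel_ids = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("invalid LFP field 'fs': must be a single positive number")
  if (nrow(samples) < 1) stop("invalid LFP field 'samples': length >= 1 required")
  if (!all(is.finite(samples))) stop("invalid LFP field 'samples': must be finite")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(ncol(samples)))
  structure(list(samples = samples, fs = fs, t0 = t0,
                 channel_ids = as.character(channel_ids)),
            class = "lfp_signal")
}

#' @export
print.lfp_signal <- function(x, ...) {
  cat(sprintf("<lfp_signal> %d samples x %d channel(s), fs = %g Hz, %.1f s\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}

# duration in seconds
lfp_duration <- function(lfp) nrow(lfp$samples) / lfp$fs

# extract one channel as a numeric vector
lfp_channel <- function(lfp, channel = 1) {
  if (is.character(channel)) channel <- match(channel, lfp$channel_ids)
  lfp$samples[, channel]
}

#' Sorted single-unit spike train
#'
#' @param unit_id unit label
#' @param timestamps strictly increasing spike times (s)
#' @param session_duration session length (s)
#' @return an object of class `spike_train`; `$basal_rate` is count/duration
#' @export
spike_train <- function(unit_id, timestamps, session_duration) {
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0))
    stop("invalid spike_train field 'timestamps': must be strictly increasing (unit ",
         unit_id, ")")
  if (length(timestamps) &&
      (min(timestamps) < 0 || max(timestamps) > session_duration))
    stop("invalid spike_train field 'timestamps': outside [0, session_duration] (unit ",
         unit_id, ")")
  structure(list(unit_id = as.character(unit_id), timestamps = timestamps,
                 session_duration = session_duration,
                 basal_rate = length(timestamps) / session_duration),
            class = "spike_train")
}

#' Laser stimulation protocol
#'
#' @param epochs data.frame with columns `onset`, `offset` (s), sorted and
#'   non-overlapping
#' @param kind `"continuous_pulse"` (e.g. 5 s ON every 20 s) or
#'   `"pulse_train"` (trains of brief pulses)
#' @param power_label free-text power annotation
#' @return an object of class `laser_protocol`
#' @export
laser_protocol <- function(epochs, kind = c("continuous_pulse", "pulse_train"),
                           power_label = "") {
  kind <- match.arg(kind)
  epochs <- as.data.frame(epochs)[, c("onset", "offset")]
  if (nrow(epochs)) {
    if (any(epochs$offset <= epochs$onset))
      stop("invalid laser_protocol field 'epochs': offset must exceed onset")
    if (is.unsorted(epochs$onset, strictly = TRUE) ||
        any(epochs$onset[-1] < epochs$offset[-nrow(epochs)]))
      stop("invalid laser_protocol field 'epochs': must be sorted and non-overlapping")
  }
  structure(list(epochs = epochs, kind = kind, power_label = power_label),
            class = "laser_protocol")
}

#' Open-field tracking trace
#'
#' @param t frame times (s), uniformly spaced at 1/fps
#' @param x,y positions (cm)
#' @param fps frame rate (Hz)
#' @return an object of class `behavior_track`
#' @export
behavior_track <- function(t, x, y, fps = 30) {
  if (length(t) > 1 && max(abs(diff(t) - 1 / fps)) > 1e-6)
    stop("invalid behavior_track field 't': frames not uniform at 1/fps")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("invalid behavior_track field 'x'/'y': positions must be finite")
  structure(list(t = t, x = x, y = y, fps = fps), class = "behavior_track")
}

#' Y-maze arm-entry sequence
#'
#' An entry implies an arm change, so consecutive identical arms are invalid;
#' use [collapse_entries()] to clean raw detections first.
#'
#' @param t entry times (s), increasing
#' @param arm arm labels (e.g. "A","B","C")
#' @return an object of class `arm_entries`
#' @export
arm_entries <- function(t, arm) {
  arm <- as.character(arm)
  if (length(t) != length(arm)) stop("invalid arm_entries: t/arm length mismatch")
  if (length(t) > 1 && any(diff(t) <= 0))
    stop("invalid arm_entries field 't': times must be increasing")
  if (length(arm) > 1 && any(arm[-1] == arm[-length(arm)]))
    stop("invalid arm_entries field 'arm': consecutive identical arms")
  structure(list(t = t, arm = arm), class = "arm_entries")
}

#' Collapse consecutive same-arm detections into single entries
#' @param t detection times (s)
#' @param arm arm labels
#' @return an `arm_entries` object
#' @export
collapse_entries <- function(t, arm) {
  arm <- as.character(arm)
  keep <- c(TRUE, arm[-1] != arm[-length(arm)])
  arm_entries(t[keep], arm[keep])
}

#' A complete recording session
#'
#' @param lfp an [lfp_signal()]
#' @param units list of [spike_train()]
#' @param laser a [laser_protocol()]
#' @param behavior optional [behavior_track()]
#' @param ymaze optional [arm_entries()]
#' @param meta list; recognized fields: `region` ("VP"/"MS"), `genotype`
#'   ("NpHR+"/"NpHR-")
#' @return an object of class `recording_session`
#' @export
recording_session <- function(lfp, units, laser, behavior = NULL, ymaze = NULL,
                              meta = list()) {
  stopifnot(inherits(lfp, "lfp_signal"), inherits(laser, "laser_protocol"))
  dur <- lfp_duration(lfp)
  if (nrow(laser$epochs) && max(laser$epochs$offset) > dur + 1e-9)
    stop("invalid recording_session: laser epochs extend past session end")
  for (u in units) stopifnot(inherits(u, "spike_train"))
  structure(list(lfp = lfp, units = units, laser = laser, behavior = behavior,
                 ymaze = ymaze, meta = meta),
            class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session> %.1f s, %d unit(s), %d laser epoch(s)%s\n",
              lfp_duration(x$lfp), length(x$units), nrow(x$laser$epochs),
              if (!is.null(x$meta$region)) paste0(", region ", x$meta$region) else ""))
  invisible(x)
}

# ---- On-disk layout -------------------------------------------------------
# lfp.bin   flat little-endian float64, sample-major (channel index fastest)
# lfp.json  {fs, n_channels, t0, channel_ids, units: "mV", dtype: "float64"}
# spikes.tsv  unit_id <tab> t
# laser.tsv   onset <tab> offset   (+ kind/power in meta.json)
# track.tsv   t <tab> x <tab> y
# ymaze.tsv   t <tab> arm
# meta.json   region, genotype, laser_kind, laser_power, session_duration

#' Write a recording session to a directory
#'
#' @param session a [recording_session()]
#' @param path target directory (created if missing)
#' @return `path`, invisibly
#' @seealso [read_session()]
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "recording_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create session directory: ", path)
  lfp <- session$lfp
  con <- file(file.path(path, "lfp.bin"), "wb")
  writeBin(as.numeric(t(lfp$samples)), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(list(fs = lfp$fs, n_channels = ncol(lfp$samples),
                            t0 = lfp$t0, channel_ids = lfp$channel_ids,
                            units = "mV", dtype = "float64"),
                       file.path(path, "lfp.json"), auto_unbox = TRUE, digits = NA)
  spk <- data.table::rbindlist(lapply(session$units, function(u)
    data.table::data.table(unit_id = u$unit_id, t = u$timestamps)))
  if (!nrow(spk)) spk <- data.table::data.table(unit_id = character(), t = numeric())
  data.table::fwrite(spk, file.path(path, "spikes.tsv"), sep = "\t")
  data.table::fwrite(session$laser$epochs, file.path(path, "laser.tsv"), sep = "\t")
  if (!is.null(session$behavior))
    data.table::fwrite(data.table::data.table(t = session$behavior$t,
                                              x = session$behavior$x,
                                              y = session$behavior$y),
                       file.path(path, "track.tsv"), sep = "\t")
  if (!is.null(session$ymaze))
    data.table::fwrite(data.table::data.table(t = session$ymaze$t,
                                              arm = session$ymaze$arm),
                       file.path(path, "ymaze.tsv"), sep = "\t")
  meta <- session$meta
  meta$laser_kind <- session$laser$kind
  meta$laser_power <- session$laser$power_label
  meta$session_duration <- lfp_duration(lfp)
  meta$unit_ids <- vapply(session$units, `[[`, "", "unit_id")
  meta$behavior_fps <- if (!is.null(session$behavior)) session$behavior$fps else NULL
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a recording session from a directory
#'
#' Validates every component; an invariant violation raises an error naming
#' the offending field.
#'
#' @param path directory written by [write_session()]
#' @return a [recording_session()]
#' @export
read_session <- function(path) {
  need <- function(f) {
    p <- file.path(path, f)
    if (!file.exists(p)) stop("missing session file: ", f, " (in ", path, ")")
    p
  }
  side <- jsonlite::read_json(need("lfp.json"), simplifyVector = TRUE)
  if (is.null(side$fs) || !is.numeric(side$fs) || side$fs <= 0)
    stop("invalid LFP field 'fs' in lfp.json")
  side$fs <- as.numeric(side$fs)
  side$t0 <- as.numeric(side$t0 %||% 0)
  nch <- as.integer(side$n_channels %||% 1)
  sz <- file.info(need("lfp.bin"))$size
  n <- sz / 8 / nch
  con <- file(file.path(path, "lfp.bin"), "rb")
  raw <- readBin(con, "double", n = n * nch, size = 8, endian = "little")
  close(con)
  samples <- matrix(raw, ncol = nch, byrow = TRUE)
  lfp <- lfp_signal(samples, side$fs, side$t0 %||% 0, side$channel_ids)
  meta <- jsonlite::read_json(need("meta.json"), simplifyVector = TRUE)
  dur <- meta$session_duration %||% lfp_duration(lfp)
  spk <- data.table::fread(need("spikes.tsv"), sep = "\t",
                           colClasses = list(character = "unit_id"))
  ids <- meta$unit_ids %||% unique(spk$unit_id)
  units <- lapply(ids, function(id)
    spike_train(id, spk$t[spk$unit_id == id], dur))
  las <- data.table::fread(need("laser.tsv"), sep = "\t")
  laser <- laser_protocol(as.data.frame(las), meta$laser_kind %||% "continuous_pulse",
                          meta$laser_power %||% "")
  behavior <- NULL
  if (file.exists(file.path(path, "track.tsv"))) {
    tr <- data.table::fread(file.path(path, "track.tsv"), sep = "\t")
    behavior <- behavior_track(tr$t, tr$x, tr$y, meta$behavior_fps %||% 30)
  }
  ymaze <- NULL
  if (file.exists(file.path(path, "ymaze.tsv"))) {
    ym <- data.table::fread(file.path(path, "ymaze.tsv"), sep = "\t",
                            colClasses = list(character = "arm"))
    ymaze <- arm_entries(ym$t, ym$arm)
  }
  meta$laser_kind <- meta$laser_power <- meta$session_duration <- NULL
  meta$unit_ids <- meta$behavior_fps <- NULL
  recording_session(lfp, units, laser, behavior, ymaze, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pre-onset OFF windows paired to laser ON epochs
#'
#' For each ON epoch, returns the immediately preceding OFF window of length
#' `pre_window`, clipped so it never overlaps an earlier ON epoch or extends
#' before the session start. Windows clipped to zero width are dropped and
#' flagged in the `"empty"` attribute.
#'
#' @param laser a [laser_protocol()]
#' @param pre_window window length (s), > 0
#' @return data.frame with columns `onset`, `offset`, `trial` (index of the
#'   paired ON epoch); attribute `empty` lists ON epochs whose OFF window
#'   vanished
#' @export
epoch_complement <- function(laser, pre_window) {
  if (!is.numeric(pre_window) || length(pre_window) != 1 || pre_window <= 0)
    stop("pre_window must be a positive scalar")
  ep <- laser$epochs
  n <- nrow(ep)
  if (!n) return(structure(data.frame(onset = numeric(), offset = numeric(),
                                      trial = integer()), empty = integer()))
  lo <- pmax(ep$onset - pre_window, c(0, ep$offset[-n]))
  lo <- pmax(lo, 0)
  hi <- ep$onset
  keep <- hi - lo > 1e-12
  structure(data.frame(onset = lo[keep], offset = hi[keep],
                       trial = which(keep)),
            empty = which(!keep))
}

# count points falling in half-open intervals [onset, offset)
count_in_epochs <- function(times, epochs) {
  if (!nrow(epochs)) return(integer())
  vapply(seq_len(nrow(epochs)), function(i)
    sum(times >= epochs$onset[i] & times < epochs$offset[i]), integer(1))
}

# total length of a set of epochs
epoch_total <- function(epochs) sum(epochs$offset - epochs$onset)
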