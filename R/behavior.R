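# Behavioral analyses around optogenetic stimulation: locomotor speed from
# 30-FPS tracking with rest/run stratification, laser-train-triggered speed
# averages, Y-maze spontaneous alternation scoring, and gated group
# comparisons.

#' Locomotor speed from a tracking trace
#'
#' Frame-to-frame speed (`fps * Euclidean displacement`), moving-average
#' smoothed, with a rest/run state per frame: rest is smoothed speed below
#' `rest_thresh` sustained for at least `rest_min_s` seconds.
#'
#' @param track a [behavior_track()]
#' @param smooth_window moving-average width (frames)
#' @param rest_thresh rest threshold (cm/s)
#' @param rest_min_s minimum sub-threshold duration counted as rest (s)
#' @return data.frame of class `speed_series`: `t`, `speed` (cm/s), `state`
#'   ("rest"/"run")
#' @export
compute_speed <- function(track, smooth_window = 5, rest_thresh = 1,
                          rest_min_s = 1) {
  stopifnot(inherits(track, "behavior_track"))
  n <- length(track$t)
  if (n < 2) stop("compute_speed: need >= 2 frames")
  if (max(abs(diff(track$t) - 1 / track$fps)) > 1e-6)
    stop("compute_speed: non-uniform frame times")
  v <- track$fps * sqrt(diff(track$x)^2 + diff(track$y)^2)
  v <- c(v[1], v)                              # align to frames
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    v <- stats::filter(v, k, sides = 2)
    v <- as.numeric(v)
    v[is.na(v)] <- 0
  }
  below <- v < rest_thresh
  r <- rle(below)
  state <- rep("run", n)
  ends <- cumsum(r$lengths)
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] >= rest_min_s * track$fps)
      state[(ends[i] - r$lengths[i] + 1):ends[i]] <- "rest"
  }
  structure(data.frame(t = track$t, speed = v, state = state),
            class = c("speed_series", "data.frame"))
}

#' Laser-train-triggered speed average
#'
#' Speed segments aligned at train onsets, filtered by the animal's state at
#' onset, averaged across triggers with standard errors.
#'
#' @param speed a `speed_series` from [compute_speed()]
#' @param onsets train onset times (s); see [train_onsets()] for extraction
#'   from a pulse-train protocol
#' @param window half-width (s)
#' @param state_filter "rest", "run" or NULL (all triggers)
#' @return list: `lag` (s), `mean`, `se` (NA with a single trigger), `n`,
#'   `segments` (matrix trigger x lag); `flag` when no trigger qualifies
#' @export
laser_triggered_speed <- function(speed, onsets, window = 10,
                                  state_filter = "rest") {
  fps <- 1 / stats::median(diff(speed$t))
  nlag <- round(window * fps)
  lag <- (-nlag:nlag) / fps
  qual <- vapply(onsets, function(on) {
    i <- which.min(abs(speed$t - on))
    i - nlag >= 1 && i + nlag <= nrow(speed) &&
      (is.null(state_filter) || speed$state[i] == state_filter)
  }, logical(1))
  if (!any(qual))
    return(list(lag = lag, mean = rep(NA_real_, length(lag)), se = NA, n = 0,
                segments = NULL, flag = "no qualifying triggers"))
  segs <- t(vapply(onsets[qual], function(on) {
    i <- which.min(abs(speed$t - on))
    speed$speed[(i - nlag):(i + nlag)]
  }, numeric(length(lag))))
  list(lag = lag, mean = colMeans(segs),
       se = if (nrow(segs) > 1) apply(segs, 2, stats::sd) / sqrt(nrow(segs))
            else rep(NA_real_, length(lag)),
       n = nrow(segs), segments = segs, flag = NULL)
}

#' Y-maze spontaneous alternation index
#'
#' A sliding window of 3 consecutive entries counts as a correct alternation
#' iff its three arms are all distinct; the index is
#' `100 * alternations / (entries - 2)`. With `block` set, a per-block time
#' course is computed over disjoint (default) or overlapping blocks of that
#' length.
#'
#' @param entries an [arm_entries()] sequence
#' @param block optional block length (s) for the time course
#' @param overlap logical; overlapping blocks stepped by `block/2`
#' @return list of class `alternation_result`: `index` (%), `n_entries`,
#'   `n_alternations`, `time_course` (data.frame block start/index or NULL),
#'   `flag` when fewer than 3 entries make the index undefined
#' @export
alternation_index <- function(entries, block = NULL, overlap = FALSE) {
  stopifnot(inherits(entries, "arm_entries"))
  arms <- entries$arm
  n <- length(arms)
  score <- function(a) {
    m <- length(a)
    if (m < 3) return(c(NA_real_, m, 0))
    alt <- vapply(3:m, function(i) length(unique(a[(i - 2):i])) == 3, logical(1))
    c(100 * sum(alt) / (m - 2), m, sum(alt))
  }
  s <- score(arms)
  tc <- NULL
  if (!is.null(block) && n >= 3) {
    t0 <- entries$t[1]
    starts <- seq(t0, max(entries$t), by = if (overlap) block / 2 else block)
    tc <- do.call(rbind, lapply(starts, function(b0) {
      in_b <- entries$t >= b0 & entries$t < b0 + block
      if (sum(in_b) < 3) return(NULL)
      data.frame(block_start = b0, index = score(arms[in_b])[1])
    }))
  }
  structure(list(index = s[1], n_entries = as.integer(s[2]),
                 n_alternations = as.integer(s[3]), time_course = tc,
                 flag = if (n < 3) "fewer than 3 entries: index undefined"),
            class = "alternation_result")
}

#' Group comparison with normality gate
#'
#' Two groups: KS-gated t-test or Wilcoxon rank-sum (or their paired
#' versions). Three or more: one-way ANOVA followed by pairwise Tukey when
#' every group passes the gate, otherwise Kruskal-Wallis followed by pairwise
#' Mann-Whitney contrasts.
#'
#' @param values named list of numeric vectors, one per group
#' @param paired logical; only valid for two equal-length groups
#' @return list: `test` (a [test_report()]), `pairwise` (data.frame of
#'   contrasts or NULL), `normal` (gate outcome)
#' @export
group_comparison <- function(values, paired = FALSE) {
  if (length(values) < 2) stop("group_comparison: need >= 2 groups")
  if (any(vapply(values, length, 1L) < 2))
    stop("group_comparison: every group needs >= 2 values")
  if (is.null(names(values))) names(values) <- paste0("g", seq_along(values))
  normal <- all(vapply(values, function(v) isTRUE(ks_normal(v)$normal),
                       logical(1)))
  if (length(values) == 2) {
    a <- values[[1]]; b <- values[[2]]
    if (paired) return(list(test = paired_compare(a, b), pairwise = NULL,
                            normal = normal))
    ht <- if (normal) stats::t.test(a, b)
          else suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    return(list(test = test_report(if (normal) "t" else "mann_whitney",
                                   unname(ht$statistic), ht$p.value,
                                   length(a) + length(b)),
                pairwise = NULL, normal = normal))
  }
  g <- factor(rep(names(values), lengths(values)), levels = names(values))
  y <- unlist(values, use.names = FALSE)
  if (normal) {
    fit <- stats::aov(y ~ g)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    pw <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                     p = tk[, "p adj"], row.names = NULL)
    list(test = test_report("one_way_anova", an[1, "F value"], an[1, "Pr(>F)"],
                            length(y)),
         pairwise = pw, normal = TRUE)
  } else {
    kw <- stats::kruskal.test(y, g)
    cmb <- utils::combn(names(values), 2)
    pw <- data.frame(
      contrast = apply(cmb, 2, paste, collapse = "-"),
      p = apply(cmb, 2, function(pr)
        suppressWarnings(stats::wilcox.test(values[[pr[1]]], values[[pr[2]]],
                                            exact = FALSE)$p.value)))
    pw$p_adj <- stats::p.adjust(pw$p, "BH")
    list(test = test_report("kruskal_wallis", unname(kw$statistic),
                            kw$p.value, length(y)),
         pairwise = pw, normal = FALSE)
  }
}
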