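#' Delineation window defaults
#'
#' Search-window defaults for beat delineation, chosen per species: mouse
#' beats (RR ~ 100-200 ms) need an order of magnitude tighter windows than
#' human beats (RR ~ 600-1300 ms). All values are in milliseconds and can be
#' overridden individually.
#'
#' @param species `"mouse"` or `"human"`.
#' @param ... Named overrides of individual window values.
#' @return A list with elements `p_search_ms` (P search span before R),
#'   `qrs_half_ms` (Q/S search half-width around R), `s_search_ms`,
#'   `t_frac_rr` (upper T-search bound as a fraction of RR),
#'   `refractory_ms` (R-detection refractory period), `rr_default_ms`,
#'   `smooth_ms` and `smooth_qrs_ms` (moving-average widths used for
#'   landmark detection on the low-amplitude P/T waves and on the
#'   large-amplitude QRS complex respectively, so threshold crossings are
#'   not dominated by sample noise).
#' @export
delineation_windows <- function(species = c("mouse", "human"), ...) {
  species <- match.arg(species)
  w <- if (species == "mouse") {
    list(p_search_ms = 50, qrs_half_ms = 15, s_search_ms = 15,
         t_frac_rr = 0.75, refractory_ms = 50, rr_default_ms = 120,
         smooth_ms = 1.5, smooth_qrs_ms = 0.5)
  } else {
    list(p_search_ms = 300, qrs_half_ms = 60, s_search_ms = 80,
         t_frac_rr = 0.60, refractory_ms = 250, rr_default_ms = 857,
         smooth_ms = 14, smooth_qrs_ms = 2)
  }
  modifyList(w, list(...))
}

# smoothed copies used for landmark detection
delineation_signals <- function(record, windows) {
  fs <- record$sampling_rate
  list(pt = smooth_ma(record$samples, round(windows$smooth_ms * fs / 1000)),
       qrs = smooth_ma(record$samples,
                       round(windows$smooth_qrs_ms * fs / 1000)))
}

# centered moving average (odd window), replicate-padded at the edges
smooth_ma <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width <= 1L) return(x)
  half <- width %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / width, width),
                           sides = 2))[(half + 1L):(half + length(x))]
}

#' Detect R peaks in a filtered ECG
#'
#' Amplitude-threshold detector: candidate local maxima above a fraction of
#' the global maximum are accepted greedily by height, with a refractory
#' window preventing double detection of one beat.
#'
#' @param record An [ecg_record()] (high-pass filtered; see
#'   [highpass_baseline()]).
#' @param min_height_frac Candidate threshold as a fraction of the maximum
#'   baseline-corrected amplitude (default 0.5).
#' @param windows Delineation windows, see [delineation_windows()]; only
#'   `refractory_ms` is used here.
#' @return Integer vector of R-peak sample indices (1-based), sorted. Empty
#'   (with a warning) if no usable peaks are found.
#' @export
detect_r_peaks <- function(record, min_height_frac = 0.5, windows = NULL) {
  stopifnot_msg(inherits(record, "ecg_record"), "record must be an ecg_record")
  if (is.null(windows)) windows <- delineation_windows(record$species_hint)
  x <- record$samples - median(record$samples)
  n <- length(x)
  top <- max(x)
  if (!(top > 0) || top < 10 * stats::mad(x, constant = 1.4826) / 5 &&
      top < 1e-9) {
    warning("no R peaks found (flat or peak-free signal)")
    return(integer(0))
  }
  thr <- min_height_frac * top
  cand <- which(x > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[x[cand] >= x[cand - 1L] & x[cand] > x[cand + 1L]]
  if (!length(cand)) {
    warning("no R peaks found above threshold")
    return(integer(0))
  }
  refr <- round(windows$refractory_ms * record$sampling_rate / 1000)
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) > refr)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Delineate one beat around an R peak
#'
#' Applies the study's interval-measurement rules to a single beat:
#' \itemize{
#'   \item P onset: first point, scanning back from the P peak, where the
#'     P deflection has fallen to 10\% of its height above the isoelectric
#'     line (linearly interpolated).
#'   \item Isoelectric level: median of a 10-ms window ending 5 ms before
#'     the P onset.
#'   \item Q onset: 10\%-of-trough backward crossing from the Q trough
#'     (QRS interval start).
#'   \item S end: point where the S wave recrosses the isoelectric line.
#'   \item T end: first point after the T peak where the T wave has
#'     completed 90\% of its decline, i.e. fallen to 10\% of the T-peak
#'     height above the isoelectric line.
#' }
#' Fiducials that cannot be located (e.g. an absent P wave) are returned as
#' `NA`; downstream averaging skips them.
#'
#' @param record An [ecg_record()].
#' @param r_peak R-peak sample index (1-based), e.g. from
#'   [detect_r_peaks()].
#' @param windows See [delineation_windows()].
#' @param next_r Optional next R-peak index, used to bound the T search.
#' @param smoothed Optional precomputed smoothed signal (internal use by
#'   [delineate_ecg()], which smooths once for all beats).
#' @return A one-row data.frame with times in ms: `p_onset_ms`, `r_peak_ms`,
#'   `q_onset_ms`, `s_end_ms`, `t_peak_ms`, `t_end90_ms`, `iso_mV`,
#'   `t_peak_mV`.
#' @export
delineate_beat <- function(record, r_peak, windows = NULL, next_r = NA,
                           smoothed = NULL) {
  stopifnot_msg(inherits(record, "ecg_record"), "record must be an ecg_record")
  if (is.null(windows)) windows <- delineation_windows(record$species_hint)
  # low-amplitude P/T landmarks are located on a smoothed copy so the
  # 10%-height threshold crossings are not dominated by sample noise; the
  # large-amplitude QRS landmarks use a much lighter smoothing to avoid
  # widening the narrow Q/R/S deflections
  if (is.null(smoothed)) smoothed <- delineation_signals(record, windows)
  v <- smoothed$pt
  vq <- smoothed$qrs
  fs <- record$sampling_rate
  dt <- 1000 / fs
  t <- ecg_time_ms(record)
  n <- length(v)
  idx <- function(ms) max(1L, min(n, as.integer(round(ms / dt)) + 1L))
  r_ms <- t[r_peak]

  out <- data.frame(p_onset_ms = NA_real_, r_peak_ms = r_ms,
                    q_onset_ms = NA_real_, s_end_ms = NA_real_,
                    t_peak_ms = NA_real_, t_end90_ms = NA_real_,
                    iso_mV = NA_real_, iso_t_mV = NA_real_,
                    t_peak_mV = NA_real_)

  # provisional isoelectric level from a short window just before the P
  # search region (the pre-QRS segment itself is largely P wave)
  pre0 <- idx(r_ms - windows$p_search_ms - 12)
  pre1 <- idx(r_ms - windows$p_search_ms - 2)
  seg <- idx(r_ms - windows$p_search_ms):idx(r_ms - windows$qrs_half_ms)
  if (length(seg) < 3L || pre1 - pre0 < 2L) return(out)
  iso <- median(v[pre0:pre1])
  r_height <- v[r_peak] - iso
  if (!(r_height > 0)) return(out)

  # P wave: peak in the pre-QRS segment, onset at 10% backward crossing
  ip <- seg[which.max(v[seg])]
  p_height <- v[ip] - iso
  sustain <- max(2L, as.integer(round(2 * windows$smooth_ms * fs / 1000)))
  if (p_height > 0.05 * r_height && ip > seg[1]) {
    # two passes: a coarse onset locates the local pre-P baseline (the
    # 10-ms window ending 5 ms before the onset), which then refines both
    # the isoelectric level and the onset threshold
    p_on <- NA_real_
    for (pass in 1:2) {
      p_on <- cross_time(t, v, iso + 0.1 * (v[ip] - iso), from = ip,
                         dir = -1L, cmp = "below", sustain_n = sustain)
      if (is.na(p_on) || p_on < t[seg[1]]) break
      w0 <- idx(p_on - 15); w1 <- idx(p_on - 5)
      if (w1 > w0 + 1L) {
        iso <- median(v[w0:w1])
        r_height <- v[r_peak] - iso
      }
    }
    if (!is.na(p_on) && p_on >= t[seg[1]]) out$p_onset_ms <- p_on
  }
  out$iso_mV <- iso

  # Q onset: 10% backward crossing from the Q trough before R
  qseg <- idx(r_ms - windows$qrs_half_ms):(r_peak - 1L)
  if (length(qseg) >= 2L) {
    iq <- qseg[which.min(vq[qseg])]
    q_depth <- iso - vq[iq]
    if (q_depth > 0.02 * r_height) {
      out$q_onset_ms <- cross_time(t, vq, iso - 0.1 * q_depth, from = iq,
                                   dir = -1L, cmp = "above")
    }
  }

  # S end: isoelectric recrossing after the S trough
  sseg <- (r_peak + 1L):idx(r_ms + windows$s_search_ms)
  if (length(sseg) >= 2L) {
    is_ <- sseg[which.min(vq[sseg])]
    if (iso - vq[is_] > 0.02 * r_height) {
      out$s_end_ms <- cross_time(t, vq, iso, from = is_, dir = 1L,
                                 cmp = "above")
    }
  }

  # T peak and 90%-decline point
  if (!is.na(out$s_end_ms)) {
    rr_est <- if (!is.na(next_r)) t[next_r] - r_ms else windows$rr_default_ms
    t_max <- r_ms + windows$t_frac_rr * rr_est
    if (!is.na(next_r)) {
      t_max <- min(t_max, t[next_r] - windows$p_search_ms - 5)
    }
    tseg <- idx(out$s_end_ms + 2):idx(t_max)
    if (length(tseg) >= 3L) {
      # T-local baseline from the quiet segment after the T search window:
      # with a high-pass filter, the baseline droops within the beat, so
      # the pre-P level is not the right reference for the T decline
      iso_t <- iso
      t0 <- idx(t_max + 8); t1 <- idx(t_max + 18)
      if (t1 > t0 + 1L && (is.na(next_r) || t[t1] < t[next_r] -
                             windows$p_search_ms)) {
        iso_t <- median(v[t0:t1])
      }
      out$iso_t_mV <- iso_t
      it <- tseg[which.max(v[tseg])]
      t_height <- v[it] - iso_t
      if (t_height > 0.03 * r_height && it < tseg[length(tseg)]) {
        out$t_peak_ms <- t[it]
        out$t_peak_mV <- v[it]
        out$t_end90_ms <- cross_time(t, v, iso_t + 0.1 * t_height,
                                     from = it, dir = 1L, cmp = "below",
                                     sustain_n = sustain)
      }
    }
  }
  out
}

#' Delineate every beat of an ECG record
#'
#' Runs [detect_r_peaks()] and [delineate_beat()] over the whole record,
#' skipping beats whose search windows would fall outside it.
#'
#' @inheritParams detect_r_peaks
#' @param min_height_frac Passed to [detect_r_peaks()].
#' @return A data.frame of per-beat fiducials (one row per delineated beat,
#'   columns as in [delineate_beat()]), with attribute `r_peaks` holding the
#'   detected peak indices.
#' @export
delineate_ecg <- function(record, windows = NULL, min_height_frac = 0.5) {
  if (is.null(windows)) windows <- delineation_windows(record$species_hint)
  peaks <- detect_r_peaks(record, min_height_frac, windows)
  vs <- delineation_signals(record, windows)
  t <- ecg_time_ms(record)
  dur <- t[length(t)]
  rows <- list()
  for (k in seq_along(peaks)) {
    r_ms <- t[peaks[k]]
    if (r_ms - windows$p_search_ms - 20 < 0) next
    if (r_ms + windows$t_frac_rr * windows$rr_default_ms > dur) next
    nr <- if (k < length(peaks)) peaks[k + 1L] else NA
    rows[[length(rows) + 1L]] <-
      delineate_beat(record, peaks[k], windows, next_r = nr, smoothed = vs)
  }
  beats <- if (length(rows)) do.call(rbind, rows) else
    delineate_beat(record, 1L, windows)[0, ]
  attr(beats, "r_peaks") <- peaks
  beats
}

#' Interval means over delineated beats
#'
#' Each interval (PR, QRS, QT, RR) is the arithmetic mean over all beats in
#' which both of its fiducials were located; the number of beats entering
#' each mean is recorded. Heart rate is derived from the mean RR.
#'
#' @param beats Per-beat fiducial data.frame from [delineate_ecg()].
#' @return An `interval_set` list with `PR_ms`, `QRS_ms`, `QT_ms`, `RR_ms`,
#'   `HR_bpm` and `n_beats_averaged` (a named integer vector).
#' @export
average_intervals <- function(beats) {
  stopifnot_msg(is.data.frame(beats) && nrow(beats) >= 1L,
                "no delineated beats to average")
  beats <- beats[order(beats$r_peak_ms), , drop = FALSE] # order invariance
  pr <- beats$r_peak_ms - beats$p_onset_ms
  qrs <- beats$s_end_ms - beats$q_onset_ms
  qt <- beats$t_end90_ms - beats$q_onset_ms
  rr <- diff(beats$r_peak_ms)
  rr <- rr[is.finite(rr)]
  mean_or_na <- function(x) {
    x <- x[is.finite(x)]
    if (length(x)) mean(x) else NA_real_
  }
  rr_m <- mean_or_na(rr)
  out <- list(
    PR_ms = mean_or_na(pr), QRS_ms = mean_or_na(qrs),
    QT_ms = mean_or_na(qt), RR_ms = rr_m,
    HR_bpm = if (is.finite(rr_m)) 60000 / rr_m else NA_real_,
    n_beats_averaged = c(PR = sum(is.finite(pr)), QRS = sum(is.finite(qrs)),
                         QT = sum(is.finite(qt)), RR = length(rr))
  )
  class(out) <- "interval_set"
  out
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf(
    "<interval_set> PR %.1f  QRS %.1f  QT %.1f  RR %.1f ms  HR %.1f bpm\n",
    x$PR_ms, x$QRS_ms, x$QT_ms, x$RR_ms, x$HR_bpm))
  cat("  beats averaged:",
      paste(names(x$n_beats_averaged), x$n_beats_averaged, sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' T-wave amplitude and area
#'
#' Amplitude is the mean T-peak height above the isoelectric level over the
#' selected beats. Area is the mean trapezoidal integral of the
#' baseline-subtracted voltage from the QRS end (S end) to the
#' 90\%-of-decline T end, conventionally averaged over 5 T waves; if fewer
#' than `n_area_beats` complete T waves exist, all available beats are used
#' and the result is flagged.
#'
#' @param record The [ecg_record()] the beats were delineated on.
#' @param beats Per-beat fiducials from [delineate_ecg()].
#' @param n_area_beats Number of T waves to average for the area (default 5).
#' @return A list with `amplitude_mV`, `area_mV_ms`, `n_amplitude`,
#'   `n_area`, and logical `flagged` (fewer than `n_area_beats` T waves).
#' @export
t_wave_metrics <- function(record, beats, n_area_beats = 5L) {
  ok <- is.finite(beats$t_peak_ms) & is.finite(beats$t_end90_ms) &
    is.finite(beats$s_end_ms)
  stopifnot_msg(any(ok), "no beats with T-wave fiducials")
  bt <- beats[ok, , drop = FALSE]
  iso_t <- ifelse(is.finite(bt$iso_t_mV), bt$iso_t_mV, bt$iso_mV)
  amp <- bt$t_peak_mV - iso_t
  sel <- head(seq_len(nrow(bt)), n_area_beats)
  t <- ecg_time_ms(record)
  v <- record$samples
  area1 <- function(i) {
    span <- which(t >= bt$s_end_ms[i] & t <= bt$t_end90_ms[i])
    if (length(span) < 2L) return(NA_real_)
    trapz_ms(t[span], v[span] - iso_t[i])
  }
  areas <- vapply(sel, area1, numeric(1))
  list(amplitude_mV = mean(amp),
       area_mV_ms = mean(areas, na.rm = TRUE),
       n_amplitude = length(amp), n_area = sum(is.finite(areas)),
       flagged = sum(is.finite(areas)) < n_area_beats)
}
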