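# z such that a Gaussian bump has fallen to 10% of its height: the wave
# "onset"/"end" convention shared by the generator and the delineator rules.
Z10 <- sqrt(2 * log(10))

#' Specification of a synthetic ECG
#'
#' Parameters of the parametric ECG generator. Defaults describe an
#' anesthetized adult mouse (HR 500 bpm, PR 40 ms, QRS 10 ms, QT 45 ms,
#' ~450 beats at 2 kHz) or a resting adult human (HR 65 bpm, PR 160 ms,
#' QRS 90 ms, QT 400 ms, 60 beats at 500 Hz).
#'
#' @param species `"mouse"` or `"human"` (sets all defaults).
#' @param hr_bpm Heart rate (bpm).
#' @param pr_ms,qrs_ms,qt_ms Programmed interval durations (ms).
#' @param r_amplitude_mV,t_amplitude_mV R and T peak amplitudes (mV).
#' @param qt_sd_ms Beat-to-beat QT jitter SD (ms).
#' @param noise_sd_mV Additive white-noise SD (mV).
#' @param wander_hz,wander_mV Sinusoidal baseline-wander frequency and
#'   amplitude.
#' @param n_beats Number of beats.
#' @param sampling_hz Sampling rate (Hz).
#' @param seed Random seed (single RNG stream per generated record).
#' @return An `ecg_spec` list.
#' @export
ecg_spec <- function(species = c("mouse", "human"), hr_bpm = NULL,
                     pr_ms = NULL, qrs_ms = NULL, qt_ms = NULL,
                     r_amplitude_mV = 1.0, t_amplitude_mV = NULL,
                     qt_sd_ms = NULL, noise_sd_mV = 0.01,
                     wander_hz = 0.2, wander_mV = 0.2, n_beats = NULL,
                     sampling_hz = NULL, seed = 20250507) {
  species <- match.arg(species)
  def <- if (species == "mouse") {
    list(hr_bpm = 500, pr_ms = 40, qrs_ms = 10, qt_ms = 45,
         t_amplitude_mV = 0.25, qt_sd_ms = 1, n_beats = 450,
         sampling_hz = 2000)
  } else {
    list(hr_bpm = 65, pr_ms = 160, qrs_ms = 90, qt_ms = 400,
         t_amplitude_mV = 0.3, qt_sd_ms = 5, n_beats = 60,
         sampling_hz = 500)
  }
  pick <- function(x, nm) if (is.null(x)) def[[nm]] else x
  spec <- list(species = species,
               hr_bpm = pick(hr_bpm, "hr_bpm"), pr_ms = pick(pr_ms, "pr_ms"),
               qrs_ms = pick(qrs_ms, "qrs_ms"), qt_ms = pick(qt_ms, "qt_ms"),
               r_amplitude_mV = r_amplitude_mV,
               t_amplitude_mV = pick(t_amplitude_mV, "t_amplitude_mV"),
               qt_sd_ms = pick(qt_sd_ms, "qt_sd_ms"),
               noise_sd_mV = noise_sd_mV, wander_hz = wander_hz,
               wander_mV = wander_mV, n_beats = pick(n_beats, "n_beats"),
               sampling_hz = pick(sampling_hz, "sampling_hz"), seed = seed)
  rr <- 60000 / spec$hr_bpm
  stopifnot_msg(spec$qt_ms < rr, "infeasible: QT must be shorter than RR")
  stopifnot_msg(spec$qt_sd_ms >= 0 && spec$noise_sd_mV >= 0 &&
                  spec$wander_mV >= 0, "SDs and amplitudes must be >= 0")
  class(spec) <- "ecg_spec"
  spec
}

# Evaluate a sum-of-Gaussian-bumps template at times t.
eval_template <- function(t, cm) {
  v <- 0
  for (w in cm) v <- v + w$a * exp(-(t - w$c)^2 / (2 * w$s^2))
  v
}

# Apply the package's measurement rules to a noiseless template on a fine
# grid (isoelectric level 0): returns the rule-defined fiducials. This is
# the shared definition of "where an interval starts/ends"; the generator
# solves wave placement against it so programmed intervals are exact by
# construction on the noiseless waveform.
measure_template <- function(cm, dt = 0.01) {
  span <- seq(cm$P$c - 4 * cm$P$s, cm$T$c + 4 * cm$T$s, by = dt)
  v <- eval_template(span, cm)
  # P onset: 10% backward crossing from the P peak
  pseg <- span <= cm$Q$c - 2 * cm$Q$s
  ipk <- which(pseg)[which.max(v[pseg])]
  p_onset <- cross_time(span, v, 0.1 * v[ipk], from = ipk, dir = -1L,
                        cmp = "below")
  # R peak: global maximum
  ir <- which.max(v)
  # Q onset: 10%-of-trough backward crossing from the Q trough
  qseg <- span >= cm$Q$c - 3 * cm$Q$s & span < span[ir]
  iq <- which(qseg)[which.min(v[qseg])]
  q_onset <- cross_time(span, v, 0.1 * v[iq], from = iq, dir = -1L,
                        cmp = "above")
  # S end: first zero recrossing after the S trough
  sseg <- span > span[ir] & span <= cm$J$c
  is_ <- which(sseg)[which.min(v[sseg])]
  s_end <- cross_time(span, v, 0, from = is_, dir = 1L, cmp = "above")
  # T peak and 90%-decline point
  tseg <- span > cm$T$c - 3 * cm$T$s
  it <- which(tseg)[which.max(v[tseg])]
  t_end90 <- cross_time(span, v, 0.1 * v[it], from = it, dir = 1L,
                        cmp = "below")
  list(p_onset = p_onset, q_onset = q_onset, r_peak = span[ir],
       s_end = s_end, t_peak = span[it], t_end90 = t_end90,
       t_peak_mV = v[it])
}

# Beat template: P, Q, R, S, J, T Gaussian bumps (J gives the S wave a
# sharp isoelectric recrossing) placed so the programmed PR, QRS and QT
# are realized exactly under the measurement rules of measure_template().
build_beat_template <- function(spec) {
  pr <- spec$pr_ms; qrs <- spec$qrs_ms; qt <- spec$qt_ms
  q_on <- -qrs / 2

  sg_p <- 0.10 * pr
  sg_qrs <- 0.10 * qrs
  sg_t <- 0.13 * qt
  comp <- list(
    P = list(c = -pr + Z10 * sg_p, s = sg_p, a = 0.10 * spec$r_amplitude_mV),
    Q = list(c = q_on + Z10 * sg_qrs, s = sg_qrs,
             a = -0.15 * spec$r_amplitude_mV),
    R = list(c = 0, s = sg_qrs, a = spec$r_amplitude_mV),
    S = list(c = 0.30 * qrs, s = sg_qrs, a = -0.25 * spec$r_amplitude_mV),
    J = list(c = 0.30 * qrs + 2.5 * sg_qrs, s = sg_qrs,
             a = 0.10 * spec$r_amplitude_mV),
    T = list(c = q_on + qt - Z10 * sg_t, s = sg_t, a = spec$t_amplitude_mV)
  )
  stopifnot_msg(comp$P$c + 2 * Z10 * sg_p < comp$Q$c - Z10 * sg_qrs,
                "infeasible: P wave would overlap the QRS complex")

  shift <- function(cm, nms, d) {
    for (nm in nms) cm[[nm]]$c <- cm[[nm]]$c + d
    cm
  }
  solve_shift <- function(cm, nms, target, value_fun, half_span) {
    f <- function(d) value_fun(measure_template(shift(cm, nms, d))) - target
    d <- uniroot(f, c(-half_span, half_span), tol = 1e-6)$root
    shift(cm, nms, d)
  }
  # two passes: the rule-based q_onset moves slightly as S/J shift the
  # early-QRS shape, so re-solve against the updated reference
  for (pass in 1:2) {
    m0 <- measure_template(comp)
    comp <- solve_shift(comp, "P", m0$r_peak - pr,
                        function(m) m$p_onset, 3 * sg_p)
    comp <- solve_shift(comp, c("S", "J"), m0$q_onset + qrs,
                        function(m) m$s_end, 0.4 * qrs)
    comp <- solve_shift(comp, "T", m0$q_onset + qt,
                        function(m) m$t_end90, 3 * sg_t)
  }
  list(components = comp, truth = measure_template(comp))
}

#' Generate a synthetic ECG with exact fiducial ground truth
#'
#' Each beat is a sum of Gaussian bumps (P, Q, R, S, a small J wave giving
#' the S wave a sharp isoelectric recrossing, and T) whose placement is
#' solved numerically so that the programmed PR, QRS and QT intervals are
#' realized exactly under the package's measurement rules. Beat-to-beat QT
#' jitter shifts the T complex; white noise and sinusoidal baseline wander
#' are added on top. The per-beat fiducial truth is returned alongside the
#' record.
#'
#' @param spec An [ecg_spec()].
#' @return A list with `record` (an [ecg_record()]) and `truth` (a
#'   data.frame of per-beat fiducial times in ms and the realized
#'   `qt_ms`, `pr_ms`, `qrs_ms`, `rr_ms`).
#' @examples
#' sim <- gen_ecg(ecg_spec("mouse", n_beats = 12, seed = 1))
#' sim$truth$qt_ms[1:3]
#' @export
gen_ecg <- function(spec) {
  stopifnot_msg(inherits(spec, "ecg_spec"), "spec must be an ecg_spec")
  set.seed(spec$seed)
  tpl <- build_beat_template(spec)
  rr <- 60000 / spec$hr_bpm
  fs <- spec$sampling_hz
  pad <- spec$pr_ms + 3 * tpl$components$P$s + 20
  dur <- pad + spec$n_beats * rr + 40
  n <- ceiling(dur * fs / 1000)
  t <- (seq_len(n) - 1L) * 1000 / fs

  jit <- rnorm(spec$n_beats, 0, spec$qt_sd_ms)
  r_times <- pad + (seq_len(spec$n_beats) - 1L) * rr

  v <- numeric(n)
  add_bump <- function(v, center, sg, a) {
    i0 <- max(1L, floor((center - 5 * sg) * fs / 1000) + 1L)
    i1 <- min(n, ceiling((center + 5 * sg) * fs / 1000) + 1L)
    if (i1 >= i0) {
      idx <- i0:i1
      v[idx] <- v[idx] + a * exp(-(t[idx] - center)^2 / (2 * sg^2))
    }
    v
  }
  for (k in seq_len(spec$n_beats)) {
    for (nm in c("P", "Q", "R", "S", "J")) {
      w <- tpl$components[[nm]]
      v <- add_bump(v, r_times[k] + w$c, w$s, w$a)
    }
    w <- tpl$components$T
    v <- add_bump(v, r_times[k] + w$c + jit[k], w$s, w$a)
  }
  if (spec$noise_sd_mV > 0) v <- v + rnorm(n, 0, spec$noise_sd_mV)
  if (spec$wander_mV > 0) {
    v <- v + spec$wander_mV * sin(2 * pi * spec$wander_hz * t / 1000)
  }

  tr <- tpl$truth
  truth <- data.frame(
    beat = seq_len(spec$n_beats),
    r_peak_ms = r_times + tr$r_peak,
    p_onset_ms = r_times + tr$p_onset,
    q_onset_ms = r_times + tr$q_onset,
    s_end_ms = r_times + tr$s_end,
    t_peak_ms = r_times + tr$t_peak + jit,
    t_end90_ms = r_times + tr$t_end90 + jit,
    pr_ms = tr$r_peak - tr$p_onset,
    qrs_ms = tr$s_end - tr$q_onset,
    qt_ms = tr$t_end90 - tr$q_onset + jit,
    rr_ms = rr
  )
  list(record = ecg_record(v, fs, lead_label = "synthetic",
                           species_hint = spec$species),
       truth = truth)
}

#' Generate a stationary AR(1) beat-to-beat QT (and HR) series
#'
#' The simplest process with controllable mean, SD and successive-difference
#' structure: `x_i = mean + phi * (x_{i-1} - mean) + e_i`, innovation SD
#' `sd * sqrt(1 - phi^2)`, initialized from the stationary distribution.
#' At `lag1_corr = 0` the series is white noise, for which
#' `E[RMSSD] -> sd * sqrt(2)`.
#'
#' @param n Series length (>= 2).
#' @param qtm_ms,sd_ms QT mean and SD (ms).
#' @param lag1_corr Lag-1 autocorrelation, |phi| < 1.
#' @param hr Optional list `list(hrm_bpm=, sd_bpm=, lag1_corr=)`; if given,
#'   an aligned HR series is generated the same way.
#' @param seed Random seed.
#' @return A data.frame with `qt_ms` (and `hr_bpm` if requested);
#'   generator truth in attribute `truth`.
#' @export
gen_qt_series <- function(n, qtm_ms = 420, sd_ms = 20, lag1_corr = 0,
                          hr = NULL, seed = 20250507) {
  stopifnot_msg(n >= 2, "n must be >= 2")
  stopifnot_msg(abs(lag1_corr) < 1, "|lag1_corr| must be < 1")
  set.seed(seed)
  ar1 <- function(n, mu, sdv, phi) {
    if (sdv == 0) return(rep(mu, n))
    x <- numeric(n)
    x[1] <- rnorm(1, mu, sdv)
    innov <- rnorm(n - 1, 0, sdv * sqrt(1 - phi^2))
    for (i in 2:n) x[i] <- mu + phi * (x[i - 1] - mu) + innov[i - 1]
    x
  }
  out <- data.frame(qt_ms = ar1(n, qtm_ms, sd_ms, lag1_corr))
  truth <- list(qtm_ms = qtm_ms, sd_ms = sd_ms, lag1_corr = lag1_corr)
  if (!is.null(hr)) {
    out$hr_bpm <- ar1(n, hr$hrm_bpm, hr$sd_bpm,
                      if (is.null(hr$lag1_corr)) lag1_corr else hr$lag1_corr)
    truth$hr <- hr
  }
  attr(out, "truth") <- truth
  out
}
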