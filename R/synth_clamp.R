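#' Specification of a synthetic gating-model cell
#'
#' Parameters of the Hodgkin-Huxley-style separable current model used by
#' [gen_voltage_clamp()]:
#' `I(t) = Gmax * m_inf(V) * (1 - exp(-t/tau_act)) * h(t) * (V - Erev)`,
#' with `m_inf` a rising Boltzmann in `(Vh_act, k_act)` and `h(t)` a
#' biexponential decay toward a sustained plateau chosen so the
#' end-of-pulse current is `late_fraction` of the peak. Steady-state
#' availability follows a falling Boltzmann in `(Vh_inact, k_inact)`;
#' recovery from inactivation is monoexponential with `tau_react_ms`.
#'
#' Presets carry realistic wild-type mouse ventricular parameters:
#' `"na"` (fast sodium: Vh_act -52.9 mV, k 4.0, Vh_inact -86.9 mV, k 5.0,
#' tau_act 0.5 ms, tau_f/tau_s 1.3/4.5 ms, tau_react 8.2 ms),
#' `"cal"` (L-type calcium) and `"kout"` (transient outward potassium,
#' mono-exponential decay tau 156 ms with a large sustained component).
#'
#' @param preset `"na"`, `"cal"` or `"kout"`.
#' @param ... Named overrides of any field: `Gmax_nS`, `Erev_mV`,
#'   `Vh_act_mV`, `k_act_mV`, `Vh_inact_mV`, `k_inact_mV`, `tau_act_ms`,
#'   `tau_f_ms`, `tau_s_ms`, `frac_fast`, `late_fraction`, `tau_react_ms`,
#'   `noise_sd_pA`, `noise_frac`, `capacitance_pF`, `seed`.
#' @return A `gating_spec` list.
#' @export
gating_spec <- function(preset = c("na", "cal", "kout"), ...) {
  preset <- match.arg(preset)
  def <- switch(preset,
    na = list(Gmax_nS = 200, Erev_mV = 65, Vh_act_mV = -52.9, k_act_mV = 4.0,
              Vh_inact_mV = -86.9, k_inact_mV = 5.0, tau_act_ms = 0.5,
              tau_f_ms = 1.3, tau_s_ms = 4.5, frac_fast = 0.8,
              late_fraction = 0.005, tau_react_ms = 8.2),
    cal = list(Gmax_nS = 30, Erev_mV = 60, Vh_act_mV = -11.1, k_act_mV = 6.4,
               Vh_inact_mV = -33.5, k_inact_mV = 5.2, tau_act_ms = 1.1,
               tau_f_ms = 20.1, tau_s_ms = 72.2, frac_fast = 0.6,
               late_fraction = 0.02, tau_react_ms = 50),
    kout = list(Gmax_nS = 20, Erev_mV = -85, Vh_act_mV = -4.6,
                k_act_mV = 14.3, Vh_inact_mV = -32.9, k_inact_mV = 7.6,
                tau_act_ms = 2, tau_f_ms = 156, tau_s_ms = 1200,
                frac_fast = 1, late_fraction = 0.40, tau_react_ms = 15.5))
  spec <- modifyList(c(def, list(noise_sd_pA = 0, noise_frac = 0,
                                 capacitance_pF = 150, seed = 20250507,
                                 preset = preset)),
                     list(...))
  stopifnot_msg(spec$tau_f_ms < spec$tau_s_ms, "need tau_f < tau_s")
  stopifnot_msg(spec$late_fraction >= 0 && spec$late_fraction < 1,
                "late_fraction must lie in [0, 1)")
  stopifnot_msg(spec$frac_fast >= 0 && spec$frac_fast <= 1,
                "frac_fast must lie in [0, 1]")
  stopifnot_msg(spec$capacitance_pF > 0, "capacitance must be > 0")
  class(spec) <- "gating_spec"
  spec
}

m_inf <- function(v, spec) 1 / (1 + exp(-(v - spec$Vh_act_mV) / spec$k_act_mV))
h_inf <- function(v, spec) 1 / (1 + exp((v - spec$Vh_inact_mV) /
                                          spec$k_inact_mV))

# time-course factor g(t) = activation * inactivation-decay; `ell` is the
# sustained plateau of the decay
gating_time_course <- function(t, spec, ell) {
  a <- 1 - exp(-t / spec$tau_act_ms)
  h <- ell + (1 - ell) * (spec$frac_fast * exp(-t / spec$tau_f_ms) +
                            (1 - spec$frac_fast) * exp(-t / spec$tau_s_ms))
  a * h
}

# plateau level such that end-of-pulse / peak = late_fraction
solve_plateau <- function(spec, pulse_ms) {
  if (spec$late_fraction == 0) return(0)
  tg <- seq(0, pulse_ms, length.out = 4000)
  f <- function(ell) {
    g <- gating_time_course(tg, spec, ell)
    g[length(g)] / max(g) - spec$late_fraction
  }
  uniroot(f, c(0, spec$late_fraction * 1.5 + 1e-6), tol = 1e-10)$root
}

CLAMP_PROTO_GEOM <- list(
  iv_na = list(hold = -120, potentials = seq(-100, 30, 5), pulse = 50,
               fs = 50000),
  inact_na = list(hold = -120, prepulses = seq(-140, -20, 10), test = -20,
                  pulse = 50, fs = 50000),
  recovery_na = list(hold = -120, test = -40, pulse = 50, fs = 50000,
                     intervals = c(0.05, 0.1, 0.2, 0.5, 1, 2, 3, 5, 8, 12,
                                   20, 50, 100, 200, 500)),
  late_na = list(hold = -120, potentials = -40, pulse = 500, fs = 50000),
  iv_cal = list(hold = -80, potentials = seq(-40, 50, 5), pulse = 500,
                fs = 4000),
  inact_cal = list(hold = -70, prepulses = seq(-90, 50, 10), test = 0,
                   pulse = 150, fs = 4000),
  ik1 = list(hold = -80, potentials = seq(-120, -30, 10), pulse = 250,
             fs = 4000),
  outward_k = list(hold = -80, potentials = seq(-80, 50, 10), pulse = 500,
                   fs = 4000)
)

#' Generate voltage-clamp sweep sets from the gating model
#'
#' Produces sweeps under the standard pulse-protocol geometries (see
#' Details) with the model of [gating_spec()], optional additive and
#' multiplicative noise, and the analytic noiseless truth per sweep.
#'
#' Protocol geometries: `iv_na` 50-ms pulses, -120 mV holding, -100..+30 mV
#' in 5-mV steps at 50 kHz; `inact_na` 500-ms conditioning prepulses
#' -140..-20 mV then a test pulse to -20 mV; `recovery_na` paired 50-ms
#' P1/P2 pulses to -40 mV at coupling intervals 0.05-500 ms; `late_na` one
#' 500-ms pulse -120 to -40 mV; `iv_cal` 500-ms pulses -40..+50 mV from
#' -80 mV at 4 kHz; `inact_cal` conditioning -90..+50 mV, test 0 mV;
#' `ik1` 250-ms steps -120..-30 mV measured at the pulse end (ohmic model
#' `Gmax * (V - Erev)`); `outward_k` 500-ms pulses -80..+50 mV in 10-mV
#' steps.
#'
#' @param spec A [gating_spec()].
#' @param protocol One of the recognized protocol names.
#' @return A [sweep_set()] with attribute `truth`: a data.frame of
#'   noiseless per-sweep values (peak density, peak-minus-end density,
#'   end-of-pulse density, and availability/recovery fractions where
#'   relevant) plus the generating spec.
#' @export
gen_voltage_clamp <- function(spec, protocol = names(CLAMP_PROTO_GEOM)) {
  stopifnot_msg(inherits(spec, "gating_spec"), "spec must be a gating_spec")
  protocol <- match.arg(protocol)
  geom <- CLAMP_PROTO_GEOM[[protocol]]
  set.seed(spec$seed)
  dt <- 1000 / geom$fs
  cm <- spec$capacitance_pF
  ell <- solve_plateau(spec, geom$pulse)
  add_noise <- function(i) {
    if (spec$noise_sd_pA > 0) i <- i + rnorm(length(i), 0, spec$noise_sd_pA)
    if (spec$noise_frac > 0) {
      i <- i * (1 + rnorm(length(i), 0, spec$noise_frac))
    }
    i
  }
  drive <- function(v) spec$Gmax_nS * m_inf(v, spec) * (v - spec$Erev_mV)
  pulse_trace <- function(v, scale = 1, pre = 2, post = 2,
                          pulse = geom$pulse) {
    t <- seq(0, pre + pulse + post, by = dt)
    i <- numeric(length(t))
    inpulse <- t >= pre & t <= pre + pulse
    i[inpulse] <- scale * drive(v) *
      gating_time_course(t[inpulse] - pre, spec, ell)
    list(t = t, i = i, pre = pre, pulse = pulse)
  }
  tg <- seq(0, geom$pulse, by = min(dt, 0.01))
  g <- gating_time_course(tg, spec, ell)
  g_peak <- max(g)
  g_end <- g[length(g)]

  sweeps <- list()
  truth <- NULL
  if (protocol %in% c("iv_na", "iv_cal", "late_na", "outward_k")) {
    for (v in geom$potentials) {
      tr <- pulse_trace(v)
      sweeps[[length(sweeps) + 1L]] <-
        clamp_sweep(tr$t, add_noise(tr$i), v, geom$hold, tr$pre, tr$pulse)
    }
    truth <- data.frame(
      Vm_mV = geom$potentials,
      peak_density = drive(geom$potentials) * g_peak / cm,
      peak_minus_end_density = drive(geom$potentials) * (g_peak - g_end) / cm,
      end_density = drive(geom$potentials) * g_end / cm)
  } else if (protocol == "ik1") {
    for (v in geom$potentials) {
      t <- seq(0, 2 + geom$pulse + 2, by = dt)
      i <- numeric(length(t))
      i[t >= 2 & t <= 2 + geom$pulse] <- spec$Gmax_nS * (v - spec$Erev_mV)
      sweeps[[length(sweeps) + 1L]] <-
        clamp_sweep(t, add_noise(i), v, geom$hold, 2, geom$pulse)
    }
    truth <- data.frame(
      Vm_mV = geom$potentials,
      end_density = spec$Gmax_nS * (geom$potentials - spec$Erev_mV) / cm)
  } else if (protocol %in% c("inact_na", "inact_cal")) {
    avail <- h_inf(geom$prepulses, spec)
    for (j in seq_along(geom$prepulses)) {
      tr <- pulse_trace(geom$test, scale = avail[j])
      sweeps[[length(sweeps) + 1L]] <-
        clamp_sweep(tr$t, add_noise(tr$i), geom$test, geom$hold, tr$pre,
                    tr$pulse, prepulse_mV = geom$prepulses[j])
    }
    truth <- data.frame(prepulse_mV = geom$prepulses, availability = avail,
                        availability_norm = avail / max(avail))
  } else if (protocol == "recovery_na") {
    rec <- 1 - exp(-geom$intervals / spec$tau_react_ms)
    for (j in seq_along(geom$intervals)) {
      gap <- geom$intervals[j]
      t <- seq(0, 2 + geom$pulse + gap + geom$pulse + 2, by = dt)
      i <- numeric(length(t))
      p1 <- t >= 2 & t <= 2 + geom$pulse
      i[p1] <- drive(geom$test) * gating_time_course(t[p1] - 2, spec, ell)
      t2 <- 2 + geom$pulse + gap
      p2 <- t >= t2 & t <= t2 + geom$pulse
      i[p2] <- rec[j] * drive(geom$test) *
        gating_time_course(t[p2] - t2, spec, ell)
      sweeps[[length(sweeps) + 1L]] <-
        clamp_sweep(t, add_noise(i), geom$test, geom$hold, 2, geom$pulse,
                    interval_ms = gap)
    }
    truth <- data.frame(interval_ms = geom$intervals, recovery = rec)
  }
  out <- sweep_set(sweeps, protocol, cm)
  attr(out, "truth") <- list(per_sweep = truth, spec = spec,
                             plateau = ell, g_peak = g_peak, g_end = g_end)
  out
}

#' Generate an action-potential trace with exact programmed APDs
#'
#' Builds a piecewise-smooth AP: a resting segment at `rmp_mV`, a 1-ms
#' linear upstroke, and a monotone (Hyman-filtered) cubic repolarization
#' passing exactly through the programmed 20/50/90\% repolarization times,
#' followed by an exponential settle to rest. Because the repolarization
#' is monotone and anchored at the APDx voltages, the programmed APDs are
#' exact by construction (peak-referenced).
#'
#' @param rmp_mV Resting membrane potential (mV).
#' @param apa_mV AP amplitude (mV); `0` yields a flat trace (no AP).
#' @param apd20_ms,apd50_ms,apd90_ms Programmed durations, strictly
#'   increasing.
#' @param sampling_hz Sampling rate (default 20 kHz).
#' @param noise_sd_mV Additive noise SD (default 0).
#' @param seed Random seed (used only if `noise_sd_mV > 0`).
#' @return A [clamp_sweep()] whose trace is membrane voltage (mV), with the
#'   programmed metrics in attribute `truth`. Stimulus onset at 20 ms,
#'   2-ms nominal stimulus window.
#' @export
gen_ap <- function(rmp_mV = -80, apa_mV = 120, apd20_ms = 20, apd50_ms = 50,
                   apd90_ms = 90, sampling_hz = 20000, noise_sd_mV = 0,
                   seed = 20250507) {
  stopifnot_msg(apd20_ms < apd50_ms && apd50_ms < apd90_ms,
                "APDs must be strictly increasing (APD20 < APD50 < APD90)")
  dt <- 1000 / sampling_hz
  stim <- 20
  upstroke <- 1
  tail_len <- max(20, 0.5 * apd90_ms)
  dur <- stim + upstroke + apd90_ms + tail_len + 20
  t <- seq(0, dur, by = dt)
  if (apa_mV <= 0) {
    v <- rep(rmp_mV, length(t))
  } else {
    peak <- rmp_mV + apa_mV
    t_peak <- stim + upstroke
    # monotone anchors for the repolarization, peak-referenced
    ax <- c(0, apd20_ms, apd50_ms, apd90_ms,
            apd90_ms + 0.5 * (apd90_ms - apd50_ms))
    ay <- peak - c(0, 0.2, 0.5, 0.9, 0.97) * apa_mV
    rep_fun <- splinefun(ax, ay, method = "hyman")
    t_set <- t_peak + ax[length(ax)]
    tau_set <- max(2, 0.2 * (apd90_ms - apd50_ms))
    v <- numeric(length(t))
    pre <- t <= stim
    up <- t > stim & t < t_peak
    repol <- t >= t_peak & t <= t_set
    settle <- t > t_set
    v[pre] <- rmp_mV
    v[up] <- rmp_mV + apa_mV * (t[up] - stim) / upstroke
    v[repol] <- rep_fun(t[repol] - t_peak)
    v[settle] <- rmp_mV + (ay[length(ay)] - rmp_mV) *
      exp(-(t[settle] - t_set) / tau_set)
  }
  if (noise_sd_mV > 0) {
    set.seed(seed)
    v <- v + rnorm(length(v), 0, noise_sd_mV)
  }
  out <- clamp_sweep(t, v, NA_real_, NA_real_, stim, 2)
  attr(out, "truth") <- list(rmp_mV = rmp_mV, apa_mV = apa_mV,
                             apd20_ms = apd20_ms, apd50_ms = apd50_ms,
                             apd90_ms = apd90_ms)
  out
}
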