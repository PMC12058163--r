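#' Amplitude measurements on a voltage-clamp sweep
#'
#' `peak_amplitude()` measures the transient amplitude as the extremum
#' within the pulse window (after blanking the capacitive transient) minus
#' the mean current over the last 5\% of the pulse ("peak minus end").
#' `sustained_amplitude()` measures the end-of-pulse level (mean of the
#' last 5\% of the pulse) minus the pre-pulse baseline. Both are signed.
#'
#' @param sweep A [clamp_sweep()].
#' @param polarity `"inward"` (extremum = minimum) or `"outward"`
#'   (extremum = maximum).
#' @param blank_ms Capacitive-transient blanking window at the pulse start
#'   excluded from the peak search (default 0.3 ms).
#' @param end_frac Fraction of the pulse defining the end-of-pulse window
#'   (default 0.05).
#' @return Amplitude in pA.
#' @examples
#' t <- seq(0, 60, by = 0.02)
#' i <- ifelse(t >= 5 & t <= 55, -1400 * exp(-(t - 5) / 3) - 100, 0)
#' sw <- clamp_sweep(t, i, -30, -120, 5, 50)
#' peak_amplitude(sw, "inward") # about -1300 (peak ~ -1500 minus end ~ -100)
#' @export
peak_amplitude <- function(sweep, polarity = c("inward", "outward"),
                           blank_ms = 0.3, end_frac = 0.05) {
  polarity <- match.arg(polarity)
  stopifnot_msg(blank_ms < sweep$pulse_duration_ms * (1 - end_frac),
                "pulse shorter than the blanking window")
  win <- pulse_indices(sweep, blank_ms)
  stopifnot_msg(length(win) >= 2L, "empty pulse window after blanking")
  i <- sweep$current_pA[win]
  ext <- if (polarity == "inward") min(i) else max(i)
  ext - end_of_pulse_level(sweep, end_frac)
}

#' @rdname peak_amplitude
#' @export
sustained_amplitude <- function(sweep, end_frac = 0.05) {
  end_of_pulse_level(sweep, end_frac) - baseline_level(sweep)
}

#' Normalize a current amplitude to cell capacitance
#'
#' @param amplitude_pA Current amplitude (pA).
#' @param capacitance_pF Cell capacitance (pF), > 0.
#' @return Current density (pA/pF).
#' @export
current_density <- function(amplitude_pA, capacitance_pF) {
  stopifnot_msg(all(capacitance_pF > 0), "capacitance must be > 0")
  amplitude_pA / capacitance_pF
}

#' Build a current-voltage relationship from a sweep set
#'
#' One density point per test potential: `peak_minus_end` uses
#' [peak_amplitude()] (transient currents), `end_of_pulse` uses
#' [sustained_amplitude()] (sustained currents and the inward rectifier).
#'
#' @param set A [sweep_set()] recorded under an I-V protocol.
#' @param measurement `"peak_minus_end"` or `"end_of_pulse"`.
#' @param polarity Peak polarity for `peak_minus_end` (default `"inward"`
#'   for Na/CaL protocols, `"outward"` for `outward_k`).
#' @param blank_ms Capacitive-transient blanking (ms).
#' @return An `iv_curve` data.frame with `Vm_mV` and `density_pA_pF`,
#'   ordered by potential; `measurement` stored as an attribute.
#' @export
build_iv <- function(set, measurement = c("peak_minus_end", "end_of_pulse"),
                     polarity = NULL, blank_ms = 0.3) {
  stopifnot_msg(inherits(set, "sweep_set"), "set must be a sweep_set")
  measurement <- match.arg(measurement)
  if (is.null(polarity)) {
    polarity <- if (set$protocol %in% c("outward_k", "ik1"))
      "outward" else "inward"
  }
  vm <- vapply(set$sweeps, `[[`, numeric(1), "test_potential_mV")
  stopifnot_msg(!anyDuplicated(vm), "duplicate test potentials")
  amp <- vapply(set$sweeps, function(s) {
    if (measurement == "peak_minus_end") {
      peak_amplitude(s, polarity, blank_ms)
    } else {
      sustained_amplitude(s)
    }
  }, numeric(1))
  ord <- order(vm)
  out <- data.frame(Vm_mV = vm[ord],
                    density_pA_pF = current_density(amp,
                      set$cell_capacitance_pF)[ord])
  attr(out, "measurement") <- measurement
  class(out) <- c("iv_curve", class(out))
  out
}

#' Inward-rectifier (IK1) current-voltage relationship
#'
#' IK1 is always measured at the end of the pulses; this is [build_iv()]
#' with the `end_of_pulse` measurement on a 250-ms step protocol.
#'
#' @param set A [sweep_set()] with protocol `"ik1"`.
#' @return An `iv_curve` data.frame.
#' @export
ik1_measure <- function(set) {
  stopifnot_msg(set$protocol == "ik1", "set must use the ik1 protocol")
  build_iv(set, "end_of_pulse")
}

#' Late (persistent) current as a percentage of the peak
#'
#' For a long (500-ms) pulse, the late component is the mean current over
#' the last `late_frac` of the pulse, expressed as a percentage of the peak
#' current; both are baseline-subtracted so the sign convention cancels.
#'
#' @param sweep A [clamp_sweep()].
#' @param polarity Peak polarity (default `"inward"`).
#' @param late_frac Fraction of the pulse defining the late window
#'   (default 0.1, i.e. the last 10\%).
#' @param blank_ms Capacitive-transient blanking (ms).
#' @return Late current as a percentage of peak.
#' @export
late_current_percent <- function(sweep, polarity = c("inward", "outward"),
                                 late_frac = 0.1, blank_ms = 0.3) {
  polarity <- match.arg(polarity)
  base <- baseline_level(sweep)
  win <- pulse_indices(sweep, blank_ms)
  i <- sweep$current_pA[win] - base
  peak <- if (polarity == "inward") min(i) else max(i)
  stopifnot_msg(abs(peak) > 1e-9, "peak current is ~0; late fraction undefined")
  late <- end_of_pulse_level(sweep, late_frac) - base
  100 * late / peak
}

#' Charge density of a transient current
#'
#' Integrates the transient component of the current — the area between the
#' trace and its end-of-pulse level, from the peak to the pulse end — and
#' normalizes to cell capacitance. A purely sustained (flat) current
#' therefore carries zero charge by this definition.
#'
#' @param sweep A [clamp_sweep()].
#' @param capacitance_pF Cell capacitance (pF).
#' @param polarity Peak polarity (default `"outward"`, the repolarizing
#'   K+ convention).
#' @param blank_ms Capacitive-transient blanking (ms).
#' @return Charge density (pC/pF).
#' @export
charge_density <- function(sweep, capacitance_pF,
                           polarity = c("outward", "inward"),
                           blank_ms = 0.3) {
  polarity <- match.arg(polarity)
  stopifnot_msg(capacitance_pF > 0, "capacitance must be > 0")
  win <- pulse_indices(sweep, blank_ms)
  stopifnot_msg(length(win) >= 2L, "empty pulse window after blanking")
  i <- sweep$current_pA[win]
  ip <- if (polarity == "outward") which.max(i) else which.min(i)
  iend <- end_of_pulse_level(sweep)
  seg <- win[ip:length(win)]
  q_fC <- trapz_ms(sweep$time_ms[seg], sweep$current_pA[seg] - iend)
  q_fC / 1000 / capacitance_pF
}

#' Charge-density-voltage relationship for a sweep set
#'
#' [charge_density()] applied to every sweep of an outward-K protocol.
#'
#' @inheritParams charge_density
#' @param set A [sweep_set()].
#' @return A data.frame with `Vm_mV` and `charge_pC_pF`, ordered by
#'   potential.
#' @export
charge_curve <- function(set, polarity = c("outward", "inward"),
                         blank_ms = 0.3) {
  polarity <- match.arg(polarity)
  vm <- vapply(set$sweeps, `[[`, numeric(1), "test_potential_mV")
  q <- vapply(set$sweeps, charge_density, numeric(1),
              capacitance_pF = set$cell_capacitance_pF,
              polarity = polarity, blank_ms = blank_ms)
  ord <- order(vm)
  data.frame(Vm_mV = vm[ord], charge_pC_pF = q[ord])
}
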