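#' Fit a current-voltage relationship with a Boltzmann-scaled ohmic model
#'
#' Fits the standard gating model
#' `I(V) = Gmax * (V - Erev) / (1 + exp(-(V - Vh) / k))`
#' to a density-voltage curve by least squares. The sign convention makes
#' channel occupancy increase with depolarization and reports the slope
#' factor `k` as positive. Initialization: `Erev` from the linear
#' extrapolation of the fully activated limb, `Vh` from the half-maximal
#' conductance crossing, `k` from the 10-90\% rise span divided by 4.4,
#' `Gmax` from the maximal chord conductance.
#'
#' @param curve An `iv_curve` from [build_iv()], with at least 5 points
#'   spanning sub- and supra-threshold potentials.
#' @return A `gating_fit` list: `Gmax` (conductance in the units of the
#'   input, i.e. nS/pF for density curves), `Erev_mV`, `Vh_mV`, `k_mV`
#'   (positive), `curve_role = "activation_conductance"`, `fit_rmse`.
#' @export
fit_iv <- function(curve) {
  stopifnot_msg(is.data.frame(curve) && nrow(curve) >= 5L,
                "need at least 5 I-V points")
  v <- curve$Vm_mV
  d <- curve$density_pA_pF
  ord <- order(v)
  v <- v[ord]; d <- d[ord]
  n <- length(v)

  # Erev: linear extrapolation of the fully activated (highest-V) limb
  ntop <- max(3L, ceiling(n / 4))
  top <- (n - ntop + 1L):n
  lf <- stats::lm.fit(cbind(1, v[top]), d[top])
  erev0 <- unname(-lf$coefficients[1] / lf$coefficients[2])
  if (!is.finite(erev0)) erev0 <- max(v) + 20

  g <- ifelse(abs(v - erev0) > 1, d / (v - erev0), NA_real_)
  gmax0 <- max(abs(g), na.rm = TRUE)
  gn <- abs(g) / gmax0
  vh0 <- cross_time(v, ifelse(is.na(gn), 0, gn), 0.5, from = 1L, dir = 1L,
                    cmp = "above")
  if (is.na(vh0)) vh0 <- v[which.min(abs(gn - 0.5))]
  v10 <- cross_time(v, ifelse(is.na(gn), 0, gn), 0.1, 1L, 1L, "above")
  v90 <- cross_time(v, ifelse(is.na(gn), 0, gn), 0.9, 1L, 1L, "above")
  k0 <- if (is.finite(v10) && is.finite(v90) && v90 > v10)
    (v90 - v10) / 4.4 else 5

  fit <- tryCatch(
    minpack.lm::nlsLM(
      d ~ Gmax * (v - Erev) / (1 + exp(-(v - Vh) / k)),
      start = list(Gmax = gmax0, Erev = erev0, Vh = vh0, k = k0),
      lower = c(Gmax = 0, Erev = -Inf, Vh = vh0 - 50, k = 0.1),
      upper = c(Gmax = Inf, Erev = Inf, Vh = vh0 + 50, k = 100),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop(sprintf(
      "I-V fit did not converge (starts: Gmax %.3g, Erev %.3g, Vh %.3g, k %.3g): %s",
      gmax0, erev0, vh0, k0, conditionMessage(e)), call. = FALSE))
  cf <- coef(fit)
  structure(list(Gmax = unname(cf["Gmax"]), Erev_mV = unname(cf["Erev"]),
                 Vh_mV = unname(cf["Vh"]), k_mV = unname(cf["k"]),
                 curve_role = "activation_conductance",
                 fit_rmse = sqrt(mean(stats::residuals(fit)^2))),
            class = "gating_fit")
}

#' @export
print.gating_fit <- function(x, ...) {
  cat(sprintf(
    "<gating_fit> %s: Vh %.2f mV  k %.2f mV  Erev %.1f mV  Gmax %.3g (rmse %.3g)\n",
    x$curve_role, x$Vh_mV, x$k_mV,
    if (is.null(x$Erev_mV)) NA else x$Erev_mV,
    if (is.null(x$Gmax)) NA else x$Gmax, x$fit_rmse))
  invisible(x)
}

#' Normalized conductance-voltage curve
#'
#' Chord conductance `G = I / (Vm - Erev)` at each test potential,
#' normalized to its maximum. Points within `exclude_mV` of the reversal
#' potential are excluded (the chord conductance is singular there).
#'
#' @param curve An `iv_curve` from [build_iv()].
#' @param Erev_mV Reversal potential, typically from [fit_iv()].
#' @param exclude_mV Exclusion half-window around `Erev_mV` (default 1 mV).
#' @return A data.frame with `Vm_mV` and `G_norm`; excluded potentials are
#'   recorded in the `excluded_mV` attribute.
#' @export
conductance_curve <- function(curve, Erev_mV, exclude_mV = 1) {
  keep <- abs(curve$Vm_mV - Erev_mV) >= exclude_mV
  stopifnot_msg(any(keep), "all points lie within the exclusion window")
  g <- curve$density_pA_pF[keep] / (curve$Vm_mV[keep] - Erev_mV)
  out <- data.frame(Vm_mV = curve$Vm_mV[keep], G_norm = abs(g) / max(abs(g)))
  attr(out, "excluded_mV") <- curve$Vm_mV[!keep]
  out
}

#' Boltzmann fit of a normalized activation or availability curve
#'
#' Least-squares fit of `y = 1 / (1 + exp(s * (Vm - Vh) / k))` with `s = -1`
#' for rising curves (activation: y grows with depolarization) and `s = +1`
#' for falling curves (steady-state inactivation / availability). The slope
#' factor is always reported positive.
#'
#' @param points Data.frame with columns `Vm_mV` (or first column) and `y`
#'   (or second column), y roughly in \[0, 1.2\], at least 5 points.
#' @param direction `"rising"` or `"falling"`.
#' @return A `gating_fit` list with `Vh_mV`, `k_mV`, `curve_role`,
#'   `fit_rmse`.
#' @export
boltzmann_fit <- function(points, direction = c("rising", "falling")) {
  direction <- match.arg(direction)
  stopifnot_msg(is.data.frame(points) && nrow(points) >= 5L,
                "need at least 5 points")
  v <- points[[1]]
  y <- points[[2]]
  stopifnot_msg(all(y > -0.05) && all(y < 1.25),
                "y must be a normalized curve in [0, 1.2]")
  s <- if (direction == "rising") -1 else 1
  ord <- order(v); v <- v[ord]; y <- y[ord]
  yy <- if (direction == "rising") y else 1 - y
  vh0 <- cross_time(v, yy, 0.5, 1L, 1L, "above")
  if (is.na(vh0)) vh0 <- v[which.min(abs(yy - 0.5))]
  v10 <- cross_time(v, yy, 0.1, 1L, 1L, "above")
  v90 <- cross_time(v, yy, 0.9, 1L, 1L, "above")
  k0 <- if (is.finite(v10) && is.finite(v90) && v90 > v10)
    (v90 - v10) / 4.4 else 5
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + exp(s * (v - Vh) / k)),
                      start = list(Vh = vh0, k = k0),
                      lower = c(Vh = vh0 - 50, k = 0.1),
                      upper = c(Vh = vh0 + 50, k = 100)),
    error = function(e) stop(sprintf(
      "Boltzmann fit did not converge (starts: Vh %.3g, k %.3g): %s",
      vh0, k0, conditionMessage(e)), call. = FALSE))
  cf <- coef(fit)
  structure(list(Gmax = NULL, Erev_mV = NULL, Vh_mV = unname(cf["Vh"]),
                 k_mV = unname(cf["k"]),
                 curve_role = if (direction == "rising")
                   "activation_conductance" else "availability_inactivation",
                 fit_rmse = sqrt(mean(stats::residuals(fit)^2))),
            class = "gating_fit")
}

#' Steady-state inactivation (availability) curve
#'
#' Test-pulse peak amplitudes, one per conditioning prepulse potential,
#' normalized to the maximum available current (attained at the most
#' negative prepulse).
#'
#' @param set A [sweep_set()] recorded under an inactivation protocol
#'   (`inact_na` or `inact_cal`); each sweep must carry `prepulse_mV`.
#' @param polarity Test-pulse peak polarity (default `"inward"`).
#' @param blank_ms Capacitive-transient blanking (ms).
#' @return A data.frame with `prepulse_mV` and normalized `y`, ordered by
#'   prepulse potential.
#' @export
inactivation_curve <- function(set, polarity = c("inward", "outward"),
                               blank_ms = 0.3) {
  polarity <- match.arg(polarity)
  stopifnot_msg(set$protocol %in% c("inact_na", "inact_cal", "outward_k"),
                "set must use an inactivation protocol")
  pp <- vapply(set$sweeps, `[[`, numeric(1), "prepulse_mV")
  stopifnot_msg(all(is.finite(pp)), "sweeps lack prepulse potentials")
  amp <- vapply(set$sweeps, peak_amplitude, numeric(1),
                polarity = polarity, blank_ms = blank_ms)
  stopifnot_msg(max(abs(amp)) > 0, "no test-pulse current in any sweep")
  ord <- order(pp)
  data.frame(prepulse_mV = pp[ord], y = (abs(amp) / max(abs(amp)))[ord])
}

# extremum-minus-end amplitude inside an arbitrary pulse window
peak_in_window <- function(sweep, t0, dur, polarity, blank_ms = 0.3,
                           end_frac = 0.05) {
  win <- which(sweep$time_ms >= t0 + blank_ms & sweep$time_ms <= t0 + dur)
  i <- sweep$current_pA[win]
  endw <- which(sweep$time_ms >= t0 + dur * (1 - end_frac) &
                  sweep$time_ms <= t0 + dur)
  ext <- if (polarity == "inward") min(i) else max(i)
  ext - mean(sweep$current_pA[endw])
}

#' Recovery from inactivation (reactivation) kinetics
#'
#' Each sweep holds a P1/P2 double-pulse pair: P1 at full availability,
#' then P2 after a coupling interval at the holding potential. The P2/P1
#' peak ratio versus interval is fitted with the monoexponential recovery
#' `ratio = plateau * (1 - exp(-t / tau))`; the plateau is fixed at 1 by
#' default (full recovery) or can be freed.
#'
#' @param set A [sweep_set()] with protocol `"recovery_na"`; each sweep
#'   carries `interval_ms`, with P2 starting at
#'   `pulse_start_ms + pulse_duration_ms + interval_ms`.
#' @param polarity Peak polarity (default `"inward"`).
#' @param fixed_plateau Fix the recovery plateau at 1 (default TRUE).
#' @param blank_ms Capacitive-transient blanking (ms).
#' @return A `kinetics_fit` list: `tau_react_ms`, `plateau`, `fit_rmse`,
#'   and the `data` (interval, ratio) used.
#' @export
recovery_from_inactivation <- function(set, polarity = c("inward", "outward"),
                                       fixed_plateau = TRUE, blank_ms = 0.3) {
  polarity <- match.arg(polarity)
  stopifnot_msg(set$protocol == "recovery_na",
                "set must use the recovery_na protocol")
  iv <- vapply(set$sweeps, `[[`, numeric(1), "interval_ms")
  stopifnot_msg(sum(is.finite(iv)) >= 4L, "need at least 4 coupling intervals")
  ratio <- vapply(set$sweeps, function(s) {
    p1 <- peak_in_window(s, s$pulse_start_ms, s$pulse_duration_ms, polarity,
                         blank_ms)
    p2 <- peak_in_window(s, s$pulse_start_ms + s$pulse_duration_ms +
                           s$interval_ms, s$pulse_duration_ms, polarity,
                         blank_ms)
    p2 / p1
  }, numeric(1))
  ord <- order(iv)
  dat <- data.frame(interval_ms = iv[ord], ratio = ratio[ord])
  tau0 <- {
    i <- which(dat$ratio >= 1 - exp(-1))[1]
    if (is.na(i)) max(dat$interval_ms) / 3 else max(dat$interval_ms[i], 0.5)
  }
  if (fixed_plateau) {
    fit <- minpack.lm::nlsLM(ratio ~ 1 - exp(-interval_ms / tau), data = dat,
                             start = list(tau = tau0),
                             lower = c(tau = 1e-4))
    plateau <- 1
  } else {
    fit <- minpack.lm::nlsLM(ratio ~ A * (1 - exp(-interval_ms / tau)),
                             data = dat, start = list(A = 1, tau = tau0),
                             lower = c(A = 0, tau = 1e-4))
    plateau <- unname(coef(fit)["A"])
  }
  structure(list(tau_react_ms = unname(coef(fit)["tau"]), plateau = plateau,
                 fit_rmse = sqrt(mean(stats::residuals(fit)^2)), data = dat),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  flds <- x[vapply(x, function(v) is.numeric(v) && length(v) == 1L,
                   logical(1))]
  cat("<kinetics_fit>",
      paste(names(flds), vapply(flds, function(v) sprintf("%.4g", v), ""),
            sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Exponential decay kinetics of a transient current
#'
#' Fits the decay of the current from its peak to the end of the pulse with
#' a monoexponential `A * exp(-t / tau) + C` or a biexponential
#' `Af * exp(-t / tau_f) + As * exp(-t / tau_s) + C` (`tau_f < tau_s`
#' enforced by ordering the fitted pair). When the activation time constant
#' is known (e.g. for fast Na+ current, where activation and fast
#' inactivation overlap in time), pass it as `tau_act_ms`: the trace is
#' divided by the activation factor `1 - exp(-t/tau_act)` before fitting,
#' which removes the otherwise substantial bias in the fast time constant.
#'
#' A biexponential fit whose smaller component carries less than
#' `min_fraction` of the total amplitude falls back to the monoexponential
#' fit, flagged. A flat trace returns `tau = NA`, flagged as degenerate.
#'
#' @param sweep A [clamp_sweep()].
#' @param model `"mono"` or `"bi"`.
#' @param polarity Peak polarity (default `"inward"`).
#' @param tau_act_ms Optional known activation time constant (ms) used to
#'   correct the decay segment (see Details).
#' @param blank_ms Capacitive-transient blanking (ms).
#' @param min_fraction Minimum biexponential amplitude fraction before
#'   falling back to mono (default 0.02).
#' @return A `kinetics_fit` list. Mono: `tau_inact_mono_ms`, `A`, `C`.
#'   Bi: `tau_fast_inact_ms`, `tau_slow_inact_ms`, `amp_fast_fraction`,
#'   `C`. Both carry `fit_rmse` and `flagged` (`NA`, `"degenerate"` or
#'   `"bi_fallback_mono"`).
#' @export
decay_kinetics <- function(sweep, model = c("mono", "bi"),
                           polarity = c("inward", "outward"),
                           tau_act_ms = NULL, blank_ms = 0.3,
                           min_fraction = 0.02) {
  model <- match.arg(model)
  polarity <- match.arg(polarity)
  base <- baseline_level(sweep)
  win <- pulse_indices(sweep, blank_ms)
  i <- sweep$current_pA[win] - base
  tpulse <- sweep$time_ms[win] - sweep$pulse_start_ms

  if (!is.null(tau_act_ms)) {
    a <- 1 - exp(-tpulse / tau_act_ms)
    keep <- a >= 0.5
    y <- i[keep] / a[keep]
    tt <- tpulse[keep] - tpulse[keep][1]
  } else {
    ip <- if (polarity == "inward") which.min(i) else which.max(i)
    y <- i[ip:length(i)]
    tt <- tpulse[ip:length(i)] - tpulse[ip]
  }
  if (polarity == "inward") y <- -y # fit a positive-going decay

  span <- diff(range(y))
  if (!(span > 1e-9)) {
    return(structure(list(tau_inact_mono_ms = NA_real_, A = 0,
                          C = mean(y), fit_rmse = 0, model = "mono",
                          flagged = "degenerate"),
                     class = "kinetics_fit"))
  }
  cend <- mean(tail(y, max(3L, length(y) %/% 20)))
  a0 <- y[1] - cend
  tau0 <- {
    lvl <- cend + a0 * exp(-1)
    tc <- cross_time(tt, y, lvl, 1L, 1L, if (a0 > 0) "below" else "above")
    if (is.finite(tc) && tc > 0) tc else max(tt) / 5
  }

  fit_mono <- function() {
    fit <- minpack.lm::nlsLM(y ~ A * exp(-tt / tau) + C,
                             start = list(A = a0, tau = tau0, C = cend),
                             lower = c(A = -Inf, tau = 1e-4, C = -Inf))
    cf <- coef(fit)
    structure(list(tau_inact_mono_ms = unname(cf["tau"]),
                   A = unname(cf["A"]), C = unname(cf["C"]),
                   fit_rmse = sqrt(mean(stats::residuals(fit)^2)),
                   model = "mono", flagged = NA_character_),
              class = "kinetics_fit")
  }
  if (model == "mono") return(fit_mono())

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ Af * exp(-tt / tf) + As * exp(-tt / ts) + C,
      start = list(Af = 0.7 * a0, tf = tau0 / 3, As = 0.3 * a0,
                   ts = tau0 * 3, C = cend),
      lower = c(Af = -Inf, tf = 1e-4, As = -Inf, ts = 1e-4, C = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- fit_mono()
    out$flagged <- "bi_fallback_mono"
    return(out)
  }
  cf <- coef(fit)
  taus <- c(cf["tf"], cf["ts"])
  amps <- c(cf["Af"], cf["As"])
  ordr <- order(taus)
  taus <- taus[ordr]; amps <- amps[ordr]
  frac_fast <- abs(amps[1]) / (abs(amps[1]) + abs(amps[2]))
  if (min(frac_fast, 1 - frac_fast) < min_fraction ||
      abs(taus[2] / taus[1] - 1) < 1e-3) {
    out <- fit_mono()
    out$flagged <- "bi_fallback_mono"
    return(out)
  }
  structure(list(tau_fast_inact_ms = unname(taus[1]),
                 tau_slow_inact_ms = unname(taus[2]),
                 amp_fast_fraction = unname(frac_fast),
                 C = unname(cf["C"]),
                 fit_rmse = sqrt(mean(stats::residuals(fit)^2)),
                 model = "bi", flagged = NA_character_),
            class = "kinetics_fit")
}
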