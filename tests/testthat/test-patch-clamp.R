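make_pulse <- function(fun, pulse = 50, fs = 10000, pre = 5, post = 5,
                       vm = -30) {
  t <- seq(0, pre + pulse + post, by = 1000 / fs)
  i <- numeric(length(t))
  inp <- t >= pre & t <= pre + pulse
  i[inp] <- fun(t[inp] - pre)
  clamp_sweep(t, i, vm, -120, pre, pulse)
}

test_that("amplitude measurements follow the peak-minus-end convention", {
  sw <- make_pulse(function(t) -100 - 1400 * exp(-t / 3))
  expect_equal(peak_amplitude(sw, "inward"), -1400, tolerance = 30)
  flat <- make_pulse(function(t) rep(0, length(t)))
  expect_equal(peak_amplitude(flat, "inward"), 0)
  expect_equal(sustained_amplitude(flat), 0)
  step <- make_pulse(function(t) rep(200, length(t)))
  expect_equal(sustained_amplitude(step), 200)
  # biexponential decay to a 150-pA plateau
  bi <- make_pulse(function(t) 150 + 500 * exp(-t / 1.5) + 100 * exp(-t / 5))
  expect_equal(sustained_amplitude(bi), 150, tolerance = 1)
  expect_error(peak_amplitude(make_pulse(function(t) t, pulse = 0.2)),
               "blanking")
})

test_that("current density is amplitude over capacitance", {
  expect_equal(current_density(-1500, 150), -10)
  expect_equal(current_density(0, 37), 0)
  expect_equal(current_density(-800, 200), current_density(-800, 100) / 2)
  expect_error(current_density(100, 0), "> 0")
})

test_that("I-V construction matches the generator's analytic peak densities", {
  set <- gen_voltage_clamp(gating_spec("na"), "iv_na")
  truth <- attr(set, "truth")$per_sweep
  iv <- build_iv(set, "peak_minus_end")
  expect_equal(iv$Vm_mV, truth$Vm_mV)
  big <- abs(truth$peak_minus_end_density) > 1
  expect_lt(max(abs(iv$density_pA_pF[big] - truth$peak_minus_end_density[big]) /
                  abs(truth$peak_minus_end_density[big])), 0.01)
  # duplicate potentials are rejected
  dup <- set
  dup$sweeps[[2]]$test_potential_mV <- dup$sweeps[[1]]$test_potential_mV
  expect_error(build_iv(dup), "duplicate")
  # single sweep -> single-point curve
  one <- sweep_set(set$sweeps[1], "iv_na", set$cell_capacitance_pF)
  expect_identical(nrow(build_iv(one)), 1L)
})

test_that("fit_iv recovers noiseless gating parameters within 0.1% and saturates ohmically", {
  set <- gen_voltage_clamp(gating_spec("na"), "iv_na")
  iv <- build_iv(set, "peak_minus_end")
  fit <- fit_iv(iv)
  expect_equal(fit$Vh_mV, -52.9, tolerance = 0.001 * 52.9)
  expect_equal(fit$k_mV, 4.0, tolerance = 0.001 * 4)
  expect_equal(fit$Erev_mV, 65, tolerance = 0.001 * 65)
  # far above Vh the fitted curve approaches the Gmax*(V - Erev) line
  vfar <- 30
  pred <- fit$Gmax * (vfar - fit$Erev_mV) /
    (1 + exp(-(vfar - fit$Vh_mV) / fit$k_mV))
  expect_equal(pred, fit$Gmax * (vfar - fit$Erev_mV), tolerance = 1e-3)
  expect_error(fit_iv(iv[1:3, ]), "at least 5")
})

test_that("the conductance route agrees with the I-V fit (two routes, one truth)", {
  set <- gen_voltage_clamp(gating_spec("na"), "iv_na")
  iv <- build_iv(set, "peak_minus_end")
  fit <- fit_iv(iv)
  g <- conductance_curve(iv, fit$Erev_mV)
  bf <- boltzmann_fit(g, "rising")
  expect_lt(abs(bf$Vh_mV - fit$Vh_mV), 1)
  expect_lt(abs(bf$k_mV - fit$k_mV), 0.5)
  # ohmic line -> constant conductance
  line <- data.frame(Vm_mV = seq(-40, 40, 10),
                     density_pA_pF = 0.5 * (seq(-40, 40, 10) - 65))
  gl <- conductance_curve(line, 65)
  expect_true(all(abs(gl$G_norm - 1) < 1e-12))
  # the singular point at Vm = Erev is excluded and flagged
  near <- data.frame(Vm_mV = c(seq(-40, 60, 10), 65),
                     density_pA_pF = c(0.5 * (seq(-40, 60, 10) - 65), 0))
  gn <- conductance_curve(near, 65)
  expect_false(65 %in% gn$Vm_mV)
  expect_true(65 %in% attr(gn, "excluded_mV"))
  expect_error(conductance_curve(line[abs(line$Vm_mV - 65) < 1, , drop = FALSE],
                                 65), "exclusion")
})

test_that("Boltzmann fits are exact on noiseless curves and translation equivariant", {
  v <- seq(-140, -20, 10)
  y <- 1 / (1 + exp((v + 86.9) / 5))
  bf <- boltzmann_fit(data.frame(v, y), "falling")
  expect_equal(bf$Vh_mV, -86.9, tolerance = 1e-6)
  expect_equal(bf$k_mV, 5, tolerance = 1e-6)
  # fitted curve passes through 0.5 at Vh by definition
  expect_equal(1 / (1 + exp((bf$Vh_mV - bf$Vh_mV) / bf$k_mV)), 0.5)
  shift <- boltzmann_fit(data.frame(v + 17, y), "falling")
  expect_equal(shift$Vh_mV, bf$Vh_mV + 17, tolerance = 1e-6)
  expect_equal(shift$k_mV, bf$k_mV, tolerance = 1e-6)
})

test_that("inactivation curves are availability-normalized with midpoint at Vh_inact", {
  set <- gen_voltage_clamp(gating_spec("na"), "inact_na")
  curve <- inactivation_curve(set)
  expect_equal(curve$y[1], 1, tolerance = 1e-6) # most negative prepulse
  expect_lt(curve$y[nrow(curve)], 0.01)         # fully inactivating prepulse
  bf <- boltzmann_fit(curve, "falling")
  expect_lt(abs(bf$Vh_mV - (-86.9)), 1)
})

test_that("recovery from inactivation is recovered within 1% and saturates at 1", {
  set <- gen_voltage_clamp(gating_spec("na"), "recovery_na")
  fit <- recovery_from_inactivation(set)
  expect_equal(fit$tau_react_ms, 8.2, tolerance = 0.01 * 8.2)
  expect_equal(fit$data$ratio[nrow(fit$data)], 1, tolerance = 0.01)
  # doubling tau doubles the interval at which the ratio reaches 1 - 1/e
  fit2 <- recovery_from_inactivation(
    gen_voltage_clamp(gating_spec("na", tau_react_ms = 16.4), "recovery_na"))
  expect_equal(fit2$tau_react_ms / fit$tau_react_ms, 2, tolerance = 0.02)
  few <- sweep_set(set$sweeps[1:3], "recovery_na", set$cell_capacitance_pF)
  expect_error(recovery_from_inactivation(few), "at least 4")
})

test_that("decay kinetics: mono and bi fits recover generator time constants", {
  # pure monoexponential, tau = 156 ms (outward K convention)
  mono <- make_pulse(function(t) 300 + 900 * exp(-t / 156), pulse = 500,
                     fs = 4000, vm = 50)
  fit <- decay_kinetics(mono, "mono", polarity = "outward")
  expect_equal(fit$tau_inact_mono_ms, 156, tolerance = 0.01 * 156)

  # biexponential Na decay at 50 kHz, activation divided out
  sp <- gating_spec("na")
  set <- gen_voltage_clamp(sp, "iv_na")
  vms <- vapply(set$sweeps, `[[`, numeric(1), "test_potential_mV")
  bi <- decay_kinetics(set$sweeps[[which(vms == -30)]], "bi",
                       tau_act_ms = sp$tau_act_ms)
  expect_equal(bi$tau_fast_inact_ms, 1.3, tolerance = 0.05 * 1.3)
  expect_equal(bi$tau_slow_inact_ms, 4.5, tolerance = 0.05 * 4.5)
  expect_lt(bi$tau_fast_inact_ms, bi$tau_slow_inact_ms)

  # a bi fit with a negligible slow component degrades to mono, flagged
  nearly_mono <- make_pulse(function(t) 1000 * exp(-t / 2) +
                              5 * exp(-t / 20), fs = 50000, vm = -30)
  fb <- decay_kinetics(nearly_mono, "bi", polarity = "outward")
  if (fb$model == "mono") {
    expect_identical(fb$flagged, "bi_fallback_mono")
    expect_equal(fb$tau_inact_mono_ms, 2, tolerance = 0.1)
  } else {
    expect_equal(fb$tau_fast_inact_ms, 2, tolerance = 0.1)
  }

  # constant trace: degenerate, flagged
  flat <- make_pulse(function(t) rep(100, length(t)))
  dg <- decay_kinetics(flat, "mono", polarity = "outward")
  expect_identical(dg$flagged, "degenerate")
  expect_true(is.na(dg$tau_inact_mono_ms))
})

test_that("late-current percentages follow their definition", {
  no_decay <- make_pulse(function(t) rep(-500, length(t)), pulse = 500,
                         fs = 2000, vm = -40)
  expect_equal(late_current_percent(no_decay), 100)
  to_1pct <- make_pulse(function(t) -1000 * pmax(exp(-t / 30), 0.01),
                        pulse = 500, fs = 2000, vm = -40)
  expect_equal(late_current_percent(to_1pct), 1, tolerance = 0.02)
  sp <- gating_spec("na")
  lna <- gen_voltage_clamp(sp, "late_na")
  expect_equal(late_current_percent(lna$sweeps[[1]]), 0.5, tolerance = 0.05)
  flat0 <- make_pulse(function(t) rep(0, length(t)))
  expect_error(late_current_percent(flat0), "peak")
})

test_that("charge integration matches closed forms and is linear", {
  # flat sustained current carries zero charge
  flat <- make_pulse(function(t) rep(400, length(t)), pulse = 500, fs = 4000,
                     vm = 50)
  expect_equal(charge_density(flat, 100), 0, tolerance = 1e-9)
  # exponential transient: integral A*tau*(1 - exp(-T/tau))
  A <- 1000; tau <- 50; Tp <- 500; cm <- 100
  ex <- make_pulse(function(t) A * exp(-t / tau), pulse = Tp, fs = 4000,
                   vm = 50)
  expect_equal(charge_density(ex, cm),
               A * tau * (1 - exp(-Tp / tau)) / 1000 / cm, tolerance = 0.02)
  # triangular transient peaking after the blanking window: h*b/2
  tri <- make_pulse(function(t) ifelse(t < 1, 800 * t,
                                       pmax(0, 800 * (1 - (t - 1) / 40))),
                    pulse = 500, fs = 4000, vm = 50)
  expect_equal(charge_density(tri, cm), 800 * 40 / 2 / 1000 / cm,
               tolerance = 0.02)
  # linearity: equal end levels add
  s1 <- make_pulse(function(t) 500 * exp(-t / 20), pulse = 500, fs = 4000)
  s2 <- make_pulse(function(t) 300 * exp(-t / 60), pulse = 500, fs = 4000)
  s12 <- s1; s12$current_pA <- s1$current_pA + s2$current_pA
  expect_equal(charge_density(s12, cm, "outward"),
               charge_density(s1, cm, "outward") +
                 charge_density(s2, cm, "outward"),
               tolerance = 0.02)
})

test_that("IK1 is measured at the end of the pulses and matches the ohmic model", {
  sp <- gating_spec("kout", Gmax_nS = 5, Erev_mV = -85)
  set <- gen_voltage_clamp(sp, "ik1")
  curve <- ik1_measure(set)
  truth <- attr(set, "truth")$per_sweep
  expect_equal(curve$Vm_mV, truth$Vm_mV) # ordering preserved
  expect_equal(curve$density_pA_pF, truth$end_density, tolerance = 1e-9)
  zero <- gen_voltage_clamp(gating_spec("kout", Gmax_nS = 5, Erev_mV = -85,
                                        noise_sd_pA = 0), "ik1")
  zero$sweeps <- lapply(zero$sweeps, function(s) {
    s$current_pA[] <- 0
    s
  })
  expect_true(all(ik1_measure(zero)$density_pA_pF == 0))
})

test_that("densities scale as 1/Cm across the module", {
  sp1 <- gating_spec("na", capacitance_pF = 100)
  sp2 <- gating_spec("na", capacitance_pF = 200)
  iv1 <- build_iv(gen_voltage_clamp(sp1, "iv_na"))
  iv2 <- build_iv(gen_voltage_clamp(sp2, "iv_na"))
  expect_equal(iv2$density_pA_pF, iv1$density_pA_pF / 2, tolerance = 1e-9)
  ko1 <- gen_voltage_clamp(gating_spec("kout", capacitance_pF = 100),
                           "outward_k")
  ko2 <- gen_voltage_clamp(gating_spec("kout", capacitance_pF = 200),
                           "outward_k")
  expect_equal(charge_curve(ko2)$charge_pC_pF,
               charge_curve(ko1)$charge_pC_pF / 2, tolerance = 1e-9)
})

test_that("sweep bundles survive a directory round trip", {
  set <- gen_voltage_clamp(gating_spec("na", seed = 5), "inact_na")
  d <- tempfile()
  write_sweep_bundle(set, d)
  back <- read_sweep_bundle(d)
  expect_identical(back$protocol, "inact_na")
  expect_equal(back$cell_capacitance_pF, set$cell_capacitance_pF)
  expect_equal(vapply(back$sweeps, `[[`, numeric(1), "prepulse_mV"),
               vapply(set$sweeps, `[[`, numeric(1), "prepulse_mV"))
  expect_equal(back$sweeps[[3]]$current_pA, set$sweeps[[3]]$current_pA,
               tolerance = 1e-6)
  unlink(d, recursive = TRUE)
})
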