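std_solutions <- fixture_solutions()

test_that("closed channels and no stimulus give a static cell", {
  m <- cell_model(internal = std_solutions$pipette_standard,
                  bath = std_solutions$bath_standard)
  y0 <- initial_state(m)
  d <- state_derivative(0, y0, m, NULL)
  expect_equal(max(abs(d$dy)), 0)
  expect_equal(unname(d$globals["i_s"]), 0)
})

test_that("resting state zeroes every gate drive and hits the target Vm", {
  r <- neuron_model()
  expect_equal(r$Vm, -0.070, tolerance = 1e-8)
  p <- voltage_clamp(data.frame(t0 = 0, t1 = 0.001, Vs = -0.070),
                     Rs = 2.4e6)
  d <- state_derivative(0, r$y0, r$model, p)
  n <- nrow(r$model$tab)
  gate_derivs <- d$dy[-(seq_len(n))]
  expect_lt(max(abs(gate_derivs)), 1e-6)
  # all channels sense their optimum: sigma == sigma_bar
  for (h in names(r$model$channels))
    expect_equal(unname(d$globals[paste0("theta.", h)]), 0,
                 tolerance = 1e-9)
})

test_that("resting charge agrees with an independent closed-form grid scan", {
  r <- neuron_model()
  tab <- r$model$tab; k <- r$model$k
  ain <- r$model$internal; aex <- r$model$bath
  chi <- k$F^2 / (2 * k$R * k$T * r$model$geom$eps_m)
  # independent reimplementation of the potential map, written out directly
  vm_direct <- function(Q) {
    X <- chi * (Q / k$F) * tab$lambda * tab$z
    inc <- ain > 0 & aex > 0
    w <- pmin(ain[inc], aex[inc])
    Vi <- (k$R * k$T) / (k$F * tab$z[inc]) *
      (log(ain[inc] / aex[inc]) + 4 * atanh(X[inc]))
    sum(w * Vi) / sum(w)
  }
  qs <- seq(-1.2e-3, 1.2e-3, length.out = 100001)
  vms <- vapply(qs, vm_direct, 0)
  i <- which(diff(sign(vms + 0.070)) != 0)[1]
  expect_true(r$Q >= qs[i] && r$Q <= qs[i + 1])
})

test_that("a clamped resting membrane stays at rest", {
  r <- neuron_model()
  p <- voltage_clamp(data.frame(t0 = 0, t1 = 0.05, Vs = -0.070),
                     Rs = 2.4e6)
  tr <- simulate_protocol(r$model, r$y0, p, sim_config(sample_dt = 1e-3))
  expect_lt(diff(range(tr$Vm)), 5e-5)   # < 0.05 mV drift over 50 ms
  expect_lt(max(abs(tr$I)), 1e-3)
})

test_that("simulated traces conserve per-ion amounts and charge bookkeeping", {
  r <- neuron_model()
  p <- voltage_clamp(data.frame(t0 = c(-0.005, 0), t1 = c(0, 0.03),
                                Vs = c(-0.07, 0.01)), Rs = 2.4e6)
  tr <- simulate_protocol(r$model, r$y0, p, sim_config(sample_dt = 1e-4))
  geom <- r$model$geom; tab <- r$model$tab; k <- r$model$k
  for (ion in tab$name) {
    dqc <- (geom$r / 3) * (tr[[paste0("ain.", ion)]][nrow(tr)] -
                             tr[[paste0("ain.", ion)]][1])
    intu <- trapz(tr$t, tr[[paste0("u.", ion)]])
    expect_equal(dqc, intu,
                 tolerance = max(1e-3, 1e-10 / max(abs(intu), 1e-12)))
  }
  # Q column equals the direct recomputation from the concentrations
  Qre <- apply(tr[paste0("ain.", tab$name)], 1, function(a)
    k$F * (geom$r / 3) * sum(tab$z * a))
  expect_equal(unname(Qre), tr$Q, tolerance = 1e-10)
  # and its net change matches the integrated charge flux (Kirchhoff)
  dQ_flux <- k$F * sum(tab$z * vapply(tab$name, function(ion)
    trapz(tr$t, tr[[paste0("u.", ion)]]), 0))
  expect_equal(tr$Q[nrow(tr)] - tr$Q[1], dQ_flux, tolerance = 1e-3)
})

test_that("repeated simulations are bit-identical", {
  r <- neuron_model()
  p <- voltage_clamp(data.frame(t0 = c(-0.005, 0), t1 = c(0, 0.02),
                                Vs = c(-0.07, 0.03)), Rs = 2.4e6)
  t1 <- simulate_protocol(r$model, r$y0, p, sim_config(sample_dt = 2e-4))
  t2 <- simulate_protocol(r$model, r$y0, p, sim_config(sample_dt = 2e-4))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("solutions refine as the tolerances tighten", {
  r <- neuron_model()
  p <- voltage_clamp(data.frame(t0 = c(-0.005, 0), t1 = c(0, 0.03),
                                Vs = c(-0.07, 0.03)), Rs = 2.4e6)
  coarse <- simulate_protocol(r$model, r$y0, p,
                              sim_config(rtol = 1e-6, atol = 1e-9,
                                         sample_dt = 1e-3))
  fine <- simulate_protocol(r$model, r$y0, p,
                            sim_config(rtol = 5e-7, atol = 5e-10,
                                       sample_dt = 1e-3))
  expect_lt(abs(coarse$Vm[nrow(coarse)] - fine$Vm[nrow(fine)]), 1e-4)
})

test_that("capacitance scales with membrane permittivity and stays in band", {
  m1 <- cell_model(internal = std_solutions$pipette_standard,
                   bath = std_solutions$bath_standard)
  cm1 <- estimate_capacitance(m1, c(-0.02, 0.02), 21)
  m2 <- cell_model(internal = std_solutions$pipette_standard,
                   bath = std_solutions$bath_standard,
                   geom = cell_geometry(eps_r = 8))
  cm2 <- estimate_capacitance(m2, c(-0.02, 0.02), 21)
  mid <- 11
  expect_equal(cm2$Cm[mid] / cm1$Cm[mid], 2, tolerance = 0.1)
  expect_error(estimate_capacitance(m1, c(-1, 1), 11), "validity")
})

test_that("uncalibrated channels and unreachable rest targets error", {
  chs <- fixture_channels()["Nav"]
  m <- cell_model(internal = std_solutions$pipette_standard,
                  bath = std_solutions$bath_standard, channels = chs)
  p <- voltage_clamp(data.frame(t0 = 0, t1 = 0.01, Vs = 0), Rs = 2.4e6)
  expect_error(simulate_protocol(m, initial_state(m), p),
               "sigma_bar")
  expect_error(find_resting_state(m, -5), "not bracketed")
})
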