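test_that("electrode current is the per-area voltage error over Rs", {
  geom <- std_geom            # r = 10 um, S = 1.2566e-9 m2
  expect_identical(electrode_current(-0.07, -0.07, 2.4e6, geom), 0)
  expect_equal(electrode_current(0.03, -0.07, 2.4e6, geom), 33.157,
               tolerance = 1e-4)
  expect_equal(electrode_current(-0.07, 0.03, 2.4e6, geom),
               -electrode_current(0.03, -0.07, 2.4e6, geom))
})

test_that("Ag/AgCl stimulation flux is carried by chloride only", {
  js <- stimulation_flux(96.48533212, std_tab)
  expect_equal(js[["Cl"]], -1e-3, tolerance = 1e-9)
  expect_equal(unname(js[c("K", "Na", "Ca", "Cs", "A")]), rep(0, 5))
  expect_identical(stimulation_flux(0, std_tab),
                   setNames(rep(0, 6), std_tab$name))
  # the chloride flux carries the full stimulation current into the cell
  expect_equal(current_from_flux(stimulation_flux(12.5, std_tab), std_tab),
               12.5, tolerance = 1e-10)
  no_cl <- ion_table(ion_species("K", 1, 1e-9, 1e-9))
  expect_error(stimulation_flux(1, no_cl), "Cl")
})

test_that("protocols evaluate piecewise and left-continuously", {
  p <- voltage_clamp(data.frame(t0 = c(-0.01, 0), t1 = c(0, 0.05),
                                Vs = c(-0.07, 0.03)), Rs = 2.4e6)
  expect_equal(protocol_value(p, -0.001), -0.07)
  expect_equal(protocol_value(p, 0), -0.07)      # boundary: earlier segment
  expect_equal(protocol_value(p, 0.001), 0.03)
  expect_error(protocol_value(p, 1), "outside")
  expect_equal(protocol_span(p), c(-0.01, 0.05))
  pc <- current_clamp(data.frame(t0 = 0, t1 = 1, kind = "sin", value = NA,
                                 amp = 0.2, omega = 20 * pi))
  expect_equal(protocol_value(pc, 0.025), 0.2)   # sin(pi/2)
  pc2 <- current_clamp(data.frame(t0 = 0, t1 = 1, kind = "const",
                                  value = 0.1))
  expect_equal(protocol_value(pc2, c(0.2, 0.7)), c(0.1, 0.1))
  # segments must be contiguous
  expect_error(voltage_clamp(data.frame(t0 = c(0, 1), t1 = c(0.5, 2),
                                        Vs = c(0, 0)), Rs = 1),
               "contiguous")
})

test_that("recorded current uses the outward-positive convention", {
  u <- setNames(numeric(6), std_tab$name)
  expect_identical(recorded_current(u, std_tab), 0)
  u["K"] <- 1e-3              # K+ influx -> inward (negative) current
  expect_equal(recorded_current(u, std_tab), -96.48533212,
               tolerance = 1e-9)
  u2 <- setNames(numeric(6), std_tab$name)
  u2["Cl"] <- 1e-3            # Cl- influx -> outward (positive) current
  expect_equal(recorded_current(u2, std_tab),
               -recorded_current(u, std_tab))
})
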