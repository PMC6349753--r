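test_that("net charge is F * sum(z * qc) with qc = (r/3) * ain", {
  geom <- std_geom
  # electroneutral interior
  ain <- c(K = 140, Na = 10, Cl = 20, A = 130, Ca = 0, Cs = 0)
  expect_equal(net_charge(ain, geom, std_tab), 0, tolerance = 1e-12)
  # single-species value: with r = 10 um, ain = 3e-2 mol/m3 gives
  # qc = 1e-7 mol/m2 and Q = F * 1e-7
  ain <- c(K = 3e-2, Na = 0, Cl = 0, A = 0, Ca = 0, Cs = 0)
  expect_equal(net_charge(ain, geom, std_tab), 9.64853e-3, tolerance = 1e-5)
  # adding equal K+ and Cl- amounts leaves Q unchanged
  ain2 <- ain + c(K = 50, Na = 0, Cl = 50, A = 0, Ca = 0, Cs = 0)
  expect_equal(net_charge(ain2, geom, std_tab),
               net_charge(ain, geom, std_tab))
})

test_that("double-layer coefficient matches F^2/(2 R T eps_m) and scalings", {
  expect_equal(chi_coefficient(std_geom, std_k), 5.4507e16,
               tolerance = 1e-3)
  g2 <- cell_geometry(eps_r = 8)
  expect_equal(chi_coefficient(g2, std_k),
               chi_coefficient(std_geom, std_k) / 2)
  k2 <- phys_constants(580)
  expect_equal(chi_coefficient(cell_geometry(k = k2), k2),
               chi_coefficient(std_geom, std_k) / 2)
})

test_that("surface densities reduce to lambda * bulk at zero charge", {
  ain <- c(K = 140, Na = 10, Cl = 20, A = 130, Ca = 0, Cs = 0)
  aex <- c(Na = 145, K = 1, Ca = 2, Cl = 150, Cs = 0, A = 0)
  sd <- surface_densities(ain, aex, std_geom, std_tab, Q = 0)
  expect_equal(sd$tin, setNames(std_tab$lambda * ain[std_tab$name],
                                std_tab$name))
  expect_equal(sd$tex, setNames(std_tab$lambda * aex[std_tab$name],
                                std_tab$name))
})

test_that("inner and outer correction factors are reciprocal", {
  ain <- c(K = 140, Na = 10, Cl = 20, A = 130, Ca = 1, Cs = 0)
  aex <- c(Na = 145, K = 1, Ca = 2, Cl = 150, Cs = 0, A = 1)
  set.seed(3)
  for (Q in runif(5, -8e-4, 8e-4)) {
    sd <- surface_densities(ain, aex, std_geom, std_tab, Q = Q)
    expect_equal(sd$tin * sd$tex,
                 setNames(std_tab$lambda^2 * ain[std_tab$name] *
                            aex[std_tab$name], std_tab$name),
                 tolerance = 1e-12)
  }
})

test_that("cation inner-surface density increases monotonically with Q", {
  ain <- c(K = 140, Na = 10, Cl = 20, A = 130, Ca = 0, Cs = 0)
  aex <- c(Na = 145, K = 1, Ca = 2, Cl = 150, Cs = 0, A = 0)
  qs <- seq(-1e-3, 1e-3, length.out = 41)
  tins <- vapply(qs, function(Q)
    surface_densities(ain, aex, std_geom, std_tab, Q = Q)$tin[["K"]], 0)
  expect_true(all(diff(tins) > 0))
})

test_that("overload beyond |X| = 1 errors unless clipped", {
  ain <- c(K = 140, Na = 10, Cl = 20, A = 130, Ca = 0, Cs = 0)
  Qbig <- 1.2 * std_k$F /
    (chi_coefficient(std_geom, std_k) * max(std_tab$lambda))
  expect_error(surface_densities(ain, ain, std_geom, std_tab, Q = Qbig),
               "double-layer overload")
  sd <- surface_densities(ain, ain, std_geom, std_tab, Q = Qbig,
                          clip = TRUE)
  expect_true(attr(sd, "overload"))
  expect_true(all(abs(sd$X) < 1))
})

test_that("membrane potential follows (RT/Fz) log(tin/tex)", {
  tab <- ion_table(ion_species("X", +1, 1e-9, 1e-9))
  mk_sd <- function(tin, tex) structure(
    list(tin = c(X = tin), tex = c(X = tex), X = c(X = 0), Q = 0),
    class = "surface_densities")
  # equal densities: zero potential
  expect_equal(membrane_potential(mk_sd(1e-7, 1e-7), c(X = 1), c(X = 1),
                                  tab), 0)
  # density ratio of 10 at 290 K: 57.54 mV for z = +1
  expect_equal(membrane_potential(mk_sd(1e-6, 1e-7), c(X = 1), c(X = 1),
                                  tab), 0.0575426, tolerance = 1e-5)
  # sign flips with valence
  tabm <- ion_table(ion_species("X", -1, 1e-9, 1e-9))
  expect_equal(membrane_potential(mk_sd(1e-6, 1e-7), c(X = 1), c(X = 1),
                                  tabm), -0.0575426, tolerance = 1e-5)
  # zero density for an included ion is an error, absent ions are excluded
  expect_error(membrane_potential(mk_sd(0, 1e-7), c(X = 1), c(X = 1), tab),
               "undefined")
})

test_that("membrane potential is antisymmetric under swapping surfaces", {
  ain <- c(K = 140, Na = 10, Cl = 20, A = 130, Ca = 0, Cs = 0)
  aex <- c(Na = 145, K = 1, Ca = 2, Cl = 150, Cs = 0, A = 0)
  sd <- surface_densities(ain, aex, std_geom, std_tab, Q = 4e-4)
  swapped <- sd
  swapped$tin <- sd$tex; swapped$tex <- sd$tin
  expect_equal(membrane_potential(sd, ain, aex, std_tab),
               -membrane_potential(swapped, aex, ain, std_tab))
})

test_that("concentration derivative scales as 3 u / r", {
  u <- c(K = 1e-6, Na = 0, Cl = 0, Ca = 0, Cs = 0, A = 0)
  d <- concentration_derivative(u, std_geom)
  expect_equal(d[["K"]], 0.3)
  expect_equal(concentration_derivative(u, cell_geometry(radius = 5e-6)),
               2 * d)
  expect_equal(concentration_derivative(0 * u, std_geom), 0 * u)
})
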