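mk_spec <- function(...) {
  defaults <- list(name = "test", s = c(K = 1), rho0 = c(K = 100),
                   sigma_bar = 1e-8, tau = 1e-3, alpha = 100, beta = 100,
                   gamma = 10, delta = 0.1, tab = std_tab)
  args <- utils::modifyList(defaults, list(...))
  do.call(channel_spec, args)
}

test_that("sensor indicators hit their stated optima and limits", {
  # density deviation: zero at the optimum, +/- pi/2 in the limits
  expect_identical(deviation_theta(1e-8, 1e-8), 0)
  expect_equal(deviation_theta(0, 1e-8), -pi / 2)
  expect_equal(deviation_theta(1e8, 1e-8), pi / 2, tolerance = 1e-7)
  expect_equal(deviation_theta(sqrt(3) * 2, 2), pi / 6)
  # flux indicator: zero at zero flux, linear
  sp <- mk_spec(tau = 1, sigma_bar = 1e-6)
  expect_identical(flux_phi(sp, 0), 0)
  expect_equal(flux_phi(sp, 1e-6), 1)
  expect_equal(flux_phi(sp, 2e-6), 2 * flux_phi(sp, 1e-6))
})

test_that("gate targets satisfy the design identities", {
  sp <- mk_spec()
  expect_identical(v_target(sp, 0), 0)
  expect_equal(v_target(sp, pi / 2), 1)
  expect_equal(v_target(sp, -pi / 2), 1)
  expect_equal(v_target(sp, pi / 3), 0.5)
  expect_identical(w_target(0, 0.3), 0.5)
  expect_equal(w_target(0.3, 0.3), 0.25)       # acot(1) = pi/4
  expect_equal(w_target(-1e9, 0.3), 1, tolerance = 1e-8)
  expect_equal(w_target(1e9, 0.3), 0, tolerance = 1e-8)
  expect_identical(filter_target(mk_spec(kappa = c(K = 1)), 0, 0),
                   setNames(rep(1, 6), std_tab$name))
  f <- filter_target(mk_spec(kappa = c(K = 1)), 1, 1)
  expect_equal(f[["K"]], exp(-1))
  expect_equal(filter_target(mk_spec(), 3, 3),
               setNames(rep(1, 6), std_tab$name))  # kappa = 0
})

test_that("judging target reproduces the four-quadrant case analysis", {
  # deviating with flux that deepens the deviation -> close (< 1/2)
  expect_lt(w_target(0.5, 0.5), 0.5)
  expect_lt(w_target(-0.5, -0.5), 0.5)
  # flux that restores the optimum -> keep open (> 1/2)
  expect_gt(w_target(-0.5, 0.5), 0.5)
  expect_gt(w_target(0.5, -0.5), 0.5)
  # zero flux -> 1/2 regardless of deviation
  expect_identical(w_target(0, 1), 0.5)
  expect_identical(w_target(0, -1), 0.5)
  # theta = 0 uses prev_sign
  expect_lt(w_target(0.5, 0, prev_sign = 1), 1e-6)
  expect_gt(w_target(0.5, 0, prev_sign = -1), 1 - 1e-6)
})

test_that("deviation indicator round-trips through its inverse", {
  set.seed(5)
  for (sigma in 10^runif(20, -10, -6)) {
    th <- deviation_theta(sigma, 1e-8)
    expect_equal(1e-8 * tan((th + pi / 2) / 2), sigma, tolerance = 1e-9)
  }
})

test_that("gate and filter dynamics point inward at the state bounds", {
  set.seed(11)
  for (i in 1:25) {
    sp <- mk_spec(alpha = runif(1, 1, 5000), beta = runif(1, 1, 5000),
                  gamma = runif(1, 1, 500), delta = runif(1, 0.01, 0.5),
                  kappa = c(K = runif(1, 0, 20)))
    th <- runif(1, -pi / 2, pi / 2); ph <- runif(1, -10, 10)
    lo <- gate_derivatives(sp, channel_state(v = 0, w = 0), th, ph)
    hi <- gate_derivatives(sp, channel_state(v = 1, w = 1), th, ph)
    expect_gte(lo$dv, 0); expect_lte(hi$dv, 0)
    expect_gte(lo$dw, 0); expect_lte(hi$dw, 0)
    expect_lte(max(hi$df), 0)                       # f = 1: can only fall
    # f cannot cross zero: df = gamma (fbar - f) >= -gamma f since fbar > 0
    tiny <- channel_state(f = setNames(rep(1e-9, 6), std_tab$name))
    d <- gate_derivatives(sp, tiny, th, ph)$df
    expect_gte(min(d + sp$gamma * 1e-9), 0)   # fbar may underflow to 0
  }
})

test_that("state at its targets is a fixed point", {
  sp <- mk_spec(kappa = c(K = 2))
  th <- 0.4; ph <- -0.7
  st <- channel_state(v = v_target(sp, th), w = w_target(ph, th),
                      f = filter_target(sp, ph, th))
  d <- gate_derivatives(sp, st, th, ph)
  expect_equal(d$dv, 0, tolerance = 1e-12)
  expect_equal(d$dw, 0, tolerance = 1e-12)
  expect_equal(max(abs(d$df)), 0, tolerance = 1e-12)
})

test_that("permeability composes filter, gate and standard permeability", {
  sp <- mk_spec(rho0 = c(K = 100))
  expect_equal(permeability(sp, channel_state(v = 0, w = 1))[["K"]], 0)
  expect_equal(permeability(sp, channel_state(v = 1, w = 0))[["K"]], 0)
  expect_equal(permeability(sp, channel_state(v = 1, w = 1))[["K"]], 100)
  st <- channel_state(v = 0.5, w = 0.5,
                      f = setNames(rep(0.8, 6), std_tab$name))
  expect_equal(permeability(sp, st)[["K"]], 20)
})

test_that("channel flux runs down the surface-density difference", {
  sp <- mk_spec(rho0 = c(K = 1))
  open <- channel_state(v = 1, w = 1)
  sd <- list(tin = setNames(rep(1e-6, 6), std_tab$name),
             tex = setNames(rep(1e-6, 6), std_tab$name))
  expect_equal(channel_flux(sp, open, sd),
               setNames(rep(0, 6), std_tab$name))
  sd$tin["K"] <- 2e-6   # inner excess -> efflux (negative influx)
  z <- channel_flux(sp, open, sd)
  expect_equal(z[["K"]], -1e-6)
  # antisymmetric under swapping the surfaces at frozen permeability
  swapped <- list(tin = sd$tex, tex = sd$tin)
  expect_equal(channel_flux(sp, open, swapped), -z)
})

test_that("detected density and flux are linear sensitivity contractions", {
  sd <- list(tin = setNames(1:6 * 1e-8, std_tab$name),
             tex = setNames(rep(0, 6), std_tab$name))
  expect_equal(detected_density(mk_spec(s = c(K = 1)), sd), 1e-8)
  expect_equal(detected_density(mk_spec(s = c(K = 1, Na = 1)), sd), 3e-8)
  expect_equal(detected_density(mk_spec(s = c(K = 0)), sd), 0)
  # sensitivity orthogonal to the permeant ion: no detected flux
  zeta <- setNames(c(0, 0, 5e-6, 0, 0, 0), std_tab$name)   # Cl-carried
  expect_equal(detected_flux(mk_spec(s = c(Ca = 1)), zeta), 0)
  expect_equal(detected_flux(mk_spec(s = c(Cl = 1)), zeta), 5e-6)
})
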