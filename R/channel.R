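#' Define an ion-channel type
#'
#' A channel is a sensor (linear readout of inner-surface ion densities and of
#' its own flux), a two-part gate (an exploring variable `v` driven by the
#' density deviation and a judging variable `w` driven by whether the flux
#' helps or harms), and a per-ion selectivity filter `f` that inactivates
#' under sustained stimulation and occupancy.
#'
#' @param name Channel label.
#' @param s Named per-ion sensitivity vector (dimensionless, >= 0); ions not
#'   named get 0.
#' @param rho0 Named per-ion standard selective permeability, 1/s (>= 0).
#' @param sigma_bar Optimum detected density, mol/m^2 (> 0), or `NA` to be
#'   calibrated by [find_resting_state()].
#' @param tau Sensor time constant, s (> 0). Larger tau makes the gate more
#'   restrictive of flux.
#' @param alpha Exploring agility, 1/s (> 0).
#' @param beta Judging agility, 1/s (> 0).
#' @param gamma Filter agility, 1/s (> 0).
#' @param delta Baseline judgement rate factor (> 0): `beta*delta*(wbar - w)`
#'   is the judging rate while `v = 0`.
#' @param eta Tolerance to density deviation (> 0, default 1).
#' @param kappa Named per-ion inactivation coefficient (>= 0; default all 0,
#'   a non-inactivating channel).
#' @param m,n Named per-ion positive-integer exponents of the inactivation
#'   law (default 1).
#' @param tab Ion table the per-ion vectors are expanded over.
#' @return List of class `"channel_spec"` with full-length per-ion vectors.
#' @export
channel_spec <- function(name, s, rho0, sigma_bar = NA_real_,
                         tau, alpha, beta, gamma, delta, eta = 1,
                         kappa = NULL, m = NULL, n = NULL,
                         tab = default_ions()) {
  stopifnot(is.character(name), tau > 0, alpha > 0, beta > 0, gamma > 0,
            delta > 0, eta > 0)
  if (!is.na(sigma_bar)) stopifnot(sigma_bar > 0)
  s <- expand_ions(s, tab); rho0 <- expand_ions(rho0, tab)
  kappa <- expand_ions(kappa, tab)
  m <- expand_ions(m, tab, fill = 1); n <- expand_ions(n, tab, fill = 1)
  stopifnot(all(s >= 0), all(rho0 >= 0), all(kappa >= 0),
            all(m >= 1), all(n >= 1), all(m == round(m)), all(n == round(n)))
  structure(list(name = name, s = s, rho0 = rho0, sigma_bar = sigma_bar,
                 tau = tau, alpha = alpha, beta = beta, gamma = gamma,
                 delta = delta, eta = eta, kappa = kappa, m = m, n = n),
            class = "channel_spec")
}

#' Dynamic gating state of one channel
#'
#' @param v Exploring gate variable in `[0, 1]`.
#' @param w Judging gate variable in `[0, 1]`.
#' @param f Named per-ion filter state, each in `(0, 1]`.
#' @param tab Ion table.
#' @return List of class `"channel_state"`.
#' @export
channel_state <- function(v = 0, w = 0.5, f = NULL, tab = default_ions()) {
  f <- if (is.null(f)) stats::setNames(rep(1, nrow(tab)), tab$name)
       else expand_ions(f, tab, fill = 1)
  stopifnot(v >= 0, v <= 1, w >= 0, w <= 1, all(f > 0), all(f <= 1))
  structure(list(v = v, w = w, f = f), class = "channel_state")
}

#' Detected ionic density
#'
#' sigma = sum_i s_i * tin_i: channels sense only the inner membrane surface.
#'
#' @param spec Channel from [channel_spec()].
#' @param sd Surface densities from [surface_densities()].
#' @return sigma, mol/m^2.
#' @export
detected_density <- function(spec, sd) {
  sum(spec$s * sd$tin[names(spec$s)])
}

#' Detected ionic flux
#'
#' psi = sum_i s_i * zeta_i over the channel's own per-ion influx; positive
#' means sensed influx. A channel whose sensitivity is orthogonal to its
#' permeant ions detects no flux at all.
#'
#' @param spec Channel spec.
#' @param zeta Per-ion influx through this channel, mol/(m^2 s).
#' @return psi, mol/(m^2 s).
#' @export
detected_flux <- function(spec, zeta) {
  sum(spec$s * zeta[names(spec$s)])
}

#' Density-deviation indicator
#'
#' theta = 2 atan(sigma / sigma_bar) - pi/2: zero at the optimum
#' (sigma = sigma_bar), approaching -pi/2 as sigma -> 0 and +pi/2 as
#' sigma -> Inf; strictly increasing in sigma.
#'
#' @param sigma Detected density, mol/m^2 (>= 0).
#' @param sigma_bar Optimum density, mol/m^2 (> 0).
#' @return theta in radians.
#' @export
deviation_theta <- function(sigma, sigma_bar) {
  stopifnot(sigma_bar > 0)
  2 * atan(sigma / sigma_bar) - pi / 2
}

#' Flux-deviation indicator
#'
#' phi = tau * psi / sigma_bar, the sensed flux scaled by the channel's time
#' constant and optimum density; zero at zero flux, linear in psi.
#'
#' @param spec Channel spec (supplies `tau` and `sigma_bar` unless given).
#' @param psi Detected flux, mol/(m^2 s).
#' @param sigma_bar Optional override of the spec's optimum density.
#' @return phi, dimensionless.
#' @export
flux_phi <- function(spec, psi, sigma_bar = spec$sigma_bar) {
  stopifnot(sigma_bar > 0)
  spec$tau * psi / sigma_bar
}

#' Target of the exploring gate
#'
#' vbar = 1 - cos(eta * theta): zero only at theta = 0 and, with eta = 1,
#' reaching 1 at theta = +/- pi/2.
#'
#' @param spec Channel spec (supplies `eta`).
#' @param theta Density deviation, radians.
#' @export
v_target <- function(spec, theta) {
  1 - cos(spec$eta * theta)
}

#' Target of the judging gate
#'
#' wbar = acot(phi / theta) / pi with acot mapping the reals onto (0, pi):
#' wbar -> 0 when the flux deepens the deviation (phi/theta -> +Inf, close
#' the gate), wbar -> 1 when it restores the optimum (phi/theta -> -Inf,
#' keep open), and wbar = 1/2 at zero flux. At theta = 0 the ratio uses
#' sign(theta)*max(|theta|, 1e-9); at exactly theta = 0, `prev_sign` (the
#' sign of theta at the previous evaluation, default +1) disambiguates, and
#' wbar = 1/2 if phi is also 0.
#'
#' @param phi Flux indicator.
#' @param theta Density deviation, radians.
#' @param prev_sign Sign used when `theta` is exactly 0 (default +1).
#' @return wbar in (0, 1).
#' @export
w_target <- function(phi, theta, prev_sign = 1) {
  s <- if (theta == 0) sign(prev_sign) else sign(theta)
  if (s == 0) s <- 1
  th <- s * max(abs(theta), 1e-9)
  if (phi == 0) return(0.5)
  (pi / 2 - atan(phi / th)) / pi
}

#' Target of the selectivity filter
#'
#' fbar_i = exp(-kappa_i * phi^(2 m_i) * theta^(2 n_i)): 1 whenever either
#' indicator is at its optimum, strictly decreasing in |phi| and |theta| when
#' kappa_i > 0. kappa_i = 0 gives a non-inactivating channel.
#'
#' @param spec Channel spec.
#' @param phi,theta Deviation indicators.
#' @return Named per-ion fbar in (0, 1].
#' @export
filter_target <- function(spec, phi, theta) {
  exp(-spec$kappa * phi^(2 * spec$m) * theta^(2 * spec$n))
}

#' Gate and filter relaxation derivatives
#'
#' dv/dt = alpha (vbar - v); dw/dt = beta (wbar - w) (v + delta);
#' df_i/dt = gamma (fbar_i - f_i). Each variable relaxes toward its target,
#' so the bounds [0,1] (and (0,1] for f) are forward-invariant.
#'
#' @param spec Channel spec.
#' @param state Channel state from [channel_state()].
#' @param theta,phi Deviation indicators.
#' @return List with `dv`, `dw` and per-ion `df`.
#' @export
gate_derivatives <- function(spec, state, theta, phi) {
  vbar <- v_target(spec, theta)
  wbar <- w_target(phi, theta)
  fbar <- filter_target(spec, phi, theta)
  list(dv = spec$alpha * (vbar - state$v),
       dw = spec$beta * (wbar - state$w) * (state$v + spec$delta),
       df = spec$gamma * (fbar - state$f))
}

#' Instantaneous selective permeability
#'
#' rho_i = f_i * g * rho0_i with gate opening g = v * w; bounded by the
#' standard permeability.
#'
#' @param spec Channel spec.
#' @param state Channel state.
#' @return Named per-ion rho, 1/s.
#' @export
permeability <- function(spec, state) {
  state$f * (state$v * state$w) * spec$rho0
}

#' Per-channel ionic influx
#'
#' zeta_i = -rho_i * (tin_i - tex_i): ions flow down their surface-density
#' difference; positive values are influx.
#'
#' @param spec Channel spec.
#' @param state Channel state.
#' @param sd Surface densities.
#' @return Named per-ion influx, mol/(m^2 s).
#' @export
channel_flux <- function(spec, state, sd) {
  -permeability(spec, state) * (sd$tin - sd$tex)
}
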