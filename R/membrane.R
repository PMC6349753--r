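#' Spherical cell geometry
#'
#' @param radius Cell radius, m (default 10 um).
#' @param eps_r Relative membrane permittivity (default 4; plausible range
#'   roughly 1.4-20 for biological membranes).
#' @param k Constants from [phys_constants()].
#' @return List with `r` (m), `S` (surface area, m^2), `eps_r`, and
#'   `eps_m = eps_r * eps0` (F/m).
#' @export
cell_geometry <- function(radius = 1e-5, eps_r = 4, k = phys_constants()) {
  stopifnot(radius > 0, eps_r > 0)
  list(r = radius, S = 4 * pi * radius^2, eps_r = eps_r,
       eps_m = eps_r * k$eps0)
}

#' Internal charge per membrane area
#'
#' For a uniform interior the per-ion amount per membrane area is
#' qc_i = (r/3) * ain_i, and Q = F * sum_i z_i * qc_i. Positive Q means a net
#' cation excess inside.
#'
#' @param ain Per-ion average internal concentrations, mol/m^3.
#' @param geom Geometry from [cell_geometry()].
#' @param tab Ion table.
#' @param k Constants.
#' @return Q in C/m^2.
#' @export
net_charge <- function(ain, geom, tab, k = phys_constants()) {
  ain <- align_ions(ain, tab)
  k$F * sum(tab$z * (geom$r / 3) * ain)
}

#' Double-layer coefficient
#'
#' chi = F^2 / (2 R T eps_m), the single coefficient of the linearized
#' double-layer correction. Units m/mol.
#'
#' @inheritParams net_charge
#' @export
#' @examples
#' chi_coefficient(cell_geometry())   # ~5.45e16 at eps_r = 4, 290 K
chi_coefficient <- function(geom, k = phys_constants()) {
  k$F^2 / (2 * k$R * k$T * geom$eps_m)
}

#' Membrane-surface ion densities from the double-layer approximation
#'
#' The net internal charge Q accumulates within one ion diameter of the
#' membrane; the resulting constant field Q/eps_m tilts each ion's Boltzmann
#' profile across its own surface layer. Writing
#' `X_i = chi * (Q/F) * lambda_i * z_i`, the surface densities are
#' `tin_i = lambda_i * ain_i * (1+X_i)/(1-X_i)` and
#' `tex_i = lambda_i * aex_i * (1-X_i)/(1+X_i)`: for a cation, positive Q
#' enriches the inner surface and depletes the outer one, and the two
#' correction factors are reciprocal, so tin*tex = lambda^2 * ain * aex
#' independently of Q.
#'
#' @param ain,aex Per-ion internal-average / external-bath concentrations,
#'   mol/m^3.
#' @param geom Geometry.
#' @param tab Ion table.
#' @param k Constants.
#' @param Q Net internal charge, C/m^2; by default recomputed from `ain`.
#' @param clip If `TRUE`, soft-clamp each `X_i` to +/-(1 - 1e-6) instead of
#'   erroring (used inside the integrator where trial steps may overshoot);
#'   the clamped result carries attribute `overload = TRUE`.
#' @return List of class `"surface_densities"` with named per-ion vectors
#'   `tin`, `tex` (mol/m^2), the correction vector `X` and scalar `Q`.
#' @export
surface_densities <- function(ain, aex, geom, tab, k = phys_constants(),
                              Q = NULL, clip = FALSE) {
  ain <- align_ions(ain, tab)
  aex <- align_ions(aex, tab)
  if (any(ain < 0) || any(aex < 0)) stop("negative concentration")
  if (is.null(Q)) Q <- net_charge(ain, geom, tab, k)
  chi <- chi_coefficient(geom, k)
  X <- chi * (Q / k$F) * tab$lambda * tab$z
  overload <- any(abs(X) >= 1)
  if (overload) {
    if (!clip)
      stop("double-layer overload: |X| >= 1 for ion(s) ",
           paste(tab$name[abs(X) >= 1], collapse = ", "),
           " (net charge too large for the linearized double layer)")
    X <- pmin(pmax(X, -(1 - 1e-6)), 1 - 1e-6)
  }
  tin <- tab$lambda * ain * (1 + X) / (1 - X)
  tex <- tab$lambda * aex * (1 - X) / (1 + X)
  out <- list(tin = stats::setNames(tin, tab$name),
              tex = stats::setNames(tex, tab$name),
              X = stats::setNames(X, tab$name), Q = Q)
  attr(out, "overload") <- overload
  class(out) <- "surface_densities"
  out
}

#' Membrane potential from surface densities
#'
#' Each charged species present on both sides contributes
#' `V_i = (R T)/(F z_i) * log(tin_i / tex_i)`; the scalar membrane potential
#' is their mean weighted by `min(ain_i, aex_i)`. Ions absent from either
#' side are excluded rather than producing infinities. Vm is zero when
#' tin = tex elementwise, and antisymmetric under swapping tin and tex.
#'
#' @param sd Surface densities from [surface_densities()].
#' @param ain,aex Bulk concentrations used for the weights, mol/m^3.
#' @param tab Ion table.
#' @param k Constants.
#' @param components If `TRUE`, also return the per-ion values and weights.
#' @return Vm in volts (scalar), or a list if `components = TRUE`.
#' @export
membrane_potential <- function(sd, ain, aex, tab, k = phys_constants(),
                               components = FALSE) {
  ain <- align_ions(ain, tab)
  aex <- align_ions(aex, tab)
  inc <- ain > 0 & aex > 0 & tab$z != 0
  if (!any(inc)) stop("no ion present on both sides: Vm undefined")
  tin <- align_ions(sd$tin, tab)
  tex <- align_ions(sd$tex, tab)
  if (any(tin[inc] <= 0) || any(tex[inc] <= 0))
    stop("zero surface density for an included ion: Vm undefined")
  Vi <- (k$R * k$T) / (k$F * tab$z[inc]) * log(tin[inc] / tex[inc])
  w <- pmin(ain[inc], aex[inc])
  Vm <- sum(w * Vi) / sum(w)
  if (!components) return(Vm)
  list(Vm = Vm,
       Vi = stats::setNames(Vi, tab$name[inc]),
       weights = stats::setNames(w, tab$name[inc]))
}

#' Rate of change of internal average concentrations
#'
#' d(ain_i)/dt = 3 u_i / r for transmembrane influx u (mol/(m^2 s)); implies
#' d(qc_i)/dt = u_i and dQ/dt = F * sum z_i u_i.
#'
#' @param u Per-ion transmembrane influx, mol/(m^2 s).
#' @param geom Geometry.
#' @return Per-ion d(ain)/dt, mol/(m^3 s).
#' @export
concentration_derivative <- function(u, geom) {
  3 * u / geom$r
}

#' Radial Boltzmann-profile oracle for the double layer
#'
#' Test-support routine: solves the zero-flux steady state
#' `d log(c_i)/dx = E(x) F z_i / (R T)` on fine grids spanning one maximal
#' ion diameter on each side of the membrane. The field is the spherical
#' Gauss integral of the bulk charge profile (net charge Q spread uniformly
#' over the interior, the diffuse layer held stable at its bulk averages,
#' membrane permittivity convention, so E(r) = Q/eps_m) — mirroring the
#' model's premise that only the adsorbed net charge generates the
#' near-membrane field. Each ion's profile is normalized to its bulk average
#' at the far edge of its own window, and the windowed integrals
#' `(1/r^2) int c x^2 dx` are the oracle surface densities against which the
#' closed-form approximation of [surface_densities()] is validated.
#'
#' @param ain,aex Bulk internal / external concentrations, mol/m^3.
#' @param Q Net internal charge, C/m^2.
#' @param geom Geometry.
#' @param tab Ion table.
#' @param k Constants.
#' @param n_grid Grid points per side (default 800).
#' @return List with `inside` and `outside` profile data frames (column `x`
#'   plus one column per ion), and named vectors `tin`, `tex` (mol/m^2).
#' @export
double_layer_oracle <- function(ain, aex, Q, geom, tab,
                                k = phys_constants(), n_grid = 800) {
  ain <- align_ions(ain, tab)
  aex <- align_ions(aex, tab)
  r <- geom$r
  L <- max(tab$lambda)
  kT <- k$R * k$T

  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  cum_trapz <- function(x, y) c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))

  solve_side <- function(inside) {
    if (inside) {
      x <- seq(r - L, r, length.out = n_grid)
      bulk <- ain
      edge_x <- r - tab$lambda         # normalization point per ion
      # Gauss integral up to the window start: the prescribed net charge Q,
      # spread uniformly over the interior below the surface layer
      I0 <- (Q / k$F) * (r - L)^3 / r
    } else {
      x <- seq(r, r + L, length.out = n_grid)
      bulk <- aex
      edge_x <- r + tab$lambda
      I0 <- NA  # filled below: total interior charge
    }
    # Gauss field of the bulk charge profile: the window contributes its
    # (electroneutral-or-not) bulk charge at the stable bulk averages
    rho_bulk <- sum(tab$z * bulk)
    if (inside) {
      I <- I0 + cum_trapz(x, rho_bulk * x^2)
    } else {
      I <- (r^2 * Q / k$F) + cum_trapz(x, rho_bulk * x^2)
    }
    E <- k$F * I / (x^2 * geom$eps_m)
    Phi <- cum_trapz(x, E)                         # int E dx from grid start
    cmat <- matrix(0, n_grid, nrow(tab), dimnames = list(NULL, tab$name))
    for (j in seq_len(nrow(tab))) {
      if (bulk[j] == 0) next
      Phi_edge <- stats::approx(x, Phi, xout = edge_x[j], rule = 2)$y
      cmat[, j] <- bulk[j] * exp(tab$z[j] * k$F / kT * (Phi - Phi_edge))
    }
    list(x = x, cmat = cmat)
  }

  ins <- solve_side(TRUE)
  out <- solve_side(FALSE)

  window_integral <- function(x, cvec, lo, hi, r) {
    grid <- seq(lo, hi, length.out = 400)
    cv <- stats::approx(x, cvec, xout = grid, rule = 2)$y
    trapz(grid, cv * grid^2) / r^2
  }
  tin <- vapply(seq_len(nrow(tab)), function(j)
    window_integral(ins$x, ins$cmat[, j], r - tab$lambda[j], r, r), 0)
  tex <- vapply(seq_len(nrow(tab)), function(j)
    window_integral(out$x, out$cmat[, j], r, r + tab$lambda[j], r), 0)

  list(inside = data.frame(x = ins$x, ins$cmat, check.names = FALSE),
       outside = data.frame(x = out$x, out$cmat, check.names = FALSE),
       tin = stats::setNames(tin, tab$name),
       tex = stats::setNames(tex, tab$name))
}
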