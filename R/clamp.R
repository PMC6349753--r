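#' Voltage-clamp protocol
#'
#' @param segments Data frame with columns `t0`, `t1` (s) and `Vs` (V);
#'   segments must be contiguous and non-overlapping.
#' @param Rs Pipette resistance, Ohm (> 0).
#' @return Protocol object (class `"mf_protocol"`, mode `"voltage"`).
#' @export
#' @examples
#' p <- voltage_clamp(data.frame(t0 = c(-0.01, 0), t1 = c(0, 0.05),
#'                               Vs = c(-0.07, 0.03)), Rs = 2.4e6)
voltage_clamp <- function(segments, Rs) {
  stopifnot(Rs > 0, all(c("t0", "t1", "Vs") %in% names(segments)))
  check_segments(segments)
  structure(list(mode = "voltage", segments = segments, Rs = Rs),
            class = "mf_protocol")
}

#' Current-clamp protocol
#'
#' Segments are either constant current (`kind = "const"`, column `value` in
#' A/m^2) or sinusoidal (`kind = "sin"`, columns `amp` in A/m^2 and `omega`
#' in rad/s, evaluated as `amp * sin(omega * t)` in absolute time).
#'
#' @param segments Data frame with columns `t0`, `t1`, `kind`, and `value`
#'   and/or `amp`, `omega`.
#' @return Protocol object (mode `"current"`).
#' @export
current_clamp <- function(segments) {
  stopifnot(all(c("t0", "t1", "kind") %in% names(segments)))
  if (!all(segments$kind %in% c("const", "sin")))
    stop("current-clamp segment kind must be 'const' or 'sin'")
  check_segments(segments)
  structure(list(mode = "current", segments = segments, Rs = NA_real_),
            class = "mf_protocol")
}

check_segments <- function(seg) {
  stopifnot(nrow(seg) >= 1, all(seg$t1 > seg$t0))
  if (nrow(seg) > 1 && any(abs(seg$t0[-1] - seg$t1[-nrow(seg)]) > 1e-12))
    stop("protocol segments must be contiguous and non-overlapping")
  invisible(seg)
}

#' Evaluate a protocol at a time point
#'
#' Piecewise evaluation, left-continuous at segment boundaries: the value at
#' a boundary belongs to the earlier segment.
#'
#' @param p Protocol.
#' @param t Time, s (scalar or vector); must lie within the protocol span.
#' @return Vs (V) for voltage clamp or Is (A/m^2) for current clamp.
#' @export
protocol_value <- function(p, t) {
  seg <- p$segments
  vapply(t, function(ti) {
    if (ti < seg$t0[1] - 1e-12 || ti > seg$t1[nrow(seg)] + 1e-12)
      stop("time ", ti, " outside protocol span")
    i <- if (ti <= seg$t1[1]) 1L
         else which(ti > seg$t0 + 1e-15 & ti <= seg$t1 + 1e-15)[1]
    if (is.na(i)) i <- nrow(seg)
    if (p$mode == "voltage") return(seg$Vs[i])
    if (seg$kind[i] == "const") seg$value[i]
    else seg$amp[i] * sin(seg$omega[i] * ti)
  }, 0)
}

#' Protocol time span
#' @param p Protocol.
#' @return c(start, end) in seconds.
#' @export
protocol_span <- function(p) {
  c(p$segments$t0[1], p$segments$t1[nrow(p$segments)])
}

#' Electrode (stimulation) current in voltage clamp
#'
#' i_s = (Vs - Vm) / (Rs * S): the voltage error across the pipette
#' resistance, expressed per membrane area. Zero when the membrane sits at
#' the command potential; odd in (Vs - Vm).
#'
#' @param Vs Command potential, V.
#' @param Vm Membrane potential, V.
#' @param Rs Pipette resistance, Ohm.
#' @param geom Geometry (supplies the surface area S).
#' @return i_s, A/m^2.
#' @export
electrode_current <- function(Vs, Vm, Rs, geom) {
  stopifnot(Rs > 0)
  (Vs - Vm) / (Rs * geom$S)
}

#' Stimulation ionic flux of an Ag/AgCl electrode
#'
#' The electrode's redox reaction converts electronic current into chloride
#' flux at the solution interface: js_Cl = -i_s / F, all other ions zero.
#' The flux carries the full stimulation current into the cell:
#' `current_from_flux(js) = +i_s` exactly (chloride leaving is a positive
#' inward current), so `dQ/dt` gains `+i_s` from the electrode term.
#'
#' @param i_s Stimulation current density, A/m^2.
#' @param tab Ion table (must contain `Cl`).
#' @param k Constants.
#' @return Named per-ion influx, mol/(m^2 s).
#' @export
stimulation_flux <- function(i_s, tab, k = phys_constants()) {
  if (!"Cl" %in% tab$name)
    stop("stimulation_flux: ion table has no Cl species for the Ag/AgCl electrode")
  js <- stats::setNames(numeric(nrow(tab)), tab$name)
  js["Cl"] <- -i_s / k$F
  js
}

#' Recorded membrane current
#'
#' I = -F * sum_i z_i * u_i over the summed channel influx: outward cation
#' movement is positive (physiological convention), so a cation influx
#' registers as a negative (inward) current.
#'
#' @param u Per-ion summed channel influx, mol/(m^2 s).
#' @param tab Ion table.
#' @param k Constants.
#' @return I, A/m^2.
#' @export
recorded_current <- function(u, tab, k = phys_constants()) {
  u <- align_ions(u, tab)
  -k$F * sum(tab$z * u)
}
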