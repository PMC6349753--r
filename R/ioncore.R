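#' Physical constants
#'
#' CODATA values for the molar gas constant, the Faraday constant and the
#' vacuum permittivity, bundled with the working temperature. All quantities
#' in the package are strict SI (mol/m^3, mol/m^2, V, A/m^2, s, m); note
#' 1 mol/m^3 = 1 mmol/L.
#'
#' @param temperature Temperature in K (default 290).
#' @return A list with elements `R` (J/(mol K)), `F` (C/mol), `eps0` (F/m)
#'   and `T` (K).
#' @export
#' @examples
#' k <- phys_constants()
#' k$R * k$T / k$F   # thermal voltage, ~25 mV
phys_constants <- function(temperature = 290) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  list(R = 8.314462618, F = 96485.33212, eps0 = 8.8541878128e-12,
       T = temperature)
}

#' Define one ion species
#'
#' @param name Short label, e.g. `"K"`.
#' @param z Signed integer valence (nonzero).
#' @param D Diffusion coefficient, m^2/s (> 0).
#' @param lambda Effective (hydrated) ion diameter, m (> 0). The diameters
#'   shipped with [default_ions()] are calibration constants: they set the
#'   thickness of the surface layer the double-layer approximation integrates
#'   over, and hence the capacitance scale of the membrane.
#' @return A one-row data frame usable with [ion_table()].
#' @export
ion_species <- function(name, z, D, lambda) {
  stopifnot(is.character(name), nchar(name) > 0,
            z == round(z), z != 0,
            is.numeric(D), D > 0,
            is.numeric(lambda), lambda > 0)
  data.frame(name = name, z = as.integer(z), D = D, lambda = lambda,
             stringsAsFactors = FALSE)
}

#' Assemble an ion table
#'
#' The ion table fixes the ordered species index shared by every per-ion
#' vector in the package; elementwise products between per-ion quantities are
#' only meaningful over the same table.
#'
#' @param ... One-row data frames from [ion_species()].
#' @return A data frame with columns `name`, `z`, `D`, `lambda`, one row per
#'   species, row names set to the species names.
#' @export
ion_table <- function(...) {
  tab <- do.call(rbind, list(...))
  if (anyDuplicated(tab$name)) stop("duplicate ion names in table")
  rownames(tab) <- tab$name
  class(tab) <- c("ion_table", "data.frame")
  tab
}

#' Default ion registry
#'
#' K+, Na+, Cl-, Ca2+, Cs+ and an impermeant intracellular anion `A` used to
#' write electroneutral resting compositions. Diffusion coefficients are
#' standard infinite-dilution values. Effective diameters `lambda` are
#' calibration constants chosen once so that the committed standard solutions
#' give a membrane capacitance of about 1 uF/cm^2 at eps_r = 4 (see the
#' methods vignette); for the divalent Ca2+, `lambda` is kept small enough
#' that `|X| < 1` holds over the full clamp range used by the experiment
#' registry (the double-layer factor scales with `lambda * z`).
#'
#' @return An [ion_table()] with six species.
#' @export
default_ions <- function() {
  ion_table(
    ion_species("K",  +1, 1.957e-9, 1.40e-9),
    ion_species("Na", +1, 1.334e-9, 1.00e-9),
    ion_species("Cl", -1, 2.032e-9, 1.40e-9),
    ion_species("Ca", +2, 0.792e-9, 0.30e-9),
    ion_species("Cs", +1, 2.056e-9, 1.39e-9),
    ion_species("A",  -1, 1.000e-9, 1.40e-9)
  )
}

#' Define a solution
#'
#' A solution maps species to bulk concentrations. Internal solutions hold the
#' average internal concentrations; bath solutions are treated as
#' time-constant (the external space is assumed large).
#'
#' @param conc Named numeric vector of concentrations, mol/m^3 (>= 0). Names
#'   must be species in `tab`; species not named get 0.
#' @param tab Ion table ([ion_table()]).
#' @param role `"internal"` or `"bath"`.
#' @return Named numeric vector over all species of `tab`, with attributes
#'   `role` and class `"mf_solution"`.
#' @export
solution <- function(conc, tab = default_ions(), role = c("internal", "bath")) {
  role <- match.arg(role)
  stopifnot(is.numeric(conc), !is.null(names(conc)))
  unknown <- setdiff(names(conc), tab$name)
  if (length(unknown))
    stop("solution names ions absent from the ion table: ",
         paste(unknown, collapse = ", "))
  if (any(conc < 0)) stop("negative concentration in solution")
  out <- stats::setNames(numeric(nrow(tab)), tab$name)
  out[names(conc)] <- conc
  attr(out, "role") <- role
  class(out) <- "mf_solution"
  out
}

# strip class/attrs -> plain named vector aligned to tab
as_conc <- function(x, tab) {
  v <- stats::setNames(numeric(nrow(tab)), tab$name)
  v[names(unclass(x))[names(unclass(x)) %in% tab$name]] <-
    unclass(x)[names(unclass(x)) %in% tab$name]
  if (is.null(names(unclass(x)))) stop("concentration vector must be named")
  v
}

#' Electromigration mobility
#'
#' mu = D * F / (R * T), the Einstein relation between the diffusion
#' coefficient and the drift mobility in an electric field.
#'
#' @param tab Ion table (or a single-row species).
#' @param k Constants from [phys_constants()].
#' @return Named vector of mobilities, m^2/(V s).
#' @export
#' @examples
#' mobility(default_ions())
mobility <- function(tab, k = phys_constants()) {
  stats::setNames(tab$D * k$F / (k$R * k$T), tab$name)
}

#' Bulk ionic flux from diffusion and electromigration
#'
#' j = -D * dc/dx + E * c * z * mu, elementwise over the species index. Used
#' by the double-layer oracle; the whole-cell time stepper works with the
#' closed-form surface densities instead.
#'
#' @param conc Per-ion concentrations, mol/m^3 (named, over `tab`).
#' @param grad_conc Per-ion spatial gradients, mol/m^4.
#' @param E Electric field, V/m (scalar).
#' @param tab Ion table.
#' @param k Constants.
#' @return Named per-ion flux density, mol/(m^2 s).
#' @export
bulk_flux <- function(conc, grad_conc, E, tab, k = phys_constants()) {
  conc <- align_ions(conc, tab)
  grad_conc <- align_ions(grad_conc, tab)
  mu <- mobility(tab, k)
  -tab$D * grad_conc + E * conc * tab$z * mu
}

#' Current density carried by an ionic flux
#'
#' i = F * sum_i z_i * j_i. Linear in the flux vector.
#'
#' @param flux Per-ion flux density, mol/(m^2 s), named over `tab`.
#' @param tab Ion table.
#' @param k Constants.
#' @return Current density, A/m^2 (scalar).
#' @export
current_from_flux <- function(flux, tab, k = phys_constants()) {
  flux <- align_ions(flux, tab)
  k$F * sum(tab$z * flux)
}

# check a named per-ion vector against the table's index set
align_ions <- function(x, tab) {
  if (is.null(names(x))) {
    if (length(x) != nrow(tab))
      stop("unnamed per-ion vector of wrong length (expected ",
           nrow(tab), ")")
    return(stats::setNames(as.numeric(x), tab$name))
  }
  if (!setequal(names(x), tab$name))
    stop("per-ion vector index does not match the ion table")
  as.numeric(x[tab$name])
}

# expand a partial named vector over the table, filling `fill`
expand_ions <- function(x, tab, fill = 0) {
  v <- stats::setNames(rep(fill, nrow(tab)), tab$name)
  if (length(x)) {
    if (is.null(names(x))) stop("partial per-ion vector must be named")
    unknown <- setdiff(names(x), tab$name)
    if (length(unknown))
      stop("unknown ion(s): ", paste(unknown, collapse = ", "))
    v[names(x)] <- x
  }
  v
}
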