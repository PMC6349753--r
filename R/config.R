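#' Load and validate a model configuration
#'
#' Reads a YAML (or JSON) configuration describing ions, solutions, cell
#' geometry, channels, stimulation protocol and solver settings, validates
#' it (unknown keys and dangling ion references are errors), and converts
#' boundary units (mM, mV, ms, MOhm, nm) to the package's strict SI.
#'
#' Top-level keys: `schema_version`, optional `ions`
#' (`[{name, z, D, lambda_nm}]`), `cell`
#' (`{radius_um, eps_r, temperature_K}`), `solutions`
#' (`{internal: {ion: mM}, bath: {ion: mM}}`), optional `buffered` (ion
#' names), optional `channels`
#' (`[{name, s: {ion: value}, rho0: {ion: per_s}, sigma_bar, tau_ms, alpha,
#' beta, gamma, delta, eta, kappa: {ion: value}, m: {ion: int},
#' n: {ion: int}}]`), optional `rest_Vm_mV`, optional `protocol`
#' (`{mode: voltage|current, Rs_MOhm, segments: [...]}` with per-segment
#' `t0_ms`, `t1_ms` and `Vs_mV`, `Is_Am2` or
#' `sin: {amp_Am2, freq_Hz}`), optional `sim`
#' (`{rtol, atol, sample_dt_ms}`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List of class `"mf_config"` with elements `model`
#'   ([cell_model()]), `protocol` (or `NULL`), `cfg` ([sim_config()]),
#'   `rest_Vm` (V or `NA`) and `canonical` (the canonical parsed form used
#'   for hashing).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  known <- c("schema_version", "ions", "cell", "solutions", "buffered",
             "channels", "rest_Vm_mV", "protocol", "sim")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "))
  for (key in c("schema_version", "solutions"))
    if (is.null(raw[[key]])) stop("config missing required key '", key, "'")

  tab <- if (is.null(raw$ions)) default_ions() else {
    rows <- lapply(raw$ions, function(io) {
      need <- c("name", "z", "D", "lambda_nm")
      miss <- setdiff(need, names(io))
      if (length(miss)) stop("ion entry missing field(s): ",
                             paste(miss, collapse = ", "))
      ion_species(io$name, io$z, io$D, io$lambda_nm * 1e-9)
    })
    do.call(ion_table, rows)
  }

  cellb <- raw$cell
  k <- phys_constants(if (is.null(cellb$temperature_K)) 290
                      else cellb$temperature_K)
  geom <- cell_geometry(
    radius = if (is.null(cellb$radius_um)) 1e-5 else cellb$radius_um * 1e-6,
    eps_r = if (is.null(cellb$eps_r)) 4 else cellb$eps_r, k = k)

  conc_vec <- function(block, what) {
    v <- unlist(block)
    bad <- setdiff(names(v), tab$name)
    if (length(bad))
      stop(what, " references undefined ion(s): ", paste(bad, collapse = ", "))
    v   # mM == mol/m^3, no numeric conversion needed
  }
  if (is.null(raw$solutions$internal) || is.null(raw$solutions$bath))
    stop("solutions must define both 'internal' and 'bath'")
  internal <- conc_vec(raw$solutions$internal, "internal solution")
  bath <- conc_vec(raw$solutions$bath, "bath solution")

  channels <- lapply(raw$channels, function(cb) {
    if (is.null(cb$name)) stop("channel entry missing 'name'")
    for (fld in c("s", "rho0"))
      if (!is.null(cb[[fld]])) {
        bad <- setdiff(names(cb[[fld]]), tab$name)
        if (length(bad))
          stop("channel '", cb$name, "' references undefined ion(s): ",
               paste(bad, collapse = ", "))
      }
    channel_spec(cb$name,
                 s = unlist(cb[["s"]]), rho0 = unlist(cb[["rho0"]]),
                 sigma_bar = if (is.null(cb[["sigma_bar"]])) NA_real_
                             else cb[["sigma_bar"]],
                 tau = cb[["tau_ms"]] * 1e-3, alpha = cb[["alpha"]],
                 beta = cb[["beta"]],
                 gamma = if (is.null(cb[["gamma"]])) 1 else cb[["gamma"]],
                 delta = cb[["delta"]],
                 eta = if (is.null(cb[["eta"]])) 1 else cb[["eta"]],
                 kappa = unlist(cb[["kappa"]]), m = unlist(cb[["m"]]),
                 n = unlist(cb[["n"]]), tab = tab)
  })
  names(channels) <- vapply(channels, `[[`, "", "name")

  buffered <- unlist(raw$buffered)
  if (length(buffered) && length(setdiff(buffered, tab$name)))
    stop("buffered references undefined ion(s): ",
         paste(setdiff(buffered, tab$name), collapse = ", "))

  model <- cell_model(internal = internal, bath = bath, channels = channels,
                      geom = geom, tab = tab, k = k,
                      buffered = if (is.null(buffered)) character()
                                 else buffered)

  protocol <- if (!is.null(raw$protocol)) parse_protocol(raw$protocol)
  simb <- raw$sim
  cfg <- sim_config(
    rtol = if (is.null(simb$rtol)) 1e-6 else simb$rtol,
    atol = if (is.null(simb$atol)) 1e-9 else simb$atol,
    sample_dt = if (is.null(simb$sample_dt_ms)) 1e-4
                else simb$sample_dt_ms * 1e-3)

  structure(list(model = model, protocol = protocol, cfg = cfg,
                 rest_Vm = if (is.null(raw$rest_Vm_mV)) NA_real_
                           else raw$rest_Vm_mV * 1e-3,
                 canonical = canonical_config(raw)),
            class = "mf_config")
}

parse_protocol <- function(pb) {
  if (is.null(pb$mode) || !pb$mode %in% c("voltage", "current"))
    stop("protocol mode must be 'voltage' or 'current'")
  segs <- pb$segments
  if (is.null(segs) || !length(segs)) stop("protocol has no segments")
  t0 <- vapply(segs, function(s) s$t0_ms * 1e-3, 0)
  t1 <- vapply(segs, function(s) s$t1_ms * 1e-3, 0)
  if (pb$mode == "voltage") {
    if (is.null(pb$Rs_MOhm)) stop("voltage-clamp protocol requires Rs_MOhm")
    Vs <- vapply(segs, function(s) {
      if (is.null(s$Vs_mV)) stop("voltage segment missing Vs_mV")
      s$Vs_mV * 1e-3
    }, 0)
    voltage_clamp(data.frame(t0 = t0, t1 = t1, Vs = Vs),
                  Rs = pb$Rs_MOhm * 1e6)
  } else {
    kind <- vapply(segs, function(s)
      if (!is.null(s$sin)) "sin" else "const", "")
    value <- vapply(segs, function(s)
      if (is.null(s$Is_Am2)) NA_real_ else s$Is_Am2, 0)
    if (any(kind == "const" & is.na(value)))
      stop("current segment missing Is_Am2")
    amp <- vapply(segs, function(s)
      if (is.null(s$sin)) NA_real_ else s$sin$amp_Am2, 0)
    omega <- vapply(segs, function(s)
      if (is.null(s$sin)) NA_real_ else 2 * pi * s$sin$freq_Hz, 0)
    current_clamp(data.frame(t0 = t0, t1 = t1, kind = kind, value = value,
                             amp = amp, omega = omega))
  }
}

# order-normalized form used for hashing: lists sorted by key recursively
canonical_config <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x))) x <- x[order(names(x))]
    lapply(x, canonical_config)
  } else x
}

#' Hash of a loaded configuration's canonical form
#' @param conf Object from [load_config()].
#' @return Character MD5 hash; identical for configs that load to the same
#'   canonical form.
#' @export
config_hash <- function(conf) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(conf$canonical, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
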