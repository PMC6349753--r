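#' Write a simulation trace
#'
#' CSV: one row per sample, one column per recorded quantity, header naming
#' the quantity and its SI unit (`name|unit`); values at full double
#' precision so a written-then-reread trace equals the original. A JSON
#' sidecar (`<path>.meta.json`) records the solver settings, package
#' version and, when available, the configuration hash.
#'
#' @param trace `membrane_trace` from [simulate_protocol()].
#' @param path Output CSV path.
#' @param format `"csv"` or `"json"` (JSON holds columns as arrays).
#' @param config_hash Optional hash string from [config_hash()].
#' @return Invisibly, the written path.
#' @export
write_trace <- function(trace, path, format = c("csv", "json"),
                        config_hash = NULL) {
  format <- match.arg(format)
  units <- vapply(names(trace), trace_unit, "")
  header <- paste0(names(trace), "|", units)
  if (format == "csv") {
    con <- file(path, "w")
    writeLines(paste(header, collapse = ","), con)
    if (nrow(trace))
      utils::write.table(
        format(as.data.frame(trace), digits = 17, scientific = TRUE,
               trim = TRUE),
        con, sep = ",", row.names = FALSE, col.names = FALSE,
        quote = FALSE)
    close(con)
  } else {
    jsonlite::write_json(stats::setNames(as.list(as.data.frame(trace)),
                                         header),
                         path, digits = NA)
  }
  cfg <- attr(trace, "cfg")
  meta <- list(package = "membraneflux",
               version = as.character(utils::packageVersion("membraneflux")),
               n_samples = nrow(trace),
               rtol = cfg$rtol, atol = cfg$atol, sample_dt = cfg$sample_dt,
               config_hash = config_hash)
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

trace_unit <- function(name) {
  if (name == "t") return("s")
  if (name == "Vm") return("V")
  if (name == "Q") return("C/m2")
  if (name %in% c("i_s", "I")) return("A/m2")
  if (grepl("^ain\\.", name)) return("mol/m3")
  if (grepl("^(u|zeta)\\.", name)) return("mol/m2/s")
  if (grepl("^sigma\\.", name)) return("mol/m2")
  if (grepl("^(v|w|f|theta|phi)\\.", name)) return("1")
  "1"
}

#' Read a trace written by [write_trace()]
#'
#' @param path CSV path.
#' @return Data frame with the original column names; units are kept in
#'   attribute `"units"`.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  parts <- strsplit(names(df), "|", fixed = TRUE)
  names(df) <- vapply(parts, `[`, "", 1)
  attr(df, "units") <- vapply(parts, function(p) p[length(p)], "")
  df
}
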