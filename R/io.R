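#' Write motility events and metrics to CSV
#'
#' @param metrics data.frame from [analyze_tirf_movie()]'s `metrics`.
#' @param file Output CSV path.
#' @export
write_events_csv <- function(metrics, file) {
  utils::write.csv(metrics, file, row.names = FALSE)
  invisible(file)
}

#' Write / read an ITC experiment as CSV plus a protocol JSON
#'
#' The CSV has unit-annotated columns `injection_index`, `volume_ul`,
#' `heat_ucal`; the protocol is echoed to `<file>.protocol.json`.
#'
#' @param experiment An `itc_experiment`.
#' @param file Output CSV path.
#' @export
write_itc_csv <- function(experiment, file) {
  df <- data.frame(injection_index = seq_along(experiment$heats),
                   volume_ul = experiment$protocol$injection_volumes_ul,
                   heat_ucal = experiment$heats)
  utils::write.csv(df, file, row.names = FALSE)
  jsonlite::write_json(unclass(experiment$protocol),
                       paste0(file, ".protocol.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_itc_csv
#' @export
read_itc_csv <- function(file) {
  df <- utils::read.csv(file)
  pj <- jsonlite::fromJSON(paste0(file, ".protocol.json"))
  proto <- itc_protocol(pj$cell_concentration, pj$syringe_concentration,
                        pj$cell_volume_ul, pj$injection_volumes_ul,
                        pj$temperature_C)
  out <- list(protocol = proto, heats = df$heat_ucal)
  class(out) <- "itc_experiment"
  out
}

#' Write / read a SEC-MALS trace as CSV
#'
#' Columns: `volume_ml`, `concentration_mg_ml`, `scattering`; dn/dc and the
#' true mass (if known) are carried in a header comment line.
#'
#' @param trace A `mals_trace`.
#' @param file Output CSV path.
#' @export
write_mals_csv <- function(trace, file) {
  con <- file(file, "w")
  writeLines(sprintf("# dn_dc_ml_g=%g true_mass_kda=%g", trace$dn_dc,
                     trace$true_mass_kda), con)
  utils::write.csv(trace$trace, con, row.names = FALSE)
  close(con)
  invisible(file)
}

#' @rdname write_mals_csv
#' @export
read_mals_csv <- function(file) {
  header <- readLines(file, n = 1)
  dn_dc <- as.numeric(sub(".*dn_dc_ml_g=([0-9.eE+-]+).*", "\\1", header))
  true_mass <- as.numeric(sub(".*true_mass_kda=([0-9.eE+-]+).*", "\\1", header))
  df <- utils::read.csv(file, comment.char = "#")
  out <- list(trace = df, dn_dc = dn_dc, true_mass_kda = true_mass)
  class(out) <- "mals_trace"
  out
}

#' Sequence-derived monomer masses shipped with the package
#'
#' Reads `inst/extdata/monomer_masses.csv`: construct name, monomer mass in
#' kDa derived from the construct sequence.
#'
#' @return Named numeric vector of masses (kDa).
#' @export
monomer_masses <- function() {
  f <- system.file("extdata", "monomer_masses.csv", package = "adaptorquant")
  df <- utils::read.csv(f, comment.char = "#")
  stats::setNames(df$mass_kda, df$construct)
}
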