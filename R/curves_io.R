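#' Read and write magnetization curves as delimited tables
#'
#' Curves are exchanged as two-column delimited text tables (comma or tab,
#' auto-detected on read) with a header row carrying unit annotations:
#' `field_T` or `field_Am` for the field column (tesla, or A/m converted via
#' B = mu0 H) and `magnetization_Am2_per_molFe` for the magnetization.
#'
#' @param path File path.
#' @param temperature Temperature (K) to attach to the curve on read.
#' @return `read_mh_table`: a [magnetization_curve()].
#' @export
read_mh_table <- function(path, temperature = 295) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  fcol <- grep("^field", names(df), value = TRUE)
  mcol <- grep("^magnetization", names(df), value = TRUE)
  if (length(fcol) != 1 || length(mcol) != 1)
    stop("expected one 'field_*' and one 'magnetization_*' column, got: ",
         paste(names(df), collapse = ", "))
  b <- df[[fcol]]
  if (grepl("_Am$", fcol)) b <- b * 4e-7 * pi  # H in A/m -> B in T
  else if (!grepl("_T$", fcol)) stop("field column must be field_T or field_Am")
  magnetization_curve(b, df[[mcol]], temperature)
}

#' @rdname read_mh_table
#' @param curve A [magnetization_curve()].
#' @param sep Field separator, `","` or `"\t"`.
#' @export
write_mh_table <- function(curve, path, sep = ",") {
  stopifnot(inherits(curve, "magnetization_curve"))
  df <- data.frame(field_T = curve$field_t,
                   magnetization_Am2_per_molFe = curve$magnetization)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write harmonic spectra as delimited tables
#'
#' Spectra are exchanged as delimited tables with columns `harmonic`
#' (odd index k), `frequency_Hz`, and `amplitude_Am2_per_molFe`.
#'
#' @param path File path.
#' @return `read_spectrum_table`: a `harmonic_spectrum`.
#' @export
read_spectrum_table <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  stopifnot(all(c("harmonic", "frequency_Hz", "amplitude_Am2_per_molFe") %in%
                  names(df)))
  f0 <- df$frequency_Hz[1] / df$harmonic[1]
  harmonic_spectrum(df$harmonic, df$amplitude_Am2_per_molFe,
                    drive_amplitude = NA_real_, drive_frequency = f0,
                    temperature = NA_real_)
}

#' @rdname read_spectrum_table
#' @param spectrum A `harmonic_spectrum` (see [simulate_mps()]).
#' @param sep Field separator.
#' @export
write_spectrum_table <- function(spectrum, path, sep = ",") {
  stopifnot(inherits(spectrum, "harmonic_spectrum"))
  df <- data.frame(harmonic = spectrum$harmonic,
                   frequency_Hz = spectrum$harmonic * spectrum$drive_frequency,
                   amplitude_Am2_per_molFe = spectrum$amplitude)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
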