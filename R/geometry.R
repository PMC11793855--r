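#' Packaged molar extinction coefficient table
#'
#' Loads the extinction-coefficient table shipped with the package: molar
#' extinction coefficients of oxy- and deoxy-hemoglobin (1/(mM*cm)) at the
#' two probe wavelengths (700 and 910 nm), drawn from standard literature
#' compilations, plus the dimensionless pathlength correction factor B for
#' each wavelength (default 1.0). Users with their own calibration can point
#' `path` at a CSV with columns `wavelength_nm, eps_hbo2, eps_hb, b_factor`.
#'
#' @param path Optional path to a user-supplied extinction table CSV.
#' @return A tibble with columns `wavelength_nm`, `eps_hbo2`, `eps_hb`,
#'   `b_factor`.
#' @export
#' @examples
#' extinction_table()
extinction_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "extinction_coefficients.csv",
                                package = "neoperf", mustWork = TRUE)
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("wavelength_nm", "eps_hbo2", "eps_hb", "b_factor")
  if (!all(need %in% names(tbl))) {
    abort(paste0("extinction table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  if (any(tbl$eps_hbo2 <= 0) || any(tbl$eps_hb <= 0) || any(tbl$b_factor <= 0)) {
    abort("extinction coefficients and b_factor must be positive")
  }
  as_tibble(tbl)
}

#' Probe geometry for the dual-wavelength optical sensor
#'
#' Describes the reflective probe: LED-photodiode separation `L` (cm) and the
#' two wavelength channels with their extinction coefficients and pathlength
#' factors. The default 1.0 cm separation matches a 10 mm LED-PD spacing.
#'
#' @param wavelengths The two channel wavelengths in nm; must be present in
#'   the extinction table.
#' @param source_detector_cm LED-photodiode distance in cm (positive).
#' @param extinction Extinction table, as from [extinction_table()].
#' @return An object of class `probe_geometry`: a list with
#'   `source_detector_cm` and a two-row `channels` tibble.
#' @export
#' @examples
#' probe_geometry()
probe_geometry <- function(wavelengths = c(700, 910),
                           source_detector_cm = 1.0,
                           extinction = extinction_table()) {
  if (length(wavelengths) != 2L || wavelengths[1] == wavelengths[2]) {
    abort("exactly two distinct wavelengths are required")
  }
  if (!is.numeric(source_detector_cm) || source_detector_cm <= 0) {
    abort("source_detector_cm must be a positive number")
  }
  idx <- match(wavelengths, extinction$wavelength_nm)
  if (anyNA(idx)) {
    abort(paste0("wavelength(s) ",
                 paste(wavelengths[is.na(idx)], collapse = ", "),
                 " nm not found in the extinction table"))
  }
  channels <- extinction[idx, ]
  structure(
    list(source_detector_cm = source_detector_cm, channels = channels),
    class = "probe_geometry"
  )
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat("<probe_geometry> L =", x$source_detector_cm, "cm\n")
  print(x$channels)
  invisible(x)
}

# 2x2 extinction matrix E, rows = channels, cols = (HbO2, Hb)
extinction_matrix <- function(geometry) {
  ch <- geometry$channels
  matrix(c(ch$eps_hbo2[1], ch$eps_hb[1],
           ch$eps_hbo2[2], ch$eps_hb[2]),
         nrow = 2, byrow = TRUE,
         dimnames = list(paste0(ch$wavelength_nm, "nm"), c("hbo2", "hb")))
}

# Intensity column names implied by a geometry ("i700", "i910")
channel_columns <- function(geometry) {
  paste0("i", round(geometry$channels$wavelength_nm))
}
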