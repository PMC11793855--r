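#' Change in optical density from detected and incident intensity
#'
#' The attenuation at one wavelength: `-log10(I_o / I_i)`. Non-positive
#' detected intensities cannot be log-transformed and are flagged `NA`;
#' the missing mark propagates through the rest of the pipeline.
#'
#' @param intensity Detected (reflected) intensity sequence, `I_o`.
#' @param incident Incident reference intensity `I_i`, a positive scalar.
#' @return Numeric vector of optical-density changes, same length as
#'   `intensity`, `NA` where `intensity <= 0`.
#' @export
#' @examples
#' delta_od(c(1, 0.1, 0.01), incident = 1) # 0, 1, 2 decades
delta_od <- function(intensity, incident) {
  if (!is.numeric(incident) || length(incident) != 1L || is.na(incident) ||
      incident <= 0) {
    abort("incident intensity must be a single positive number")
  }
  out <- rep(NA_real_, length(intensity))
  ok <- !is.na(intensity) & intensity > 0
  out[ok] <- -log10(intensity[ok] / incident)
  out
}

#' Invert the modified Beer-Lambert law for two wavelengths
#'
#' Recovers per-sample oxy- and deoxy-hemoglobin concentration changes from
#' the pair of optical-density changes by the least-squares normal-equations
#' form: each attenuation is first divided by its pathlength factor B, then
#' `[dHbO2, dHb]' = (1/L) (E'E)^{-1} E' A`, with `E` the 2x2 matrix of molar
#' extinction coefficients (rows = wavelengths, columns = HbO2, Hb).
#'
#' @param od_1,od_2 Optical-density change sequences for the first and
#'   second channel of `geometry` (equal lengths).
#' @param geometry A [probe_geometry()].
#' @param max_condition Maximum allowed condition number of `E`; an
#'   ill-conditioned extinction table is a hard error because the inversion
#'   would amplify noise without bound.
#' @return A tibble with columns `d_hbo2` and `d_hb`.
#' @export
#' @examples
#' g <- probe_geometry()
#' mbll_invert(c(0.3, 0), c(0.2, 0), g)
mbll_invert <- function(od_1, od_2, geometry, max_condition = 1e8) {
  if (length(od_1) != length(od_2)) {
    abort("the two optical-density sequences must have equal length")
  }
  E <- extinction_matrix(geometry)
  if (kappa(E, exact = TRUE) > max_condition) {
    abort(paste0(
      "extinction matrix is ill-conditioned (condition number > ",
      format(max_condition), "); check the extinction table at ",
      paste(geometry$channels$wavelength_nm, collapse = "/"), " nm"
    ))
  }
  b <- geometry$channels$b_factor
  A <- rbind(od_1 / b[1], od_2 / b[2])
  M <- solve(crossprod(E), t(E)) / geometry$source_detector_cm
  out <- M %*% A
  tibble(d_hbo2 = out[1, ], d_hb = out[2, ])
}

#' Total-hemoglobin concentration change
#'
#' @param d_hbo2,d_hb Oxy- and deoxy-hemoglobin change sequences (equal
#'   length).
#' @return Element-wise sum `d_hbo2 + d_hb`.
#' @export
delta_hbt <- function(d_hbo2, d_hb) {
  if (length(d_hbo2) != length(d_hb)) {
    abort("d_hbo2 and d_hb must have equal length")
  }
  d_hbo2 + d_hb
}

#' Tissue oxygen saturation change
#'
#' The oxy fraction of the total-hemoglobin change, in percent:
#' `100 * d_hbo2 / (d_hbo2 + d_hb)`. Samples whose denominator magnitude
#' falls below `floor` are marked missing rather than emitting huge or
#' infinite ratios; downstream window means skip missing samples.
#'
#' @inheritParams delta_hbt
#' @param floor Smallest denominator magnitude considered informative.
#' @return Percent sequence, `NA` at degenerate samples.
#' @export
#' @examples
#' delta_sto2(c(1, 3), c(1, 1)) # 50, 75
delta_sto2 <- function(d_hbo2, d_hb, floor = 1e-9) {
  if (length(d_hbo2) != length(d_hb)) {
    abort("d_hbo2 and d_hb must have equal length")
  }
  den <- d_hbo2 + d_hb
  out <- 100 * d_hbo2 / den
  out[!is.na(den) & abs(den) < floor] <- NA_real_
  out
}

#' Process a raw optical trace into hemoglobin time series
#'
#' Applies the full modified Beer-Lambert chain to a recording: per-channel
#' optical density (relative to the incident reference), least-squares
#' inversion to oxy/deoxy changes, then total hemoglobin and tissue oxygen
#' saturation.
#'
#' The incident reference is not recorded by the probe as a separate
#' channel. By default it is estimated per channel as the mean detected
#' intensity over the first `baseline_s` seconds of the recording, which
#' makes every derived quantity a change from that early baseline. When the
#' true incident intensities are known (e.g. for simulated recordings, where
#' the manifest stores them) pass them via `incident` to recover the
#' absolute signal levels.
#'
#' @param trace A data frame with columns `time_s` and the two intensity
#'   channels named after the geometry wavelengths (`i700`, `i910` for the
#'   default probe).
#' @param geometry A [probe_geometry()].
#' @param incident `NULL` (estimate from the first `baseline_s` seconds) or
#'   a numeric vector of two positive incident intensities, ordered as the
#'   geometry channels.
#' @param baseline_s Length of the leading window used to estimate the
#'   incident reference when `incident` is `NULL`.
#' @param sto2_floor Denominator floor passed to [delta_sto2()].
#' @param max_condition Passed to [mbll_invert()].
#' @return A tibble with columns `time_s`, `d_hbo2`, `d_hb`, `d_hbt`,
#'   `d_sto2` (and `pressure`, carried through if present).
#' @export
mbll_process <- function(trace, geometry = probe_geometry(), incident = NULL,
                         baseline_s = 1, sto2_floor = 1e-9,
                         max_condition = 1e8) {
  cols <- channel_columns(geometry)
  need <- c("time_s", cols)
  if (!all(need %in% names(trace))) {
    abort(paste0("trace must have columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(trace) < 2L) abort("trace must have at least 2 samples")
  if (is.unsorted(trace$time_s, strictly = TRUE)) {
    abort("time_s must be strictly increasing")
  }
  if (is.null(incident)) {
    sel <- trace$time_s <= trace$time_s[1] + baseline_s
    incident <- vapply(cols, function(cl) {
      v <- trace[[cl]][sel]
      v <- v[!is.na(v) & v > 0]
      if (!length(v)) abort(paste0("no usable baseline samples in ", cl))
      mean(v)
    }, numeric(1))
  }
  if (length(incident) != 2L || any(!is.finite(incident)) || any(incident <= 0)) {
    abort("incident must be two positive intensities (one per channel)")
  }
  od_1 <- delta_od(trace[[cols[1]]], incident[[1]])
  od_2 <- delta_od(trace[[cols[2]]], incident[[2]])
  hemo <- mbll_invert(od_1, od_2, geometry, max_condition = max_condition)
  out <- tibble(
    time_s = trace$time_s,
    d_hbo2 = hemo$d_hbo2,
    d_hb = hemo$d_hb,
    d_hbt = delta_hbt(hemo$d_hbo2, hemo$d_hb),
    d_sto2 = delta_sto2(hemo$d_hbo2, hemo$d_hb, floor = sto2_floor)
  )
  if ("pressure" %in% names(trace)) out$pressure <- trace$pressure
  out
}
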