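#' Analysis windows for perfusion index extraction
#'
#' The seven perfusion indexes are window statistics of the hemoglobin
#' signals around the press/release cycles. The protocol description leaves
#' the windows open; these defaults avoid the transition transients:
#' baseline = 3 s immediately before the first press, press plateau = last
#' `press_plateau_s` of each press, recovery plateau = last
#' `recovery_plateau_s` of each release, and the reperfusion rate is the
#' slope of an ordinary-least-squares line over the first `rate_fit_s`
#' after each release.
#'
#' @param baseline_s,press_plateau_s,recovery_plateau_s,rate_fit_s Window
#'   lengths in seconds.
#' @return A named list of window lengths.
#' @export
index_windows <- function(baseline_s = 3, press_plateau_s = 2,
                          recovery_plateau_s = 3, rate_fit_s = 2) {
  list(baseline_s = baseline_s, press_plateau_s = press_plateau_s,
       recovery_plateau_s = recovery_plateau_s, rate_fit_s = rate_fit_s)
}

#' Mean of a signal over a sample window, skipping missing samples
#'
#' @param signal Numeric vector.
#' @param from,to Sample indices (inclusive) of the window.
#' @return Arithmetic mean of the non-missing samples.
#' @export
window_mean <- function(signal, from, to) {
  if (from < 1L || to > length(signal) || from > to) {
    abort("window out of bounds")
  }
  v <- signal[from:to]
  v <- v[!is.na(v)]
  if (!length(v)) abort("window contains no usable samples")
  mean(v)
}

#' Early-reperfusion rate after a pressure release
#'
#' Slope (signal units per second) of the ordinary-least-squares line fit
#' of the signal against time over the first `fit_window_s` seconds after
#' the press offset. Missing samples are dropped; fewer than 3 usable
#' samples is an error.
#'
#' @param signal Numeric vector.
#' @param time_s Time stamps, same length as `signal`.
#' @param press_offset Sample index at which the release starts.
#' @param fit_window_s Length of the fit window in seconds.
#' @return The OLS slope.
#' @export
recovery_rate <- function(signal, time_s, press_offset, fit_window_s = 2) {
  if (press_offset < 1L || press_offset > length(signal)) {
    abort("press_offset out of bounds")
  }
  t0 <- time_s[press_offset]
  sel <- which(time_s >= t0 & time_s <= t0 + fit_window_s)
  y <- signal[sel]
  x <- time_s[sel]
  ok <- !is.na(y)
  if (sum(ok) < 3L) {
    abort("fewer than 3 usable samples in the recovery-rate fit window")
  }
  x <- x[ok]; y <- y[ok]
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

#' Extract the seven perfusion indexes from one hemoglobin signal
#'
#' Given a processed hemoglobin trace and a protocol segmentation, computes
#' for the chosen signal (total hemoglobin `"hbt"` or tissue oxygen
#' saturation `"sto2"`):
#' \describe{
#'   \item{Index I}{baseline-window mean (initial circulation state).}
#'   \item{Index II}{mean across cycles of the press-plateau means
#'     (perfusion under occlusion).}
#'   \item{Index III}{mean across cycles of the recovery-plateau means
#'     (recovered perfusion).}
#'   \item{Index IV}{III - I (recovered minus initial level), exactly.}
#'   \item{Index V}{press plateau of cycle 1 minus the mean of cycles 2-3
#'     (first versus repeated occlusion).}
#'   \item{Index VI}{mean across cycles of the early-reperfusion rate
#'     (perfusion rate, units/s).}
#'   \item{Index VII}{reperfusion rate of cycle 1 minus the mean of cycles
#'     2-3.}
#' }
#' Indexes V and VII need at least two cycles and are `NA` otherwise.
#'
#' @param hemo Tibble from [mbll_process()] (columns `time_s`, `d_hbt`,
#'   `d_sto2`).
#' @param seg A [segment_protocol()] result for the same recording.
#' @param signal `"hbt"` or `"sto2"`.
#' @param windows Window lengths from [index_windows()].
#' @return One-row tibble: `signal`, `index_i` ... `index_vii`, and
#'   `conformant` (all protocol timing checks passed).
#' @export
perfusion_indexes <- function(hemo, seg, signal = c("hbt", "sto2"),
                              windows = index_windows()) {
  signal <- match.arg(signal)
  col <- paste0("d_", signal)
  if (!all(c("time_s", col) %in% names(hemo))) {
    abort(paste0("hemo must have columns time_s and ", col))
  }
  y <- hemo[[col]]
  t <- hemo$time_s
  fs <- seg$sampling_rate
  cy <- seg$cycles
  nc <- nrow(cy)

  press_w <- max(1L, round(windows$press_plateau_s * fs))
  rec_w <- max(1L, round(windows$recovery_plateau_s * fs))

  idx_i <- window_mean(y, seg$baseline_start, seg$baseline_end)
  press_means <- vapply(seq_len(nc), function(i) {
    window_mean(y, max(cy$press_onset[i], cy$press_offset[i] - press_w),
                cy$press_offset[i])
  }, numeric(1))
  rec_means <- vapply(seq_len(nc), function(i) {
    window_mean(y, max(cy$press_offset[i], cy$release_offset[i] - rec_w),
                cy$release_offset[i])
  }, numeric(1))
  rates <- vapply(seq_len(nc), function(i) {
    recovery_rate(y, t, cy$press_offset[i], windows$rate_fit_s)
  }, numeric(1))

  idx_ii <- mean(press_means)
  idx_iii <- mean(rec_means)
  idx_v <- if (nc >= 2) press_means[1] - mean(press_means[-1]) else NA_real_
  idx_vi <- mean(rates)
  idx_vii <- if (nc >= 2) rates[1] - mean(rates[-1]) else NA_real_

  tibble(
    signal = signal,
    index_i = idx_i,
    index_ii = idx_ii,
    index_iii = idx_iii,
    index_iv = idx_iii - idx_i,
    index_v = idx_v,
    index_vi = idx_vi,
    index_vii = idx_vii,
    conformant = all(seg$conformance$pass)
  )
}

# Feature order used by the classifier: the five indexes that separate the
# good- and poor-perfusion groups.
feature_names <- function() {
  c("hbt_index_i", "hbt_index_ii", "hbt_index_iii", "hbt_index_vi",
    "sto2_index_vii")
}

#' Assemble classifier feature vectors from per-trial index tables
#'
#' The classifier input is the fixed-order 5-vector
#' (HbT Index I, HbT II, HbT III, HbT VI, StO2 VII) per trial. Input is a
#' long index table with one row per trial per signal (as produced by
#' [process_cohort()] or [run_process()]); trials missing any constituent
#' index are excluded with a message.
#'
#' @param index_table Tibble with columns `signal`, `index_i` ...
#'   `index_vii` plus any identifier columns (e.g. `group`, `subject`,
#'   `trial`), one row per trial per signal.
#' @return A tibble with the identifier columns and the five feature
#'   columns `hbt_index_i`, `hbt_index_ii`, `hbt_index_iii`,
#'   `hbt_index_vi`, `sto2_index_vii`.
#' @export
build_features <- function(index_table) {
  id_cols <- setdiff(names(index_table),
                     c("signal", paste0("index_", c("i", "ii", "iii", "iv",
                                                    "v", "vi", "vii")),
                       "conformant"))
  wide <- index_table |>
    dplyr::select(dplyr::all_of(c(id_cols, "signal", "index_i", "index_ii",
                                  "index_iii", "index_vi", "index_vii"))) |>
    tidyr::pivot_wider(names_from = "signal",
                       values_from = dplyr::starts_with("index_"),
                       names_glue = "{signal}_{.value}")
  out <- wide |>
    dplyr::select(dplyr::all_of(id_cols),
                  hbt_index_i = "hbt_index_i",
                  hbt_index_ii = "hbt_index_ii",
                  hbt_index_iii = "hbt_index_iii",
                  hbt_index_vi = "hbt_index_vi",
                  sto2_index_vii = "sto2_index_vii")
  bad <- !stats::complete.cases(out[feature_names()])
  if (any(bad)) {
    inform(sprintf("build_features: excluding %d trial(s) with undefined indexes",
                   sum(bad)))
    out <- out[!bad, ]
  }
  out
}
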