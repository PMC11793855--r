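#' Segment the applied-pressure signal into press/release cycles
#'
#' The measurement protocol applies pressure to the probe for a nominal 5 s,
#' releases it for 10 s, and repeats three times. This detects the press
#' epochs as maximal runs where the pressure exceeds a relative threshold,
#' `q05 + threshold_frac * (q95 - q05)` of the robust signal range (so the
#' segmentation is invariant to affine rescaling of the sensor units).
#' Sub-debounce gaps inside a run are bridged and sub-debounce runs are
#' dropped, which makes the detection robust to sensor spikes.
#'
#' @param trace Data frame with columns `time_s` and `pressure`.
#' @param n_cycles Number of press/release cycles expected (protocol
#'   default 3). Detection of a different number is an error.
#' @param threshold_frac Fraction of the robust range used as the on/off
#'   threshold.
#' @param debounce_s Runs or gaps shorter than this are merged away.
#' @param baseline_s Length (s) of the pre-press baseline window; at least
#'   `min_baseline_s` of it must exist before the first press.
#' @param min_baseline_s Minimum usable baseline, else an error.
#' @param nominal_press_s,nominal_release_s Nominal protocol timings used
#'   for conformance flags and for the trailing release window.
#' @param tolerance_frac Relative timing tolerance for conformance flags
#'   (cycles outside nominal +/- this fraction are flagged, not dropped).
#' @return A `protocol_segmentation` object: list with `cycles` (tibble of
#'   sample indices `press_onset`, `press_offset`, `release_offset` and the
#'   corresponding times), `baseline_start`, `baseline_end`,
#'   `sampling_rate`, `n` and `conformance` (see [validate_protocol()]).
#' @export
segment_protocol <- function(trace, n_cycles = 3, threshold_frac = 0.5,
                             debounce_s = 0.25, baseline_s = 3,
                             min_baseline_s = 1,
                             nominal_press_s = 5, nominal_release_s = 10,
                             tolerance_frac = 0.2) {
  if (!all(c("time_s", "pressure") %in% names(trace))) {
    abort("trace must have columns time_s and pressure")
  }
  p <- trace$pressure
  t <- trace$time_s
  n <- length(p)
  if (n < 3L) abort("pressure trace too short to segment")
  fs <- (n - 1) / (t[n] - t[1])

  q <- quantile(p, c(0.05, 0.95), na.rm = TRUE, names = FALSE)
  rng <- q[2] - q[1]
  if (!is.finite(rng) || rng <= .Machine$double.eps * max(1, abs(q[2]))) {
    abort("pressure signal is flat: no press/release cycles to segment")
  }
  thr <- q[1] + threshold_frac * rng
  above <- !is.na(p) & p > thr

  deb <- max(1L, round(debounce_s * fs))
  r <- rle(above)
  # bridge short FALSE gaps strictly between TRUE runs
  if (length(r$lengths) > 2L) {
    inner <- which(!r$values & r$lengths < deb)
    inner <- inner[inner > 1L & inner < length(r$values)]
    r$values[inner] <- TRUE
    r <- rle(inverse.rle(r))
  }
  # drop short TRUE runs
  r$values[r$values & r$lengths < deb] <- FALSE
  above <- inverse.rle(r)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_idx <- starts[r$values]
  off_idx <- ends[r$values]
  n_found <- length(on_idx)

  # Refine each boundary against the cycle's own plateau level: the global
  # threshold drifts with pulse-to-pulse amplitude variation, a local 50%
  # crossing does not. Light smoothing suppresses near-threshold chatter.
  if (n_found) {
    sm <- as.numeric(stats::filter(p, rep(1 / 3, 3)))
    sm[is.na(sm)] <- p[is.na(sm)]
    for (j in seq_len(n_found)) {
      local_amp <- stats::median(p[on_idx[j]:off_idx[j]])
      local_thr <- q[1] + threshold_frac * (local_amp - q[1])
      win <- max(1L, on_idx[j] - deb):min(n, on_idx[j] + deb)
      hit <- win[sm[win] >= local_thr]
      if (length(hit)) on_idx[j] <- min(hit)
      win <- max(1L, off_idx[j] - deb):min(n, off_idx[j] + deb)
      hit <- win[sm[win] >= local_thr]
      if (length(hit)) off_idx[j] <- max(hit)
    }
  }
  if (n_found != n_cycles) {
    eps <- if (n_found) {
      paste(sprintf("[%.2f, %.2f] s", t[on_idx], t[off_idx]), collapse = ", ")
    } else "none"
    abort(sprintf(
      "expected %d press cycles but detected %d (epochs: %s)",
      n_cycles, n_found, eps))
  }

  release_off <- integer(n_cycles)
  for (i in seq_len(n_cycles)) {
    release_off[i] <- if (i < n_cycles) {
      on_idx[i + 1] - 1L
    } else {
      min(n, off_idx[i] + round(nominal_release_s * fs))
    }
  }

  b_end <- on_idx[1] - 1L
  b_start <- max(1L, on_idx[1] - round(baseline_s * fs))
  if (b_end < 1L || (t[b_end] - t[b_start]) < min_baseline_s) {
    abort(sprintf(
      "insufficient pre-press baseline: need at least %.1f s before the first press",
      min_baseline_s))
  }

  cycles <- tibble(
    cycle = seq_len(n_cycles),
    press_onset = on_idx,
    press_offset = off_idx,
    release_offset = release_off,
    press_onset_s = t[on_idx],
    press_offset_s = t[off_idx],
    release_offset_s = t[release_off]
  )
  seg <- structure(
    list(cycles = cycles, baseline_start = b_start, baseline_end = b_end,
         sampling_rate = fs, n = n, threshold = thr,
         nominal_press_s = nominal_press_s,
         nominal_release_s = nominal_release_s,
         tolerance_frac = tolerance_frac),
    class = "protocol_segmentation"
  )
  seg$conformance <- validate_protocol(seg, trace)
  seg
}

#' Check a segmentation against the nominal protocol timing
#'
#' Computes per-cycle press and release durations and flags cycles whose
#' timing falls outside the nominal values by more than the tolerance
#' fraction. Conformance is timing-only; the applied pressure magnitude is
#' not standardized by the protocol.
#'
#' @param seg A `protocol_segmentation`.
#' @param trace The pressure trace the segmentation came from.
#' @param nominal_press_s,nominal_release_s,tolerance_frac Override the
#'   values stored in `seg`.
#' @return A tibble with one row per cycle: durations in seconds and
#'   logical `press_ok`, `release_ok`, `pass`.
#' @export
validate_protocol <- function(seg, trace,
                              nominal_press_s = seg$nominal_press_s,
                              nominal_release_s = seg$nominal_release_s,
                              tolerance_frac = seg$tolerance_frac) {
  cy <- seg$cycles
  press_dur <- cy$press_offset_s - cy$press_onset_s
  release_dur <- cy$release_offset_s - cy$press_offset_s
  press_ok <- abs(press_dur - nominal_press_s) <= tolerance_frac * nominal_press_s
  release_ok <- abs(release_dur - nominal_release_s) <=
    tolerance_frac * nominal_release_s
  tibble(
    cycle = cy$cycle,
    press_duration_s = press_dur,
    release_duration_s = release_dur,
    press_ok = press_ok,
    release_ok = release_ok,
    pass = press_ok & release_ok
  )
}

#' @export
print.protocol_segmentation <- function(x, ...) {
  cat(sprintf(
    "<protocol_segmentation> %d cycles, fs = %.4g Hz, baseline [%d, %d]\n",
    nrow(x$cycles), x$sampling_rate, x$baseline_start, x$baseline_end))
  print(x$cycles)
  invisible(x)
}

#' @rdname segment_protocol
#' @param x A `protocol_segmentation`.
#' @param ... Unused.
#' @method tidy protocol_segmentation
#' @export
tidy.protocol_segmentation <- function(x, ...) {
  dplyr::left_join(x$cycles, x$conformance, by = "cycle")
}

#' Serialize a segmentation to JSON
#'
#' @param seg A `protocol_segmentation`.
#' @param path Optional output file; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
segmentation_json <- function(seg, path = NULL) {
  payload <- list(
    sampling_rate_hz = seg$sampling_rate,
    baseline = list(start = seg$baseline_start, end = seg$baseline_end),
    cycles = seg$cycles,
    conformance = seg$conformance
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
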