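#' Simulation configuration for the press-release protocol
#'
#' Defaults reproduce the study conditions: pressure applied for 5 s and
#' released for 10 s, repeated 3 times per trial, 6 trials per subject,
#' sampled at 20 Hz (the recording rate is not standardized by the
#' protocol; 20 Hz comfortably resolves the 0.5 s pressure ramps).
#'
#' @param sampling_rate Hz.
#' @param press_s,release_s,n_cycles Protocol timing.
#' @param trials_per_subject Repeated measurements per subject.
#' @param baseline_pad_s Quiet recording before the first press.
#' @param end_pad_s Trailing recording after the last release.
#' @param ramp_s Rise/fall time of the applied-pressure trapezoid; the
#'   nominal press boundaries sit at mid-ramp.
#' @param timing_jitter Relative uniform jitter on press/release durations.
#' @param amplitude_jitter Relative uniform jitter on the pulse amplitude.
#' @param pressure_amplitude Nominal pulse height (sensor units).
#' @param pressure_noise_sd Additive Gaussian noise on the pressure signal.
#' @param tau_press_s Time constant of the occlusion response.
#' @param tau_settle_s Time constant of the post-ramp settling.
#' @param rate_ramp_s Duration of the linear reperfusion ramp; covers the
#'   rate-fit window of [index_windows()] plus a small guard so the fitted
#'   slope reads the drawn rate.
#' @param press_plateau_s,recovery_plateau_s Plateau windows the generator
#'   calibrates against (matching [index_windows()] defaults).
#' @param between_subject_frac Fraction of each calibrated index variance
#'   placed between subjects (the remainder is within-subject,
#'   trial-to-trial).
#' @return Named list of settings.
#' @export
sim_config <- function(sampling_rate = 20, press_s = 5, release_s = 10,
                       n_cycles = 3, trials_per_subject = 6,
                       baseline_pad_s = 5, end_pad_s = 2, ramp_s = 0.5,
                       timing_jitter = 0.05, amplitude_jitter = 0.10,
                       pressure_amplitude = 1, pressure_noise_sd = 0.02,
                       tau_press_s = 1.5, tau_settle_s = 0.6,
                       rate_ramp_s = 2.25,
                       press_plateau_s = 2, recovery_plateau_s = 3,
                       between_subject_frac = 0.7) {
  as.list(environment())
}

#' Packaged group-level calibration table
#'
#' Group-wise means and standard deviations of the perfusion indexes that
#' the generator reproduces, one row per (group, quantity). The
#' `provenance` column distinguishes reported group statistics from values
#' that had to be assumed because no group statistic is available.
#'
#' @return A tibble with columns `group`, `n_subjects`, `quantity`,
#'   `mean`, `sd`, `provenance`.
#' @export
calibration_table <- function() {
  path <- system.file("extdata", "calibration_groups.csv",
                      package = "neoperf", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(group = readr::col_character()))
}

#' Group preset for the synthetic-cohort generator
#'
#' Converts the calibration table rows of one group into the kinetic
#' parameters of the generator so that the pipeline-recovered indexes match
#' the calibration targets by construction: the HbT baseline equals the
#' Index I target, the occlusion drop equals I - II, the recovery deficit
#' equals I - III, and the reperfusion-rate distribution matches Index VI.
#' StO2 is generated around its Index II level, with cycle-1 versus
#' repeat-cycle reperfusion rates separated by the Index VII target.
#'
#' @param group One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param calibration The calibration table (override to recalibrate).
#' @param n_subjects Optional override of the group size.
#' @param hbt_noise_sd,sto2_noise_sd Additive per-sample measurement noise
#'   on the hemoglobin trajectories (signal units / percent).
#' @param cycle1_drop_mult Cycle-1 occlusion drop relative to later cycles
#'   (drives Index V).
#' @return A `group_preset` list of generator parameters.
#' @export
group_preset <- function(group = c("I", "II", "III", "IV"),
                         calibration = calibration_table(),
                         n_subjects = NULL,
                         hbt_noise_sd = 0.002, sto2_noise_sd = 0.10,
                         cycle1_drop_mult = 1.1) {
  group <- match.arg(group)
  cal <- calibration[calibration$group == group, ]
  if (!nrow(cal)) abort(paste0("no calibration rows for group ", group))
  get <- function(q) {
    row <- cal[cal$quantity == q, ]
    if (nrow(row) != 1) abort(paste0("calibration missing quantity ", q))
    list(mean = row$mean, sd = row$sd)
  }
  i <- get("hbt_index_i"); ii <- get("hbt_index_ii")
  iii <- get("hbt_index_iii"); vi <- get("hbt_index_vi")
  s_ii <- get("sto2_index_ii"); s_vii <- get("sto2_index_vii")
  sd_floor <- 0.003
  drop_sd <- sqrt(max(ii$sd^2 - i$sd^2, sd_floor^2))
  recdef_sd <- sqrt(max(iii$sd^2 - i$sd^2, sd_floor^2))
  if (i$mean - ii$mean <= 0) abort("preset implies a non-positive occlusion drop")
  preset <- list(
    group = group,
    n_subjects = n_subjects %||% cal$n_subjects[1],
    hbt_baseline_mean = i$mean, hbt_baseline_sd = i$sd,
    hbt_press_drop_mean = i$mean - ii$mean, hbt_press_drop_sd = drop_sd,
    hbt_recovery_deficit_mean = i$mean - iii$mean,
    hbt_recovery_deficit_sd = recdef_sd,
    hbt_rate_mean = vi$mean, hbt_rate_sd = vi$sd,
    sto2_baseline_mean = s_ii$mean + 0.35, sto2_baseline_sd = s_ii$sd,
    sto2_press_drop_mean = 0.35, sto2_press_drop_sd = 0.05,
    sto2_recovery_deficit_mean = 0.10, sto2_recovery_deficit_sd = 0.03,
    sto2_rate_repeat_mean = 1.5,
    sto2_rate_first_mean = 1.5 + s_vii$mean,
    sto2_rate_first_sd = s_vii$sd / sqrt(2),
    sto2_rate_repeat_sd = s_vii$sd,
    hbt_noise_sd = hbt_noise_sd, sto2_noise_sd = sto2_noise_sd,
    cycle1_drop_mult = cycle1_drop_mult
  )
  if (preset$sto2_baseline_mean - preset$sto2_press_drop_mean <= 0) {
    abort("preset implies a non-positive StO2 level under occlusion")
  }
  structure(preset, class = "group_preset")
}

#' Simulate the applied-pressure signal of one trial
#'
#' Baseline-then-trapezoidal pulses with 0.5 s ramps, uniform timing and
#' amplitude jitter, and additive Gaussian sensor noise (the signal is
#' clipped at zero, as a contact-force sensor reads). Ground-truth press
#' boundaries (mid-ramp times) are returned alongside the trace.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (randomness is local to the call).
#' @return List with `trace` (tibble `time_s`, `pressure`) and `truth`
#'   (tibble `cycle`, `press_onset_s`, `press_offset_s`, `release_end_s`).
#' @export
simulate_pressure <- function(config = sim_config(), seed = NULL) {
  run <- function() {
    nc <- config$n_cycles
    jit <- function(x) x * (1 + runif(1, -config$timing_jitter,
                                      config$timing_jitter))
    on_s <- off_s <- rel_s <- numeric(nc)
    t_cur <- config$baseline_pad_s
    for (c in seq_len(nc)) {
      on_s[c] <- t_cur
      off_s[c] <- on_s[c] + jit(config$press_s)
      rel_s[c] <- off_s[c] + jit(config$release_s)
      t_cur <- rel_s[c]
    }
    total <- t_cur + config$end_pad_s
    fs <- config$sampling_rate
    time_s <- seq(0, total, by = 1 / fs)
    p <- numeric(length(time_s))
    half <- config$ramp_s / 2
    for (c in seq_len(nc)) {
      amp <- config$pressure_amplitude *
        (1 + runif(1, -config$amplitude_jitter, config$amplitude_jitter))
      rise <- time_s >= on_s[c] - half & time_s < on_s[c] + half
      hold <- time_s >= on_s[c] + half & time_s < off_s[c] - half
      fall <- time_s >= off_s[c] - half & time_s < off_s[c] + half
      p[rise] <- amp * (time_s[rise] - (on_s[c] - half)) / config$ramp_s
      p[hold] <- amp
      p[fall] <- amp * ((off_s[c] + half) - time_s[fall]) / config$ramp_s
    }
    p <- pmax(0, p + rnorm(length(p), 0, config$pressure_noise_sd))
    list(
      trace = tibble(time_s = time_s, pressure = p),
      truth = tibble(cycle = seq_len(nc), press_onset_s = on_s,
                     press_offset_s = off_s, release_end_s = rel_s)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Piecewise kinetic trajectory calibrated to plateau targets.
#
# Occlusion: first-order approach toward an asymptote chosen so the mean of
# the last `press_plateau_s` of the press equals the press target. Release:
# linear reperfusion ramp at the drawn rate for `rate_ramp_s`, then
# first-order settling toward an asymptote chosen so the mean of the last
# `recovery_plateau_s` equals the recovery target. Closed-form window-mean
# corrections keep the calibration exact in continuous time.
kinetic_trajectory <- function(time_s, truth, baseline, press_targets,
                               recovery_targets, rates, config) {
  tp <- config$tau_press_s; ts <- config$tau_settle_s
  ramp <- config$rate_ramp_s
  wp <- config$press_plateau_s; wr <- config$recovery_plateau_s
  y <- rep(baseline, length(time_s))
  v0 <- baseline
  for (c in seq_len(nrow(truth))) {
    on <- truth$press_onset_s[c]; off <- truth$press_offset_s[c]
    rel <- truth$release_end_s[c]
    dp <- off - on
    mbar_p <- (tp / wp) * (exp(-(dp - wp) / tp) - exp(-dp / tp))
    A <- (press_targets[c] - v0 * mbar_p) / (1 - mbar_p)
    sel <- time_s >= on & time_s < off
    y[sel] <- A + (v0 - A) * exp(-(time_s[sel] - on) / tp)
    v1 <- A + (v0 - A) * exp(-dp / tp)

    sel_ramp <- time_s >= off & time_s < off + ramp
    y[sel_ramp] <- v1 + rates[c] * (time_s[sel_ramp] - off)
    peak <- v1 + rates[c] * ramp

    dr <- rel - off
    mbar_r <- (ts / wr) * (exp(-(dr - wr - ramp) / ts) - exp(-(dr - ramp) / ts))
    R <- (recovery_targets[c] - peak * mbar_r) / (1 - mbar_r)
    sel_set <- time_s >= off + ramp & time_s < rel
    y[sel_set] <- R + (peak - R) * exp(-(time_s[sel_set] - off - ramp) / ts)
    v0 <- R + (peak - R) * exp(-(dr - ramp) / ts)
    y[time_s >= rel] <- v0
  }
  y
}

# Per-subject parameter draws; between-subject share of the calibrated
# variance per sim_config()$between_subject_frac.
draw_subject_params <- function(preset, config) {
  fb <- sqrt(config$between_subject_frac)
  list(
    hbt_baseline = rnorm(1, preset$hbt_baseline_mean,
                         fb * preset$hbt_baseline_sd),
    hbt_press_drop = rnorm(1, preset$hbt_press_drop_mean,
                           fb * preset$hbt_press_drop_sd),
    hbt_recovery_deficit = rnorm(1, preset$hbt_recovery_deficit_mean,
                                 fb * preset$hbt_recovery_deficit_sd),
    hbt_rate = rnorm(1, preset$hbt_rate_mean, fb * preset$hbt_rate_sd),
    sto2_baseline = rnorm(1, preset$sto2_baseline_mean,
                          fb * preset$sto2_baseline_sd),
    sto2_press_drop = rnorm(1, preset$sto2_press_drop_mean,
                            fb * preset$sto2_press_drop_sd),
    sto2_recovery_deficit = rnorm(1, preset$sto2_recovery_deficit_mean,
                                  fb * preset$sto2_recovery_deficit_sd)
  )
}

# Per-trial draws around the subject values.
#
# The within-subject share of the calibrated level variance (30% of the
# printed index variance) is split into a trial-common shift (1/3 of it)
# plus window-independent drift (2/3): over a ~50 s trial the tissue level
# drifts, so the baseline, occlusion and recovery windows fluctuate partly
# independently rather than moving in lockstep. The drift terms enter the
# baseline level and the press/recovery window targets separately (shared
# across the three cycles, so the cycle contrasts V and VII are untouched).
#
# HbT cycle rates decompose the calibrated Index VI variance as 70%
# between subjects, 25% between trials, 5% across the 3-cycle average.
# StO2 cycle-1 and repeat rates carry sd/sqrt(2) and sd respectively, so
# Var(rate1 - mean(rate2, rate3)) equals the calibrated Index VII variance.
draw_trial_params <- function(sub, preset, config) {
  fw <- 1 - config$between_subject_frac
  f_tr <- sqrt(fw / 3)       # trial-common share of the level variance
  f_wn <- sqrt(2 * fw / 3)   # window-independent share
  nc <- config$n_cycles
  rate_trial <- rnorm(1, sub$hbt_rate, sqrt(0.25) * preset$hbt_rate_sd)
  hbt_rates <- rnorm(nc, rate_trial, sqrt(0.15) * preset$hbt_rate_sd)
  sto2_rates <- c(
    rnorm(1, preset$sto2_rate_first_mean, preset$sto2_rate_first_sd),
    rnorm(nc - 1, preset$sto2_rate_repeat_mean, preset$sto2_rate_repeat_sd)
  )
  drop_t <- rnorm(1, sub$hbt_press_drop, sqrt(fw) * preset$hbt_press_drop_sd)
  drops <- drop_t * c(preset$cycle1_drop_mult, rep(1, nc - 1))
  s_drop_t <- rnorm(1, sub$sto2_press_drop, sqrt(fw) * preset$sto2_press_drop_sd)
  level_t <- rnorm(1, sub$hbt_baseline, f_tr * preset$hbt_baseline_sd)
  s_level_t <- rnorm(1, sub$sto2_baseline, f_tr * preset$sto2_baseline_sd)
  list(
    hbt_baseline = rnorm(1, level_t, f_wn * preset$hbt_baseline_sd),
    hbt_level = level_t,
    hbt_press_window_shift = rnorm(1, 0, f_wn * preset$hbt_baseline_sd),
    hbt_recovery_window_shift = rnorm(1, 0, f_wn * preset$hbt_baseline_sd),
    hbt_drops = drops,
    hbt_recovery_deficit = rnorm(1, sub$hbt_recovery_deficit,
                                 sqrt(fw) * preset$hbt_recovery_deficit_sd),
    hbt_rates = hbt_rates,
    sto2_baseline = rnorm(1, s_level_t, f_wn * preset$sto2_baseline_sd),
    sto2_level = s_level_t,
    sto2_press_window_shift = rnorm(1, 0, f_wn * preset$sto2_baseline_sd),
    sto2_recovery_window_shift = rnorm(1, 0, f_wn * preset$sto2_baseline_sd),
    sto2_drops = rep(s_drop_t, nc),
    sto2_recovery_deficit = rnorm(1, sub$sto2_recovery_deficit,
                                  sqrt(fw) * preset$sto2_recovery_deficit_sd),
    sto2_rates = sto2_rates
  )
}

#' Ground-truth hemodynamic trajectories for one trial
#'
#' Builds the total-hemoglobin and tissue-oxygen-saturation trajectories
#' over the given protocol timing (see the package vignette for the kinetic
#' model), adds per-sample Gaussian measurement noise, and derives the
#' oxy/deoxy components by inverting the definitions of total hemoglobin
#' and saturation: `d_hbo2 = sto2/100 * hbt`, `d_hb = hbt - d_hbo2`.
#'
#' @param preset A [group_preset()].
#' @param config A [sim_config()].
#' @param truth Press-boundary tibble from [simulate_pressure()].
#' @param time_s Sample times.
#' @param params Optional pre-drawn trial parameters (from the internal
#'   draw helpers); drawn fresh around the preset means when `NULL`.
#' @param seed Optional integer seed.
#' @return List with `hemo` (tibble `time_s`, `hbt`, `sto2`, `d_hbo2`,
#'   `d_hb`) and `params` (the kinetic parameters used).
#' @export
simulate_hemodynamics <- function(preset, config, truth, time_s,
                                  params = NULL, seed = NULL) {
  run <- function() {
    if (is.null(params)) {
      sub <- draw_subject_params(preset, config)
      params <- draw_trial_params(sub, preset, config)
    }
    nc <- config$n_cycles
    h_level <- params$hbt_level %||% params$hbt_baseline
    s_level <- params$sto2_level %||% params$sto2_baseline
    h <- kinetic_trajectory(
      time_s, truth,
      baseline = params$hbt_baseline,
      press_targets = h_level - params$hbt_drops +
        (params$hbt_press_window_shift %||% 0),
      recovery_targets = rep(h_level - params$hbt_recovery_deficit +
                               (params$hbt_recovery_window_shift %||% 0), nc),
      rates = params$hbt_rates, config = config)
    s <- kinetic_trajectory(
      time_s, truth,
      baseline = params$sto2_baseline,
      press_targets = s_level - params$sto2_drops +
        (params$sto2_press_window_shift %||% 0),
      recovery_targets = rep(s_level - params$sto2_recovery_deficit +
                               (params$sto2_recovery_window_shift %||% 0), nc),
      rates = params$sto2_rates, config = config)
    h <- h + rnorm(length(h), 0, preset$hbt_noise_sd)
    s <- s + rnorm(length(s), 0, preset$sto2_noise_sd)
    d_hbo2 <- s / 100 * h
    list(
      hemo = tibble(time_s = time_s, hbt = h, sto2 = s,
                    d_hbo2 = d_hbo2, d_hb = h - d_hbo2),
      params = params
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Forward optical model: hemoglobin changes to detected intensities
#'
#' Applies the attenuation relation in the forward direction:
#' `dOD(lambda) = (eps_HbO2 dHbO2 + eps_Hb dHb) * L * B(lambda)` and
#' `I_o = I_i * 10^-dOD`, with optional multiplicative shot noise.
#' Intensities that would underflow are clipped with a warning.
#'
#' @param hemo Tibble with `time_s`, `d_hbo2`, `d_hb`.
#' @param geometry A [probe_geometry()].
#' @param incident Incident intensity per channel (positive).
#' @param shot_noise_sd Relative sd of multiplicative intensity noise.
#' @param seed Optional integer seed.
#' @return Tibble with `time_s` and one intensity column per channel
#'   (`i700`, `i910` for the default probe).
#' @export
forward_optics <- function(hemo, geometry = probe_geometry(),
                           incident = c(1, 1), shot_noise_sd = 0,
                           seed = NULL) {
  run <- function() {
    E <- extinction_matrix(geometry)
    b <- geometry$channels$b_factor
    L <- geometry$source_detector_cm
    out <- tibble(time_s = hemo$time_s)
    cols <- channel_columns(geometry)
    for (k in 1:2) {
      od <- (E[k, 1] * hemo$d_hbo2 + E[k, 2] * hemo$d_hb) * L * b[k]
      io <- incident[k] * 10^(-od)
      if (shot_noise_sd > 0) {
        io <- io * (1 + rnorm(length(io), 0, shot_noise_sd))
      }
      lo <- incident[k] * 1e-12
      if (any(io < lo, na.rm = TRUE)) {
        warn(sprintf("%d sample(s) in %s clipped at the intensity floor",
                     sum(io < lo, na.rm = TRUE), cols[k]))
        io <- pmax(io, lo)
      }
      out[[cols[k]]] <- io
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate one complete trial
#'
#' Pressure protocol, hemodynamic ground truth, and forward optics,
#' assembled into the same four-column recording schema the real-data
#' reader consumes.
#'
#' @inheritParams simulate_hemodynamics
#' @param geometry A [probe_geometry()].
#' @param incident Incident intensities used by the forward model (stored
#'   with the trial so processing can invert at the true reference).
#' @param shot_noise_sd Optical noise, see [forward_optics()].
#' @param subject_params Optional subject-level parameter draws (so trials
#'   of one subject share them).
#' @param seed Optional integer seed.
#' @return List with `trace` (tibble `time_s`, `pressure`, `i700`,
#'   `i910`), `truth` (press boundaries), `params`, `incident`.
#' @export
simulate_trial <- function(preset, config = sim_config(),
                           geometry = probe_geometry(), incident = c(1, 1),
                           shot_noise_sd = 0, subject_params = NULL,
                           seed = NULL) {
  run <- function() {
    pr <- simulate_pressure(config)
    params <- if (!is.null(subject_params)) {
      draw_trial_params(subject_params, preset, config)
    } else NULL
    hd <- simulate_hemodynamics(preset, config, pr$truth,
                                pr$trace$time_s, params = params)
    opt <- forward_optics(hd$hemo, geometry, incident = incident,
                          shot_noise_sd = shot_noise_sd)
    trace <- dplyr::bind_cols(pr$trace, opt[-1])
    list(trace = trace, truth = pr$truth, params = hd$params,
         incident = incident, ground_truth = hd$hemo)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a multi-group cohort
#'
#' Draws `n_subjects` per group preset, `trials_per_subject` trials each,
#' with subject-level kinetic parameters shared across a subject's trials.
#' All randomness flows from `seed`; the same seed reproduces the cohort
#' exactly.
#'
#' @param presets List of [group_preset()] objects (default: all four
#'   groups at their calibrated sizes, 24/14/51/13 subjects).
#' @param config A [sim_config()].
#' @param geometry A [probe_geometry()].
#' @param incident Incident intensities per channel.
#' @param shot_noise_sd Optical noise level.
#' @param seed Integer seed.
#' @return A `sim_cohort`: list with `manifest` (one row per trial:
#'   identifiers, kinetic parameters, incident intensities) and `trials`
#'   (list of trace tibbles, parallel to the manifest rows).
#' @export
simulate_cohort <- function(presets = lapply(c("I", "II", "III", "IV"),
                                             group_preset),
                            config = sim_config(),
                            geometry = probe_geometry(),
                            incident = c(1, 1), shot_noise_sd = 0,
                            seed = 1) {
  withr::with_seed(seed, {
    manifest <- list(); trials <- list(); k <- 0L
    for (preset in presets) {
      for (s in seq_len(preset$n_subjects)) {
        sub <- draw_subject_params(preset, config)
        for (tr in seq_len(config$trials_per_subject)) {
          sim <- simulate_trial(preset, config, geometry,
                                incident = incident,
                                shot_noise_sd = shot_noise_sd,
                                subject_params = sub)
          k <- k + 1L
          trials[[k]] <- sim$trace
          manifest[[k]] <- tibble(
            group = preset$group,
            subject = sprintf("%s_S%02d", preset$group, s),
            trial = tr,
            hbt_baseline = sim$params$hbt_baseline,
            hbt_drop = sim$params$hbt_drops[2],
            hbt_recovery_deficit = sim$params$hbt_recovery_deficit,
            hbt_rate = mean(sim$params$hbt_rates),
            sto2_baseline = sim$params$sto2_baseline,
            sto2_rate_first = sim$params$sto2_rates[1],
            incident_1 = incident[1], incident_2 = incident[2]
          )
        }
      }
    }
    structure(list(manifest = dplyr::bind_rows(manifest), trials = trials,
                   seed = seed),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d trials (%d subjects), seed %d\n",
              nrow(x$manifest), length(unique(x$manifest$subject)), x$seed))
  print(dplyr::count(x$manifest, .data$group))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' One CSV per trial (`time_s, pressure, i700, i910`, the same schema the
#' real-data reader consumes) plus a JSON manifest holding identifiers,
#' ground-truth kinetic parameters, incident intensities and file names.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (with a `file` column), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- cohort$manifest
  man$file <- sprintf("%s_T%d.csv", man$subject, man$trial)
  for (i in seq_len(nrow(man))) {
    readr::write_csv(cohort$trials[[i]], file.path(dir, man$file[i]))
  }
  jsonlite::write_json(list(seed = cohort$seed, trials = man),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(man)
}

#' Read one trial recording
#'
#' @param path CSV with columns `time_s, pressure, i700, i910` (header
#'   required; empty fields are missing values).
#' @return A tibble.
#' @export
read_trial <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
}
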