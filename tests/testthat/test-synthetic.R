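test_that("jitter-free pressure pulses sit exactly on the nominal grid", {
  cfg <- clean_config()
  pr <- simulate_pressure(cfg, seed = 1)
  expect_equal(pr$truth$press_onset_s, c(5, 20, 35))
  expect_equal(pr$truth$press_offset_s, c(10, 25, 40))
  # sample count: baseline + 3 cycles + end pad at 20 Hz, inclusive grid
  expect_equal(nrow(pr$trace), (5 + 3 * 15 + 2) * 20 + 1)
})

test_that("timing jitter keeps press durations inside the configured band", {
  cfg <- sim_config(timing_jitter = 0.10)
  durs <- unlist(lapply(1:100, function(s) {
    tr <- simulate_pressure(cfg, seed = s)$truth
    tr$press_offset_s - tr$press_onset_s
  }))
  expect_true(all(durs >= 4.5 & durs <= 5.5))
  expect_gt(sd(durs), 0)   # jitter is actually applied
})

test_that("noise-free kinetics hit their plateau targets in closed form", {
  preset <- group_preset("I", hbt_noise_sd = 0, sto2_noise_sd = 0)
  cfg <- clean_config()
  pr <- simulate_pressure(cfg, seed = 31)
  params <- list(
    hbt_baseline = 0.68, hbt_drops = rep(0.04, 3),
    hbt_recovery_deficit = 0.012, hbt_rates = rep(1.2, 3),
    sto2_baseline = 52.5, sto2_drops = rep(0.35, 3),
    sto2_recovery_deficit = 0.1, sto2_rates = rep(2, 3)
  )
  hd <- simulate_hemodynamics(preset, cfg, pr$truth, pr$trace$time_s,
                              params = params)
  fs <- cfg$sampling_rate
  # press-plateau window mean equals baseline - drop (calibrated asymptote)
  for (c in 1:3) {
    off <- round(pr$truth$press_offset_s[c] * fs) + 1
    pw <- mean(hd$hemo$hbt[(off - 2 * fs):off])
    expect_equal(pw, 0.68 - 0.04, tolerance = 2e-3)
    rel <- round(pr$truth$release_end_s[c] * fs) + 1
    rw <- mean(hd$hemo$hbt[(rel - 3 * fs):rel])
    expect_equal(rw, 0.68 - 0.012, tolerance = 2e-3)
  }
  # reperfusion ramp carries the drawn rate
  off1 <- round(pr$truth$press_offset_s[1] * fs) + 1
  expect_equal(recovery_rate(hd$hemo$hbt, hd$hemo$time_s, off1), 1.2,
               tolerance = 0.02)

  # zero drop produces a flat trace at baseline
  params$hbt_drops <- rep(0, 3)
  params$hbt_rates <- rep(0, 3)
  params$hbt_recovery_deficit <- 0
  hd0 <- simulate_hemodynamics(preset, cfg, pr$truth, pr$trace$time_s,
                               params = params)
  expect_equal(hd0$hemo$hbt, rep(0.68, nrow(hd0$hemo)), tolerance = 1e-9)
})

test_that("forward optics is the exact inverse image of the MBLL chain", {
  g <- probe_geometry()
  t <- seq(0, 1, by = 0.05)
  hemo <- tibble::tibble(time_s = t, d_hbo2 = rep(0, length(t)),
                         d_hb = rep(0, length(t)))
  # zero change -> detected equals incident
  opt <- forward_optics(hemo, g, incident = c(1.3, 0.7))
  expect_equal(opt$i700, rep(1.3, length(t)))
  expect_equal(opt$i910, rep(0.7, length(t)))

  # doubling the source-detector distance doubles the attenuation
  hemo$d_hbo2 <- 0.3; hemo$d_hb <- 0.25
  g2 <- probe_geometry(source_detector_cm = 2)
  od1 <- -log10(forward_optics(hemo, g)$i700)
  od2 <- -log10(forward_optics(hemo, g2)$i700)
  expect_equal(od2, 2 * od1, tolerance = 1e-12)
})

test_that("a noise-free trial recovers its drawn parameters through the pipeline", {
  preset <- group_preset("I", hbt_noise_sd = 0, sto2_noise_sd = 0)
  sim <- simulate_trial(preset, clean_config(), seed = 33)
  ix <- process_trial(sim$trace, incident = sim$incident)
  hbt <- ix[ix$signal == "hbt", ]
  expect_equal(hbt$index_i, sim$params$hbt_baseline, tolerance = 5e-3)
  expect_equal(hbt$index_iii,
               sim$params$hbt_level - sim$params$hbt_recovery_deficit +
                 sim$params$hbt_recovery_window_shift,
               tolerance = 5e-3)
  expect_equal(hbt$index_ii,
               sim$params$hbt_level - mean(sim$params$hbt_drops) +
                 sim$params$hbt_press_window_shift,
               tolerance = 6e-3)
  expect_equal(hbt$index_vi, mean(sim$params$hbt_rates), tolerance = 0.02)
})

test_that("cohort generation is deterministic and tracks its presets", {
  p <- group_preset("II", n_subjects = 2)
  cfg <- sim_config(trials_per_subject = 2)
  a <- simulate_cohort(list(p), config = cfg, seed = 77)
  b <- simulate_cohort(list(p), config = cfg, seed = 77)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$trials, b$trials)
  expect_equal(nrow(a$manifest), 4L)

  c2 <- simulate_cohort(list(p), config = cfg, seed = 78)
  expect_false(identical(a$trials[[1]], c2$trials[[1]]))
})

test_that("subject-level parameter draws concentrate around the preset means", {
  p <- group_preset("III", n_subjects = 40)
  cfg <- sim_config(trials_per_subject = 1)
  co <- simulate_cohort(list(p), config = cfg, seed = 5)
  man <- co$manifest
  se <- p$hbt_baseline_sd / sqrt(nrow(man))
  expect_lt(abs(mean(man$hbt_baseline) - p$hbt_baseline_mean), 3 * se)
  se_r <- p$hbt_rate_sd / sqrt(nrow(man))
  expect_lt(abs(mean(man$hbt_rate) - p$hbt_rate_mean), 3 * se_r)
})

test_that("group presets preserve the published orderings", {
  pres <- lapply(c("I", "II", "III", "IV"), group_preset)
  base <- vapply(pres, function(p) p$hbt_baseline_mean, numeric(1))
  # full-term groups (I, II) above premature groups (III, IV)
  expect_true(min(base[1:2]) > max(base[3:4]))
  rate1 <- vapply(pres, function(p) p$sto2_rate_first_mean, numeric(1))
  # Group I saturation recovery contrast above groups III/IV
  expect_true(rate1[1] > max(rate1[3:4]))
})
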