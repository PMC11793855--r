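test_that("window_mean averages non-missing samples", {
  expect_equal(window_mean(rep(0.68, 10), 1, 10), 0.68)
  expect_equal(window_mean(c(0.6, 0.8), 1, 2), 0.7)
  withr::with_seed(2, x <- rnorm(50))
  x[c(3, 17)] <- NA
  oracle <- {
    s <- 0; k <- 0
    for (i in 5:40) if (!is.na(x[i])) { s <- s + x[i]; k <- k + 1 }
    s / k
  }
  expect_equal(window_mean(x, 5, 40), oracle)
  expect_error(window_mean(c(NA, NA), 1, 2), "no usable samples")
  expect_error(window_mean(1:5, 0, 3), "out of bounds")
})

test_that("recovery rate recovers exact lines and slow-exponential slopes", {
  t <- seq(0, 10, by = 0.05)
  # perfectly linear post-release ramp
  y <- 0.6 + 0.9 * t
  expect_equal(recovery_rate(y, t, 1), 0.9, tolerance = 1e-12)
  # constant signal has zero rate
  expect_equal(recovery_rate(rep(0.6, length(t)), t, 1), 0)
  # slow exponential: OLS slope over 2 s within 10% of the analytic
  # initial slope (amplitude * rate)
  amp <- 10; r <- 0.05
  y <- amp * (1 - exp(-r * t))
  expect_equal(recovery_rate(y, t, 1, fit_window_s = 2), amp * r,
               tolerance = 0.1)
  expect_error(recovery_rate(c(1, NA, NA, NA), c(0, 1, 2, 3), 1),
               "fewer than 3")
})

# Build a piecewise-constant HbT signal aligned to a detected segmentation
piecewise_hemo <- function(seg, time_s, baseline, press_vals, recovery) {
  y <- rep(baseline, length(time_s))
  for (c in seq_len(nrow(seg$cycles))) {
    y[seg$cycles$press_onset[c]:seg$cycles$press_offset[c]] <- press_vals[c]
    y[(seg$cycles$press_offset[c] + 1L):seg$cycles$release_offset[c]] <- recovery
  }
  last <- max(seg$cycles$release_offset)
  if (last < length(time_s)) y[(last + 1L):length(time_s)] <- recovery
  tibble::tibble(time_s = time_s, d_hbt = y, d_sto2 = y)
}

test_that("plateau indexes are read off a piecewise-constant signal", {
  pr <- simulate_pressure(clean_config(), seed = 21)
  seg <- segment_protocol(pr$trace)
  hemo <- piecewise_hemo(seg, pr$trace$time_s, 0.68, rep(0.64, 3), 0.67)
  ix <- perfusion_indexes(hemo, seg, "hbt")
  expect_equal(ix$index_i, 0.68)
  expect_equal(ix$index_ii, 0.64)
  expect_equal(ix$index_iii, 0.67)
  expect_equal(ix$index_iv, 0.67 - 0.68)
  expect_equal(ix$index_v, 0)
  expect_lt(abs(ix$index_vi), 0.01)   # flat plateaus, near-zero rate

  # first-cycle occlusion deeper than repeats
  hemo2 <- piecewise_hemo(seg, pr$trace$time_s, 0.68, c(0.60, 0.64, 0.64), 0.67)
  ix2 <- perfusion_indexes(hemo2, seg, "hbt")
  expect_equal(ix2$index_v, -0.04)
})

test_that("index IV is exactly III minus I and shifts cancel in contrasts", {
  sim <- simulate_trial(group_preset("II"), sim_config(), seed = 22)
  hemo <- mbll_process(sim$trace, incident = sim$incident)
  seg <- segment_protocol(sim$trace)
  ix <- perfusion_indexes(hemo, seg, "hbt")
  expect_identical(ix$index_iv, ix$index_iii - ix$index_i)

  # adding a constant shifts levels I-III, leaves contrasts IV-VII alone
  shifted <- dplyr::mutate(hemo, d_hbt = d_hbt + 0.25)
  ixs <- perfusion_indexes(shifted, seg, "hbt")
  expect_equal(ixs$index_i, ix$index_i + 0.25)
  expect_equal(ixs$index_ii, ix$index_ii + 0.25)
  expect_equal(ixs$index_iii, ix$index_iii + 0.25)
  expect_equal(ixs$index_iv, ix$index_iv)
  expect_equal(ixs$index_v, ix$index_v)
  expect_equal(ixs$index_vi, ix$index_vi)
  expect_equal(ixs$index_vii, ix$index_vii)
})

test_that("indexes are stable under doubling the sampling rate", {
  params <- list(
    hbt_baseline = 0.68, hbt_drops = c(0.044, 0.04, 0.04),
    hbt_recovery_deficit = 0.012, hbt_rates = c(1.3, 1.0, 1.1),
    sto2_baseline = 52.5, sto2_drops = rep(0.35, 3),
    sto2_recovery_deficit = 0.1, sto2_rates = c(9, 2, 2)
  )
  preset0 <- group_preset("I", hbt_noise_sd = 0, sto2_noise_sd = 0)
  res <- lapply(c(20, 40), function(fs) {
    cfg <- clean_config(sampling_rate = fs)
    pr <- simulate_pressure(cfg, seed = 1)
    hd <- simulate_hemodynamics(preset0, cfg, pr$truth, pr$trace$time_s,
                                params = params)
    trace <- dplyr::bind_cols(pr$trace,
                              forward_optics(hd$hemo)[-1])
    hemo <- mbll_process(trace, incident = c(1, 1))
    seg <- segment_protocol(trace)
    perfusion_indexes(hemo, seg, "hbt")
  })
  for (col in paste0("index_", c("i", "ii", "iii", "iv", "v"))) {
    expect_equal(res[[1]][[col]], res[[2]][[col]], tolerance = 0.005)
  }
  expect_equal(res[[1]]$index_vi, res[[2]]$index_vi, tolerance = 0.03)
})

test_that("feature vectors keep the canonical order and drop broken trials", {
  mk <- function(subject, signal, vals, na_vii = FALSE) {
    tibble::tibble(group = "I", subject = subject, trial = 1L,
                   signal = signal,
                   index_i = vals[1], index_ii = vals[2], index_iii = vals[3],
                   index_iv = vals[3] - vals[1], index_v = 0,
                   index_vi = vals[4],
                   index_vii = if (na_vii) NA_real_ else vals[5],
                   conformant = TRUE)
  }
  tbl <- dplyr::bind_rows(
    mk("S1", "hbt", c(0.68, 0.64, 0.67, 0.9, 0.1)),
    mk("S1", "sto2", c(52, 51.5, 51.9, 2, 8)),
    mk("S2", "hbt", c(0.66, 0.62, 0.65, 1.1, 0.2)),
    mk("S2", "sto2", c(51, 50.5, 50.9, 2, 8), na_vii = TRUE)
  )
  expect_message(f <- build_features(tbl), "excluding 1")
  expect_equal(nrow(f), 1L)
  expect_equal(unname(unlist(f[1, c("hbt_index_i", "hbt_index_ii",
                                    "hbt_index_iii", "hbt_index_vi",
                                    "sto2_index_vii")])),
               c(0.68, 0.64, 0.67, 0.9, 8))
})
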