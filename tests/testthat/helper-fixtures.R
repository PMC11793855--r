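# Shared fixtures. Heavy simulated cohorts are built once per test run and
# cached, since several test files exercise the same pipeline output.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Calibrated Group I / Group IV cohorts at their study sizes, processed
# through the full optics -> MBLL -> segmentation -> index pipeline.
group_cohort <- function(group, seed) {
  cached(paste0("cohort_", group, "_", seed), {
    simulate_cohort(list(group_preset(group)), seed = seed)
  })
}

group_indexes <- function(group, seed) {
  cached(paste0("indexes_", group, "_", seed), {
    process_cohort(group_cohort(group, seed))
  })
}

# An ideal (noise- and jitter-free) protocol configuration.
clean_config <- function(...) {
  sim_config(timing_jitter = 0, amplitude_jitter = 0,
             pressure_noise_sd = 0, ...)
}

# Geometry whose extinction matrix is the identity (B = 1, L = 1), so the
# MBLL inversion can be read off by hand.
identity_geometry <- function() {
  ext <- tibble::tibble(
    wavelength_nm = c(700, 910),
    eps_hbo2 = c(1, 1e-9), eps_hb = c(1e-9, 1),
    b_factor = c(1, 1)
  )
  # eps must be strictly positive; 1e-9 stands in for the zero entries
  probe_geometry(c(700, 910), source_detector_cm = 1, extinction = ext)
}

# Cluster-robust standard error of a cohort mean: SD of subject-level
# means over the subjects (trials within a subject are correlated).
cluster_se <- function(values, subjects) {
  m <- tapply(values, subjects, mean)
  sd(m) / sqrt(length(m))
}
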