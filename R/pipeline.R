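#' Default run configuration
#'
#' Union of the per-module settings, with defaults at the published
#' operating point: 5 s press / 10 s release / 3 cycles, 6 trials per
#' subject, 64 hidden neurons, decision threshold 0.5. Use
#' [load_config()] to override from a YAML file.
#'
#' @return A named list of settings.
#' @export
default_config <- function() {
  list(
    protocol = list(n_cycles = 3, threshold_frac = 0.5, debounce_s = 0.25,
                    baseline_s = 3, min_baseline_s = 1,
                    nominal_press_s = 5, nominal_release_s = 10,
                    tolerance_frac = 0.2),
    mbll = list(source_detector_cm = 1.0, baseline_s = 1,
                sto2_floor = 1e-9, max_condition = 1e8),
    windows = index_windows(),
    rbfnn = list(n_hidden = 64, threshold = 0.5, mu = 0.05, epochs = 200,
                 eps = 1e-8),
    split = list(policy = "subject", n_train = 70, n_test = 30),
    sim = sim_config(),
    seed = 1
  )
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()] (nested keys
#' override individually). Unknown top-level or nested keys are an error so
#' that typos do not silently fall back to defaults.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return A config list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_into <- function(base, upd, prefix = "") {
    for (key in names(upd)) {
      if (!key %in% names(base)) {
        abort(paste0("unknown config key: ", prefix, key))
      }
      if (is.list(base[[key]]) && is.list(upd[[key]])) {
        base[[key]] <- merge_into(base[[key]], upd[[key]],
                                  paste0(prefix, key, "."))
      } else {
        base[[key]] <- upd[[key]]
      }
    }
    base
  }
  merge_into(cfg, user)
}

#' Process one recording into per-signal perfusion indexes
#'
#' Runs the full per-trial chain: modified Beer-Lambert processing,
#' pressure-protocol segmentation, and index extraction for both the total
#' hemoglobin and tissue oxygen saturation signals.
#'
#' @param trace Recording tibble (`time_s, pressure, i700, i910`).
#' @param geometry A [probe_geometry()].
#' @param incident Passed to [mbll_process()] (`NULL` = baseline-referenced).
#' @param config A config list from [default_config()]/[load_config()].
#' @return Two-row tibble (one per signal) of perfusion indexes.
#' @export
process_trial <- function(trace, geometry = probe_geometry(),
                          incident = NULL, config = default_config()) {
  hemo <- mbll_process(trace, geometry, incident = incident,
                       baseline_s = config$mbll$baseline_s,
                       sto2_floor = config$mbll$sto2_floor,
                       max_condition = config$mbll$max_condition)
  pc <- config$protocol
  seg <- segment_protocol(trace, n_cycles = pc$n_cycles,
                          threshold_frac = pc$threshold_frac,
                          debounce_s = pc$debounce_s,
                          baseline_s = pc$baseline_s,
                          min_baseline_s = pc$min_baseline_s,
                          nominal_press_s = pc$nominal_press_s,
                          nominal_release_s = pc$nominal_release_s,
                          tolerance_frac = pc$tolerance_frac)
  dplyr::bind_rows(
    perfusion_indexes(hemo, seg, "hbt", windows = config$windows),
    perfusion_indexes(hemo, seg, "sto2", windows = config$windows)
  )
}

#' Process a simulated cohort into an index table
#'
#' Applies [process_trial()] to every trial of a [simulate_cohort()]
#' result, inverting at each trial's recorded incident reference. Trials
#' that fail segmentation are dropped with a message naming them.
#'
#' @param cohort A `sim_cohort`.
#' @param geometry A [probe_geometry()].
#' @param config A config list.
#' @return Long tibble: `group`, `subject`, `trial`, `signal`,
#'   `index_i` ... `index_vii`, `conformant`.
#' @export
process_cohort <- function(cohort, geometry = probe_geometry(),
                           config = default_config()) {
  man <- cohort$manifest
  rows <- vector("list", nrow(man))
  failed <- character()
  for (i in seq_len(nrow(man))) {
    res <- tryCatch(
      process_trial(cohort$trials[[i]], geometry,
                    incident = c(man$incident_1[i], man$incident_2[i]),
                    config = config),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("%s T%d (%s)", man$subject[i],
                                  man$trial[i], conditionMessage(res)))
      next
    }
    rows[[i]] <- dplyr::bind_cols(
      tibble(group = man$group[i], subject = man$subject[i],
             trial = man$trial[i]),
      res
    )
  }
  if (length(failed)) {
    inform(c("process_cohort: excluded trials failing segmentation:",
             failed))
  }
  dplyr::bind_rows(rows)
}

#' Simulate a cohort to disk (command entry point)
#'
#' @param out_dir Output directory for trial CSVs and the manifest.
#' @param groups Group identifiers to simulate.
#' @param config A config list (its `sim` element and `seed` are used
#'   unless overridden).
#' @param seed Integer seed (overrides `config$seed`).
#' @return The manifest tibble, invisibly.
#' @export
run_simulate <- function(out_dir, groups = c("I", "II", "III", "IV"),
                         config = default_config(), seed = NULL) {
  cohort <- simulate_cohort(presets = lapply(groups, group_preset),
                            config = config$sim,
                            seed = seed %||% config$seed)
  write_cohort(cohort, out_dir)
}

#' Process a directory of trial recordings (command entry point)
#'
#' Reads every trial listed in the directory's `manifest.json` (or, absent
#' a manifest, every `*.csv` file), processes it, and writes/returns the
#' per-trial index table. With a manifest, each trial is inverted at its
#' recorded incident reference; without one, the baseline-referenced
#' default applies.
#'
#' @param in_dir Directory of trial CSVs.
#' @param out_csv Optional path for the index table CSV.
#' @param geometry A [probe_geometry()].
#' @param config A config list.
#' @return The index table tibble.
#' @export
run_process <- function(in_dir, out_csv = NULL,
                        geometry = probe_geometry(),
                        config = default_config()) {
  man_path <- file.path(in_dir, "manifest.json")
  if (file.exists(man_path)) {
    man <- jsonlite::read_json(man_path, simplifyVector = TRUE)$trials
    man <- as_tibble(man)
  } else {
    files <- list.files(in_dir, pattern = "\\.csv$")
    man <- tibble(group = NA_character_,
                  subject = sub("\\.csv$", "", files),
                  trial = seq_along(files), file = files,
                  incident_1 = NA_real_, incident_2 = NA_real_)
  }
  rows <- vector("list", nrow(man))
  failed <- character()
  for (i in seq_len(nrow(man))) {
    trace <- read_trial(file.path(in_dir, man$file[i]))
    inc <- if (is.finite(man$incident_1[i])) {
      c(man$incident_1[i], man$incident_2[i])
    } else NULL
    res <- tryCatch(
      process_trial(trace, geometry, incident = inc, config = config),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("%s (%s)", man$file[i],
                                  conditionMessage(res)))
      next
    }
    rows[[i]] <- dplyr::bind_cols(
      tibble(group = man$group[i], subject = man$subject[i],
             trial = man$trial[i]),
      res
    )
  }
  if (length(failed)) {
    inform(c("run_process: excluded trials failing processing:", failed))
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_csv)) readr::write_csv(out, out_csv)
  out
}

#' Split good/poor-perfusion trials into training and test sets
#'
#' The published evaluation trains on 70 trials drawn from the
#' good-perfusion (Group I) and poor-perfusion (Group IV) cohorts and
#' tests on 30 held-out trials. `policy = "trial"` reproduces that
#' trial-level draw; the default `policy = "subject"` keeps all trials of
#' a subject on the same side of the split (no subject leakage), admitting
#' whole subjects until the requested training size is reached.
#'
#' @param features Feature tibble with `group` and `subject` columns
#'   (Groups I and IV are used).
#' @param n_train,n_test Trial counts.
#' @param policy `"subject"` or `"trial"`.
#' @param seed Integer seed.
#' @return List with `train` and `test` tibbles, each with a `label`
#'   column (`"good"` for Group I, `"poor"` for Group IV).
#' @export
split_trials <- function(features, n_train = 70, n_test = 30,
                         policy = c("subject", "trial"), seed = 1) {
  policy <- match.arg(policy)
  df <- features[features$group %in% c("I", "IV"), ]
  if (nrow(df) < n_train + n_test) {
    abort(sprintf("only %d Group I/IV trials available for a %d/%d split",
                  nrow(df), n_train, n_test))
  }
  df$label <- ifelse(df$group == "I", "good", "poor")
  withr::with_seed(seed, {
    if (policy == "trial") {
      idx <- sample.int(nrow(df))
      train <- df[idx[seq_len(n_train)], ]
      test <- df[idx[n_train + seq_len(n_test)], ]
    } else {
      subs <- df |> dplyr::distinct(.data$group, .data$subject)
      subs <- subs[sample.int(nrow(subs)), ]
      counts <- vapply(subs$subject,
                       function(s) sum(df$subject == s), integer(1))
      take <- cumsum(counts) < n_train
      take[which(!take)[1]] <- TRUE  # cross the boundary with a whole subject
      train_subs <- subs$subject[take]
      train <- df[df$subject %in% train_subs, ]
      rest <- df[!df$subject %in% train_subs, ]
      test <- rest[sample.int(nrow(rest), min(n_test, nrow(rest))), ]
    }
    list(train = train, test = test)
  })
}

#' Train and evaluate the perfusion classifier (command entry point)
#'
#' From a per-trial index table: builds the five-index feature vectors,
#' splits the good (Group I) and poor (Group IV) perfusion trials into
#' training and test sets, fits the RBF network at the configured
#' operating point, and reports the test confusion matrix and metrics
#' plus the mean fuzzy output per group for all four groups.
#'
#' @param index_table Long index table from [process_cohort()] /
#'   [run_process()].
#' @param config A config list.
#' @param seed Integer seed (overrides `config$seed`).
#' @return List of class `perf_eval`: `model`, `split`, `confusion`,
#'   `metrics`, `group_outputs`, `test_predictions`.
#' @export
run_train_eval <- function(index_table, config = default_config(),
                           seed = NULL) {
  seed <- seed %||% config$seed
  feats <- build_features(index_table)
  sp <- split_trials(feats, n_train = config$split$n_train,
                     n_test = config$split$n_test,
                     policy = config$split$policy, seed = seed)
  rb <- config$rbfnn
  model <- rbf_fit(sp$train, outcome = "label",
                   n_hidden = rb$n_hidden, threshold = rb$threshold,
                   mu = rb$mu, epochs = rb$epochs, eps = rb$eps,
                   seed = seed)
  pred_class <- predict(model, sp$test, type = "class")
  cm <- confusion_matrix(sp$test$label, pred_class)
  outputs <- feats |>
    dplyr::mutate(output = predict(model, feats)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_output = mean(.data$output),
                     sd_output = sd(.data$output), n = dplyr::n())
  structure(
    list(model = model, split = sp, confusion = cm,
         metrics = perf_metrics(cm), group_outputs = outputs,
         test_predictions = tibble(truth = sp$test$label,
                                   predicted = pred_class,
                                   output = predict(model, sp$test))),
    class = "perf_eval"
  )
}

#' @export
print.perf_eval <- function(x, ...) {
  cat("<perf_eval> test confusion (positive = good perfusion):\n")
  print(x$confusion)
  cat("metrics (%):\n")
  print(round(x$metrics, 2))
  cat("mean RBFNN output by group:\n")
  print(x$group_outputs)
  invisible(x)
}

#' Decision-threshold sweep
#'
#' Re-applies a fitted model's fuzzy outputs at a grid of thresholds and
#' tabulates the resulting test metrics, exposing the trade-off the
#' operating threshold was chosen on.
#'
#' @param eval_result A [run_train_eval()] result.
#' @param thresholds Numeric grid in \[0, 1\].
#' @return Tibble: one row per threshold with confusion counts and metrics.
#' @export
threshold_sweep <- function(eval_result,
                            thresholds = seq(0, 1, by = 0.05)) {
  preds <- eval_result$test_predictions
  purrr::map(thresholds, function(th) {
    lab <- ifelse(preds$output >= th, "poor", "good")
    cm <- confusion_matrix(preds$truth, lab)
    dplyr::bind_cols(tibble(threshold = th), cm, perf_metrics(cm))
  }) |> dplyr::bind_rows()
}
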