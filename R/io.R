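#' Write / read a hemodynamic recording as a wide CSV table
#'
#' The on-disk dialect is a UTF-8 CSV with a header row, a time column `t`
#' (seconds) and one column per channel and chromophore named `ch01_hbo`,
#' ..., `ch15_hbo`, `ch01_hbr`, ..., `ch15_hbr`.
#'
#' @param ts A [hemo_ts()].
#' @param path File path.
#' @return `write_recording` returns `path` invisibly.
#' @export
write_recording <- function(ts, path) {
  assert_that(inherits(ts, "hemo_ts"), "ts must be a hemo_ts")
  nch <- nrow(ts$hbo)
  df <- data.frame(t = ts$t)
  for (ch in seq_len(nch)) df[[sprintf("ch%02d_hbo", ch)]] <- ts$hbo[ch, ]
  for (ch in seq_len(nch)) df[[sprintf("ch%02d_hbr", ch)]] <- ts$hbr[ch, ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param format Input format; only `"csv_wide"` is supported on disk
#'   (SNIRF/HDF5 containers are not handled by this reader).
#' @param layout A [channel_layout()] the file is validated against: channel
#'   count and sampling rate must match.
#' @return `read_recording` returns a [hemo_ts()].
#' @export
read_recording <- function(path, format = c("csv_wide", "snirf"),
                           layout = channel_layout()) {
  format <- match.arg(format)
  if (format == "snirf") {
    stop_nirslat("SNIRF input is not supported by this reader; export the recording as a wide CSV (columns t, ch01_hbo, ..., ch15_hbr)",
                 "nirslat_validation_error")
  }
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  assert_that("t" %in% names(df), "missing time column 't'")
  hbo_cols <- grep("^ch[0-9]+_hbo$", names(df), value = TRUE)
  hbr_cols <- grep("^ch[0-9]+_hbr$", names(df), value = TRUE)
  assert_that(length(hbo_cols) == length(hbr_cols) && length(hbo_cols) > 0,
              "expected matched chXX_hbo / chXX_hbr column pairs")
  if (length(hbo_cols) != layout$n_channels) {
    stop_nirslat(sprintf(
      "channel-count mismatch: file has %d channels, layout expects %d",
      length(hbo_cols), layout$n_channels), "nirslat_validation_error")
  }
  fs <- 1 / stats::median(diff(df$t))
  assert_that(abs(fs - layout$fs_hz) < 1e-3 * layout$fs_hz,
              sprintf("sampling rate %.4f Hz does not match layout fs %.4f Hz",
                      fs, layout$fs_hz))
  hemo_ts(t(as.matrix(df[hbo_cols])), t(as.matrix(df[hbr_cols])),
          layout$fs_hz, df$t)
}

#' Write a cohort table as CSV
#' @param cohort A [sample_cohort()] data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Default end-to-end pipeline configuration
#'
#' Collects every tunable parameter of the analysis in one validated list:
#' filter band/order/ripple, epoch window and baseline, channel layout,
#' Beer-Lambert constants, laterality aggregation, sAA thresholds, cohort
#' size and noise amplitudes.
#'
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    filter = list(low_hz = 0.01, high_hz = 0.02, order = 6L, ripple_db = 0.5),
    epoch = list(window = c(-1, 60), baseline = c(-1, 0)),
    lis = list(aggregation_mode = "max", interval = c(0, 60)),
    mbll = list(dpf = 6),
    saa = list(control_max = 28, stress_min = 33, distress_min = 44),
    cohort = list(n_per_group = 11L, gain_jitter_sd = 0.10),
    seed = 0L
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields present in the file override the defaults; everything else keeps
#' its [default_config()] value.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  config <- default_config()
  for (section in names(raw)) {
    if (is.list(raw[[section]]) && is.list(config[[section]])) {
      for (field in names(raw[[section]])) {
        config[[section]][[field]] <- raw[[section]][[field]]
      }
    } else {
      config[[section]] <- raw[[section]]
    }
  }
  validate_config(config)
}

#' Validate a pipeline configuration
#'
#' Checks every constraint the consuming stages rely on before any stage
#' runs: filter band inside (0, fs/2), positive epoch window, known
#' aggregation mode, ordered sAA thresholds, cohort size.
#'
#' @param config A `pipeline_config` list.
#' @param layout The [channel_layout()] the run will use.
#' @return `config`, invisibly classed, or an error naming the first
#'   violated constraint.
#' @export
validate_config <- function(config, layout = channel_layout()) {
  f <- config$filter
  assert_that(f$low_hz > 0 && f$low_hz < f$high_hz,
              "filter: need 0 < low_hz < high_hz")
  assert_that(f$high_hz < layout$fs_hz / 2,
              sprintf("filter: high_hz must be below fs/2 = %g Hz",
                      layout$fs_hz / 2))
  assert_that(f$order >= 1 && f$ripple_db > 0,
              "filter: order >= 1 and ripple_db > 0 required")
  w <- config$epoch$window
  assert_that(length(w) == 2 && w[1] < 0 && w[2] > 0,
              "epoch: window must bracket the onset")
  assert_that(config$lis$aggregation_mode %in% c("max", "mean"),
              "lis: aggregation_mode must be 'max' or 'mean'")
  s <- config$saa
  assert_that(s$control_max < s$stress_min && s$stress_min < s$distress_min,
              "saa: thresholds must be ordered control_max < stress_min < distress_min")
  assert_that(config$cohort$n_per_group >= 1, "cohort: n_per_group >= 1")
  class(config) <- "pipeline_config"
  invisible(config)
}

# Preprocess one recording: band-pass -> epoch -> baseline correction.
preprocess_recording <- function(ts, onsets, config) {
  filtered <- bandpass(ts, config$filter$low_hz, config$filter$high_hz,
                       config$filter$order, config$filter$ripple_db)
  baseline_correct(epoch(filtered, onsets, config$epoch$window))
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Samples a cohort, builds both session schedules, simulates every
#' participant's recordings, preprocesses them (band-pass filter, epoching,
#' baseline correction), computes the laterality table per group and session
#' for the three-group and the pooled two-group analyses, and runs the
#' accompanying statistics (two-group t-test and three-group ANOVA + Dunnett
#' T3 on sAA, Pearson correlations of sAA with the behavioural covariates).
#' Deterministic given `config$seed`.
#'
#' @param config A `pipeline_config`, see [default_config()].
#' @param params A [sim_params()] controlling response and noise amplitudes.
#' @param cohort_params Group parameter table, see [cohort_parameters()];
#'   override to change group gains or covariate distributions.
#' @param layout A [channel_layout()].
#' @param out_dir Optional output directory; when given, writes
#'   `cohort.csv`, `lis_three_group.csv`, `lis_two_group.csv`,
#'   `stats.json` and `manifest.json` there.
#' @return List with `cohort`, `lis_three_group`, `lis_two_group` (both in
#'   the configured aggregation mode), `stats`, and `manifest`.
#' @export
run_pipeline <- function(config = default_config(), params = sim_params(),
                         cohort_params = cohort_parameters(),
                         layout = channel_layout(), out_dir = NULL) {
  validate_config(config, layout)
  seed <- config$seed
  cohort <- sample_cohort(config$cohort$n_per_group, seed = seed,
                          params = cohort_params,
                          gain_jitter_sd = config$cohort$gain_jitter_sd)
  schedules <- list(`1` = build_session_schedule(1, seed),
                    `2` = build_session_schedule(2, seed + 1L))
  onsets <- lapply(schedules, trial_onsets)

  epoch_table <- list()
  for (i in seq_len(nrow(cohort))) {
    for (ses in 1:2) {
      ts <- simulate_hemodynamics(
        schedules[[ses]], cohort[i, ], params, layout,
        seed = seed + 1000L * ses + i)
      epoch_table[[length(epoch_table) + 1L]] <- list(
        id = cohort$id[i],
        group = cohort$true_group[i],
        session = ses,
        epochs = preprocess_recording(ts, onsets[[ses]], config))
    }
  }

  mode <- config$lis$aggregation_mode
  interval <- config$lis$interval
  lis3 <- lis_by_group_session(epoch_table, layout, interval, mode)
  two_table <- lapply(epoch_table, function(e) {
    e$group <- if (e$group == "control") "control" else "stress"
    e
  })
  lis2 <- lis_by_group_session(two_table, layout, interval, mode)

  two_group <- ifelse(cohort$true_group == "control", "control", "stress")
  stats_out <- list(
    saa_two_group = compare_two_groups(cohort$saa_kul, two_group),
    saa_three_group = compare_three_groups(cohort$saa_kul, cohort$true_group),
    cor_saa_accuracy = correlate(cohort$saa_kul, cohort$accuracy_pct),
    cor_saa_rt = correlate(cohort$saa_kul, cohort$rt_ms),
    cor_saa_bpm = correlate(cohort$saa_kul, cohort$bpm)
  )

  manifest <- list(
    package = "nirslat",
    version = as.character(packageVersion("nirslat")),
    r_version = as.character(getRversion()),
    seed = seed,
    config = unclass(config),
    n_participants = nrow(cohort),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  result <- list(cohort = cohort, lis_three_group = lis3,
                 lis_two_group = lis2, stats = stats_out,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    write_lis_table(lis3, file.path(out_dir, "lis_three_group.csv"))
    write_lis_table(lis2, file.path(out_dir, "lis_two_group.csv"))
    jsonlite::write_json(
      lapply(stats_out, function(s) if (inherits(s, "test_report")) unclass(s) else s),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
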