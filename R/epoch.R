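#' Segment a hemodynamic time series into task-locked epochs
#'
#' Extracts one window per task onset covering \[-1, 60\] s relative to the
#' onset. Sample indexing: the t = 0 sample of an epoch is `floor(onset * fs)`
#' (0-based); the window runs from `floor(fs)` samples before it to
#' `floor(60 * fs)` samples after it, both inclusive, which at 8.138 Hz is
#' 8 + 488 + 1 = 497 samples (`floor(61 * fs) + 1`).
#'
#' @param ts A [hemo_ts()].
#' @param onsets Task onsets in seconds (e.g. from [trial_onsets()]).
#' @param window Epoch window in seconds relative to onset.
#' @return An `epoch_set`: list with arrays `hbo`, `hbr`
#'   (trials x channels x samples), the relative time axis `t_rel`,
#'   `onset_index` (1-based sample of t = 0 within the window),
#'   `baseline_window`, `fs`, and a `baseline_corrected` flag.
#' @export
epoch <- function(ts, onsets, window = c(-1, 60)) {
  assert_that(inherits(ts, "hemo_ts"), "ts must be a hemo_ts")
  assert_that(length(window) == 2 && window[1] < 0 && window[2] > 0,
              "window must bracket the onset, e.g. c(-1, 60)")
  fs <- ts$fs
  n <- ncol(ts$hbo)
  n_pre <- floor(-window[1] * fs)
  n_post <- floor(window[2] * fs)
  len <- n_pre + n_post + 1L
  i0 <- floor(onsets * fs)  # 0-based
  bad <- which(i0 - n_pre < 0 | i0 + n_post > n - 1)
  if (length(bad)) {
    stop_nirslat(sprintf(
      "epoch window out of range for trial(s) %s (onset %s s)",
      paste(bad, collapse = ", "),
      paste(signif(onsets[bad], 6), collapse = ", ")),
      "nirslat_validation_error")
  }
  nch <- nrow(ts$hbo)
  hbo <- array(0, dim = c(length(onsets), nch, len))
  hbr <- array(0, dim = c(length(onsets), nch, len))
  for (tr in seq_along(onsets)) {
    idx <- (i0[tr] - n_pre):(i0[tr] + n_post) + 1L
    hbo[tr, , ] <- ts$hbo[, idx]
    hbr[tr, , ] <- ts$hbr[, idx]
  }
  structure(list(
    hbo = hbo, hbr = hbr,
    t_rel = ((-n_pre):n_post) / fs,
    onset_index = n_pre + 1L,
    baseline_window = c(window[1], 0),
    fs = fs,
    baseline_corrected = FALSE
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$hbo)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples [%g, %g] s%s\n",
              d[1], d[2], d[3], x$t_rel[1], x$t_rel[length(x$t_rel)],
              if (isTRUE(x$baseline_corrected)) ", baseline-corrected" else ""))
  invisible(x)
}

#' Baseline-correct an epoch set
#'
#' Per trial and channel, subtracts the mean over the pre-onset reference
#' interval \[-1, 0) s (half-open: the t = 0 sample belongs to the task).
#' After correction the baseline mean is zero to machine precision.
#'
#' @param ep An `epoch_set` that has not been corrected yet.
#' @return The corrected `epoch_set` with `baseline_corrected = TRUE`.
#' @export
baseline_correct <- function(ep) {
  assert_that(inherits(ep, "epoch_set"), "ep must be an epoch_set")
  if (isTRUE(ep$baseline_corrected)) {
    stop_nirslat("epoch set is already baseline-corrected",
                 "nirslat_validation_error")
  }
  base_idx <- seq_len(ep$onset_index - 1L)
  for (field in c("hbo", "hbr")) {
    a <- ep[[field]]
    bl <- rowMeans(a[, , base_idx, drop = FALSE], dims = 2)
    ep[[field]] <- a - array(bl, dim = dim(a))  # recycles over samples
  }
  ep$baseline_corrected <- TRUE
  ep
}

#' Grand-average epochs over trials, then participants
#'
#' @param eps A single `epoch_set` or a list of them (one per participant),
#'   all with identical dimensions.
#' @param chromophore `"hbo"` or `"hbr"`.
#' @return Channels x samples matrix: the mean over trials within each
#'   participant, then the mean of those means over participants.
#' @export
grand_average <- function(eps, chromophore = c("hbo", "hbr")) {
  chromophore <- match.arg(chromophore)
  if (inherits(eps, "epoch_set")) eps <- list(eps)
  assert_that(length(eps) >= 1 && all(vapply(eps, inherits, TRUE, "epoch_set")),
              "eps must be an epoch_set or list of epoch_sets")
  dims <- lapply(eps, function(e) dim(e[[chromophore]])[2:3])
  assert_that(length(unique(vapply(dims, paste, "", collapse = "x"))) == 1,
              "all epoch sets must have identical channel/sample dimensions")
  per_part <- lapply(eps, function(e) colMeans(e[[chromophore]]))
  Reduce(`+`, per_part) / length(per_part)
}

#' Per-channel temporal mean over a task interval
#'
#' Averages the (baseline-corrected) signal over trials and over the task
#' interval, by default onset (0 s) to termination (60 s), giving one scalar
#' per channel.
#'
#' @param ep A baseline-corrected `epoch_set`.
#' @param interval Two-element interval in seconds within the epoch window.
#' @param chromophore `"hbo"` or `"hbr"`.
#' @return Numeric vector, one value per channel.
#' @export
temporal_mean <- function(ep, interval = c(0, 60),
                          chromophore = c("hbo", "hbr")) {
  chromophore <- match.arg(chromophore)
  assert_that(inherits(ep, "epoch_set"), "ep must be an epoch_set")
  assert_that(isTRUE(ep$baseline_corrected),
              "temporal_mean expects a baseline-corrected epoch_set")
  tr <- ep$t_rel
  # the discrete window ends up to one sample short of the nominal bounds
  slack <- 1 / ep$fs
  assert_that(interval[1] >= tr[1] - slack &&
                interval[2] <= tr[length(tr)] + slack,
              sprintf("interval [%g, %g] s outside epoch window [%g, %g] s",
                      interval[1], interval[2], tr[1], tr[length(tr)]))
  idx <- which(tr >= interval[1] - 1e-9 & tr <= interval[2] + 1e-9)
  apply(ep[[chromophore]][, , idx, drop = FALSE], 2, mean)
}
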