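#' Group parameters of the synthetic cohort
#'
#' Salivary alpha-amylase (sAA) distributions per group (mean and SD in KU/L,
#' truncated to the group's defining interval), default right-hemisphere
#' amplitude gains, and behavioural covariate distributions. The sAA
#' means/SDs and accuracy means/SDs are the reported cohort values; the
#' right-hemisphere gains are chosen so the noiseless pipeline lands at
#' laterality indices of about 0.09 (control), 0.25 (eustress) and 0.004
#' (distress) via the closed form `LIS = (g - 1)/(g + 1)`.
#'
#' @return Data frame keyed by `group` with columns `saa_mean`, `saa_sd`,
#'   `saa_lo`, `saa_hi`, `right_gain`, `acc_mean`, `acc_sd`, `rt_mean`,
#'   `rt_sd`, `bpm_mean`, `bpm_sd`.
#' @export
cohort_parameters <- function() {
  data.frame(
    group = c("control", "eustress", "distress"),
    saa_mean = c(12.73, 37.82, 61.82),
    saa_sd = c(9.76, 3.49, 18.07),
    saa_lo = c(0, 33, 44),
    saa_hi = c(28, 44, Inf),
    right_gain = c(1.20, 1.67, 1.008),
    acc_mean = c(95.5, 96.9, 95.8),
    acc_sd = c(3.4, 0.8, 2.0),
    rt_mean = c(640, 605, 685),   # inverted-U: eustress fastest, distress slowest
    rt_sd = c(50, 40, 60),
    bpm_mean = c(19.7, 16.1, 14.8),
    bpm_sd = c(4.5, 15.1, 4.2)
  )
}

# Truncated-normal sampling by resampling until inside (lo, hi), open at both
# ends so classification by the strict sAA thresholds is exact.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw > lo & draw < hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Sample a synthetic cohort
#'
#' Draws `n_per_group` participants per group (control, eustress, distress).
#' sAA values follow per-group truncated normal distributions confined to the
#' group-defining intervals (control < 28, eustress 33-44, distress > 44
#' KU/L), so [classify_by_saa()] recovers `true_group` exactly. Each
#' participant receives a right-hemisphere gain equal to the group default
#' times a log-normal jitter (`exp(N(0, gain_jitter_sd))`) representing
#' between-subject variability in lateralization, plus behavioural
#' covariates (accuracy, reaction time, breaths per minute).
#'
#' @param n_per_group Participants per group, at least 1.
#' @param seed Integer seed; the draw is reproducible bit-for-bit.
#' @param params Group parameter table, see [cohort_parameters()].
#' @param gain_jitter_sd SD of the log-normal right-gain jitter
#'   (0 gives every participant the exact group gain).
#' @return Data frame of class `synthetic_cohort` with columns `id`,
#'   `saa_kul`, `true_group`, `right_gain`, `accuracy_pct`, `rt_ms`, `bpm`.
#' @export
#' @examples
#' cohort <- sample_cohort(11, seed = 1)
#' table(cohort$true_group)
sample_cohort <- function(n_per_group, seed = 0L,
                          params = cohort_parameters(),
                          gain_jitter_sd = 0.10) {
  assert_that(is_scalar_number(n_per_group) && n_per_group >= 1,
              "n_per_group must be at least 1")
  n_per_group <- as.integer(n_per_group)
  withr_seed(seed, {
    rows <- lapply(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      data.frame(
        id = sprintf("%s%02d", substr(p$group, 1, 1), seq_len(n_per_group)),
        saa_kul = rtrunc_norm(n_per_group, p$saa_mean, p$saa_sd,
                              p$saa_lo, p$saa_hi),
        true_group = p$group,
        right_gain = p$right_gain *
          exp(rnorm(n_per_group, 0, gain_jitter_sd)),
        accuracy_pct = pmin(100, pmax(0, rnorm(n_per_group, p$acc_mean,
                                               p$acc_sd))),
        rt_ms = pmax(150, rnorm(n_per_group, p$rt_mean, p$rt_sd)),
        bpm = rtrunc_norm(n_per_group, p$bpm_mean, p$bpm_sd, 0, Inf)
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, seed = as.integer(seed),
              class = c("synthetic_cohort", "data.frame"))
  })
}

#' Simulation parameters for synthetic hemodynamics
#'
#' The event-related response is a canonical double-gamma hemodynamic
#' response function (peak ~6 s, undershoot ~16 s, undershoot ratio 1/6)
#' convolved with the boxcar of target-stimulation periods. Physiological
#' nuisance terms are a slow drift, Mayer waves (~0.1 Hz), respiration
#' (~0.25 Hz) and the cardiac pulse (~1.1 Hz; aliasing at fs = 8.138 Hz is
#' accepted as realistic), plus white measurement noise. Amplitudes are in
#' the same (arbitrary, uM-scaled) concentration units as the response;
#' laterality indices are invariant to the overall scale.
#'
#' @param response_amplitude Peak amplitude of the clean dHbO response.
#' @param hrf_peak_s,hrf_undershoot_s,hrf_undershoot_ratio Double-gamma
#'   shape parameters (seconds, seconds, dimensionless).
#' @param hbr_ratio dHbR = `hbr_ratio` x the noiseless dHbO component
#'   (negative: deoxyhemoglobin mirrors oxyhemoglobin).
#' @param drift_amp,mayer_amp,resp_amp,cardiac_amp,white_sd Noise amplitudes.
#' @param fs Sampling rate in Hz.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(response_amplitude = 1,
                       hrf_peak_s = 6, hrf_undershoot_s = 16,
                       hrf_undershoot_ratio = 1 / 6,
                       hbr_ratio = -1 / 3,
                       drift_amp = 0.5, mayer_amp = 0.3, resp_amp = 0.2,
                       cardiac_amp = 0.1, white_sd = 0.3,
                       fs = 8.138) {
  amps <- c(drift_amp, mayer_amp, resp_amp, cardiac_amp, white_sd)
  assert_that(all(amps >= 0), "noise amplitudes must be non-negative")
  assert_that(hbr_ratio < 0, "hbr_ratio must be negative")
  assert_that(is_scalar_number(fs) && fs > 0, "fs must be positive")
  structure(list(
    response_amplitude = response_amplitude,
    hrf_peak_s = hrf_peak_s, hrf_undershoot_s = hrf_undershoot_s,
    hrf_undershoot_ratio = hrf_undershoot_ratio,
    hbr_ratio = hbr_ratio,
    drift_amp = drift_amp, mayer_amp = mayer_amp, resp_amp = resp_amp,
    cardiac_amp = cardiac_amp, white_sd = white_sd, fs = fs
  ), class = "sim_params")
}

#' Canonical double-gamma hemodynamic response function
#'
#' @param t Time in seconds (non-negative).
#' @param peak_s Time-to-peak of the positive lobe.
#' @param undershoot_s Time-to-peak of the undershoot.
#' @param undershoot_ratio Undershoot amplitude relative to the peak.
#' @return HRF samples, normalized to a maximum of 1.
#' @export
double_gamma_hrf <- function(t, peak_s = 6, undershoot_s = 16,
                             undershoot_ratio = 1 / 6) {
  shape1 <- peak_s; shape2 <- undershoot_s  # gamma shapes with unit rate
  h <- stats::dgamma(t, shape = shape1, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = shape2, rate = 1)
  h / max(h)
}

# Boxcar of target-stimulation periods sampled at fs over the session span.
stimulus_vector <- function(schedule, fs) {
  n <- floor(schedule_span(schedule) * fs) + 1L
  s <- numeric(n)
  tgt <- schedule[schedule$kind == "target", ]
  for (i in seq_len(nrow(tgt))) {
    a <- floor(tgt$onset[i] * fs) + 1L
    b <- min(n, floor((tgt$onset[i] + tgt$duration[i]) * fs) + 1L)
    s[a:b] <- 1
  }
  s
}

#' Simulate a lateralized event-related fNIRS recording
#'
#' Generates the per-channel dHbO/dHbR time series of one participant for
#' one session. The clean dHbO response is the target-period boxcar convolved
#' with the double-gamma HRF, normalized to peak 1, times
#' `response_amplitude`, times the participant's `right_gain` on
#' right-hemisphere channels (1.0 on the left, the mean of both on the
#' midline). dHbR is `hbr_ratio` times the noiseless dHbO component. Both
#' chromophores receive independent drift, sinusoidal physiological
#' oscillations with random per-channel phases, and white noise.
#'
#' @param schedule A `stim_schedule` from [build_session_schedule()].
#' @param participant One row of a [sample_cohort()] data frame (or any list
#'   with a `right_gain` field).
#' @param params A [sim_params()].
#' @param layout A [channel_layout()].
#' @param seed Integer seed for the noise draws.
#' @return A [hemo_ts()] spanning the schedule at `params$fs`.
#' @export
simulate_hemodynamics <- function(schedule, participant,
                                  params = sim_params(),
                                  layout = channel_layout(),
                                  seed = 0L) {
  assert_that(inherits(schedule, "stim_schedule") && nrow(schedule) > 0,
              "schedule must be a non-empty stim_schedule")
  g <- participant$right_gain
  assert_that(is_scalar_number(g) && g > 0, "right_gain must be positive")
  fs <- params$fs
  stim <- stimulus_vector(schedule, fs)
  n <- length(stim)
  hrf <- double_gamma_hrf(seq(0, 32, by = 1 / fs), params$hrf_peak_s,
                          params$hrf_undershoot_s,
                          params$hrf_undershoot_ratio)
  shape <- stats::convolve(stim, rev(hrf), type = "open")[seq_len(n)]
  peak <- max(abs(shape))
  if (peak > 0) shape <- shape / peak
  shape <- shape * params$response_amplitude

  gains <- numeric(layout$n_channels)
  gains[layout$right_channels] <- g
  gains[layout$left_channels] <- 1
  gains[layout$midline_channels] <- (g + 1) / 2

  tt <- (seq_len(n) - 1) / fs
  withr_seed(seed, {
    freqs <- c(drift = 0.002, mayer = 0.1, resp = 0.25, cardiac = 1.1)
    amps <- c(params$drift_amp, params$mayer_amp, params$resp_amp,
              params$cardiac_amp)
    sin_base <- vapply(freqs, function(f) sin(2 * pi * f * tt), numeric(n))
    cos_base <- vapply(freqs, function(f) cos(2 * pi * f * tt), numeric(n))
    noise_block <- function() {
      # random phase per channel and oscillation:
      # a*sin(wt + ph) = a*cos(ph)*sin(wt) + a*sin(ph)*cos(wt)
      ph <- matrix(runif(layout$n_channels * length(freqs), 0, 2 * pi),
                   layout$n_channels)
      m <- (t(amps * cos(t(ph))) %*% t(sin_base)) +
        (t(amps * sin(t(ph))) %*% t(cos_base))
      if (params$white_sd > 0) {
        m <- m + matrix(rnorm(length(m), 0, params$white_sd), nrow(m))
      }
      m
    }
    clean <- outer(gains, shape)
    hbo <- clean + noise_block()
    hbr <- params$hbr_ratio * clean + noise_block()
    hemo_ts(hbo, hbr, fs)
  })
}
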