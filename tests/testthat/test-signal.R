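lay <- channel_layout()

test_that("Beer-Lambert inversion recovers concentrations from optical densities", {
  n <- 200
  set.seed(1)
  hemo <- hemo_ts(matrix(rnorm(15 * n), 15), matrix(rnorm(15 * n), 15),
                  lay$fs_hz)
  back <- mbll_inverse(forward_mbll(hemo, lay), lay)
  expect_lt(max(abs(back$hbo - hemo$hbo)) / max(abs(hemo$hbo)), 1e-9)
  expect_lt(max(abs(back$hbr - hemo$hbr)) / max(abs(hemo$hbr)), 1e-9)
  # zero optical density maps to zero concentration
  zero <- optical_recording(array(0, c(15, 2, n)), lay$wavelengths_nm, lay$fs_hz)
  expect_true(all(mbll_inverse(zero, lay)$hbo == 0))
})

test_that("a duplicated wavelength makes the extinction system singular", {
  rec <- optical_recording(array(0, c(15, 2, 10)), c(780, 780), lay$fs_hz)
  expect_error(mbll_inverse(rec, lay), "780",
               class = "nirslat_numeric_error")
})

test_that("band-pass design matches an independent Chebyshev implementation", {
  # wide, well-conditioned band where the transfer-function form is stable
  bt <- signal::cheby1(4, 0.5, c(0.5, 1.5) * 2 / lay$fs_hz, type = "pass")
  sos <- design_cheby_bandpass(4, 0.5, 0.5, 1.5, lay$fs_hz)
  f <- seq(0.05, 3.5, by = 0.05)
  z <- exp(2i * pi * f / lay$fs_hz)
  evalp <- function(coef) Reduce(`+`, lapply(seq_along(coef),
                                             function(i) coef[i] * z^-(i - 1)))
  h_ref <- abs(evalp(bt$b) / evalp(bt$a))
  expect_equal(abs(sos_freq_response(sos, f, lay$fs_hz)), h_ref,
               tolerance = 1e-9)
})

make_tone <- function(freq, fs = lay$fs_hz, span = 1220, nch = 2) {
  tt <- seq(0, span, by = 1 / fs)
  hemo_ts(matrix(rep(sin(2 * pi * freq * tt), each = nch), nch),
          matrix(0, nch, length(tt)), fs)
}

central_amplitude <- function(x, freq, fs) {
  n <- length(x)
  mid <- x[floor(n / 4):ceiling(3 * n / 4)]
  tt <- (seq_along(mid) - 1) / fs
  2 * Mod(mean(mid * exp(-2i * pi * freq * tt)))
}

test_that("the default filter preserves in-band tones and matches its own response", {
  out <- bandpass(make_tone(0.015), chromophores = "hbo")
  amp <- central_amplitude(out$hbo[1, ], 0.015, lay$fs_hz)
  expect_gt(amp, 0.95)
  expect_lt(amp, 1.05)
  sos <- design_cheby_bandpass(6, 0.5, 0.01, 0.02, lay$fs_hz)
  predicted <- Mod(sos_freq_response(sos, 0.015, lay$fs_hz))^2
  expect_equal(amp, predicted, tolerance = 0.01)
})

test_that("out-of-band tones are strongly attenuated and DC is removed", {
  out <- bandpass(make_tone(0.2), chromophores = "hbo")
  amp <- central_amplitude(out$hbo[1, ], 0.2, lay$fs_hz)
  expect_lt(20 * log10(amp), -20)
  dc <- hemo_ts(matrix(1, 2, 9929), matrix(0, 2, 9929), lay$fs_hz)
  out_dc <- bandpass(dc, chromophores = "hbo")
  n <- ncol(out_dc$hbo)
  expect_lt(max(abs(out_dc$hbo[1, floor(n / 4):ceiling(3 * n / 4)])), 1e-3)
})

test_that("zero-phase filtering is linear and preserves symmetric peak latency", {
  set.seed(2)
  n <- 4000
  x <- hemo_ts(matrix(rnorm(2 * n), 2), matrix(0, 2, n), lay$fs_hz)
  y <- hemo_ts(matrix(rnorm(2 * n), 2), matrix(0, 2, n), lay$fs_hz)
  mix <- hemo_ts(2 * x$hbo - 3 * y$hbo, matrix(0, 2, n), lay$fs_hz)
  bx <- bandpass(x, chromophores = "hbo")$hbo
  by <- bandpass(y, chromophores = "hbo")$hbo
  bmix <- bandpass(mix, chromophores = "hbo")$hbo
  expect_equal(bmix, 2 * bx - 3 * by, tolerance = 1e-9)

  # symmetric bump about the record midpoint stays centred after filtering
  tt <- (seq_len(9929) - 1) / lay$fs_hz
  centre <- tt[length(tt)] / 2
  bump <- exp(-(tt - centre)^2 / (2 * 30^2))
  ts <- hemo_ts(rbind(bump, bump), matrix(0, 2, length(tt)), lay$fs_hz)
  out <- bandpass(ts, chromophores = "hbo")
  peak_in <- which.max(bump)
  peak_out <- which.max(abs(out$hbo[1, ]))
  expect_lte(abs(peak_out - peak_in), 1)
})

test_that("filter rejects invalid bands and too-short signals", {
  ts <- hemo_ts(matrix(rnorm(2 * 1000), 2), matrix(0, 2, 1000), lay$fs_hz)
  expect_error(bandpass(ts, low_hz = 0.01, high_hz = 5),
               "fs/2", class = "nirslat_validation_error")
  short <- hemo_ts(matrix(rnorm(2 * 10), 2), matrix(0, 2, 10), lay$fs_hz)
  expect_error(bandpass(short), "short", class = "nirslat_validation_error")
})

test_that("epoching uses the fixed [-1, 60] s window convention", {
  sched <- build_session_schedule(1, 0)
  onsets <- trial_onsets(sched)
  ts <- simulate_hemodynamics(sched, participant_with_gain(1),
                              noiseless_params(), seed = 0)
  ep <- epoch(ts, onsets)
  expect_equal(dim(ep$hbo), c(20, 15, floor(61 * lay$fs_hz) + 1))
  expect_equal(dim(ep$hbo)[3], 497)
  expect_equal(ep$t_rel[ep$onset_index], 0)
  expect_error(epoch(ts, c(0.5, onsets[-1])), "trial",
               class = "nirslat_validation_error")
  expect_error(epoch(ts, c(onsets[-20], 1219)), "1219",
               class = "nirslat_validation_error")
})

test_that("baseline correction zeroes the reference interval once only", {
  sched <- build_session_schedule(1, 0)
  ts <- simulate_hemodynamics(sched, participant_with_gain(1.3), sim_params(),
                              seed = 5)
  ep <- baseline_correct(epoch(ts, trial_onsets(sched)))
  base_idx <- seq_len(ep$onset_index - 1)
  bl_means <- rowMeans(ep$hbo[, , base_idx, drop = FALSE], dims = 2)
  expect_lt(max(abs(bl_means)), 1e-12)
  expect_error(baseline_correct(ep), "already",
               class = "nirslat_validation_error")

  # constant epochs become identically zero
  const_ep <- manual_epoch_set(array(7, c(3, 2, 497)))
  expect_true(all(baseline_correct(const_ep)$hbo == 0))
})

test_that("a ramp epoch has the mean of its baseline samples subtracted", {
  fs <- lay$fs_hz
  n <- floor(1220 * fs) + 1
  tt <- (seq_len(n) - 1) / fs
  ts <- hemo_ts(matrix(tt, 1), matrix(0, 1, n), fs)
  onset <- 10
  ep <- baseline_correct(epoch(ts, onset))
  # the subtracted constant is the mean over samples in [-1, 0) s
  i0 <- floor(onset * fs)
  expected_bl <- mean(tt[(i0 - 8):(i0 - 1) + 1])
  expect_equal(ep$hbo[1, 1, ep$onset_index], tt[i0 + 1] - expected_bl)
  expect_equal(expected_bl - tt[i0 + 1], -0.553, tolerance = 0.01)
})

test_that("grand averaging pools trials then participants", {
  a <- manual_epoch_set(array(rnorm(2 * 3 * 10), c(2, 3, 10)))
  expect_equal(grand_average(a), colMeans(a$hbo))
  single <- manual_epoch_set(array(rnorm(1 * 3 * 10), c(1, 3, 10)))
  expect_equal(grand_average(single), single$hbo[1, , ])
  neg <- a; neg$hbo <- -a$hbo
  expect_true(all(grand_average(list(a, neg)) == 0))
  expect_equal(grand_average(list(a, a, a)), grand_average(a))
  b <- manual_epoch_set(array(0, c(2, 3, 11)))
  expect_error(grand_average(list(a, b)), "identical",
               class = "nirslat_validation_error")
})

test_that("temporal means average the task interval per channel", {
  # 1 on [0, 60], 0 before the onset
  n <- 497
  step <- array(0, c(4, 15, n))
  step[, , 9:n] <- 1
  ep <- manual_epoch_set(step, baseline_corrected = TRUE)
  expect_equal(temporal_mean(ep), rep(1, 15))
  expect_true(all(temporal_mean(manual_epoch_set(
    array(0, c(4, 15, n)), baseline_corrected = TRUE)) == 0))
  # full sine period over [0, 60] averages to ~0
  tr <- manual_epoch_set(array(0, c(1, 1, n)), baseline_corrected = TRUE)
  sine <- ifelse(tr$t_rel >= 0, sin(2 * pi * tr$t_rel / 60), 0)
  tr$hbo <- array(sine, c(1, 1, n))
  expect_lt(abs(temporal_mean(tr)), 0.02)
  expect_error(temporal_mean(ep, interval = c(0, 120)), "outside",
               class = "nirslat_validation_error")
})

test_that("noiseless grand-averaged responses peak after the task onset", {
  sched <- build_session_schedule(1, 0)
  ep <- preprocessed_epochs(sched, gain = 1.5)
  ga <- grand_average(ep)
  peak_sample <- which.max(abs(ga[1, ]))
  expect_gt(ep$t_rel[peak_sample], 0)
})
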