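#' Hemodynamic concentration-change time series
#'
#' Container for per-channel oxyhemoglobin (dHbO) and deoxyhemoglobin (dHbR)
#' concentration changes. Units are uM under the default differential
#' pathlength factor convention (with DPF = 1 the values read as uM*mm molar
#' absorbance-path products); every downstream laterality quantity is
#' invariant to this scale.
#'
#' @param hbo,hbr Numeric matrices, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param t Optional time axis in seconds; defaults to `(0:(n-1))/fs`.
#' @return An object of class `hemo_ts` with elements `hbo`, `hbr`, `fs`,
#'   `t`, and a `filtered` flag.
#' @export
hemo_ts <- function(hbo, hbr, fs, t = NULL) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  assert_that(all(dim(hbo) == dim(hbr)), "hbo and hbr dimensions must match")
  assert_that(all(is.finite(hbo)) && all(is.finite(hbr)),
              "hemodynamic series must be finite")
  assert_that(is_scalar_number(fs) && fs > 0, "fs must be positive")
  if (is.null(t)) t <- (seq_len(ncol(hbo)) - 1) / fs
  assert_that(length(t) == ncol(hbo), "time axis length must match samples")
  structure(list(hbo = hbo, hbr = hbr, fs = fs, t = t, filtered = FALSE),
            class = "hemo_ts")
}

#' @export
print.hemo_ts <- function(x, ...) {
  cat(sprintf("<hemo_ts> %d channels x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$hbo), ncol(x$hbo), x$fs, ncol(x$hbo) / x$fs,
              if (isTRUE(x$filtered)) ", band-pass filtered" else ""))
  invisible(x)
}

#' Total hemoglobin change
#' @param ts A `hemo_ts`.
#' @return Channels x samples matrix `dHbT = dHbO + dHbR`.
#' @export
hbt <- function(ts) ts$hbo + ts$hbr

#' Optical-density change recording
#'
#' @param dod Numeric array, channels x wavelengths x samples, of
#'   optical-density changes (dimensionless).
#' @param wavelengths_nm Wavelengths in nm matching the second dimension.
#' @param fs Sampling rate in Hz.
#' @return An object of class `optical_recording`.
#' @export
optical_recording <- function(dod, wavelengths_nm, fs) {
  assert_that(length(dim(dod)) == 3, "dod must be channels x wavelengths x samples")
  assert_that(dim(dod)[2] == length(wavelengths_nm),
              "second dimension must match the number of wavelengths")
  assert_that(all(is.finite(dod)), "optical densities must be finite")
  structure(list(dod = dod, wavelengths_nm = as.numeric(wavelengths_nm),
                 fs = fs, t = (seq_len(dim(dod)[3]) - 1) / fs),
            class = "optical_recording")
}

#' @export
print.optical_recording <- function(x, ...) {
  cat(sprintf("<optical_recording> %d channels x %d wavelengths (%s nm) x %d samples @ %g Hz\n",
              dim(x$dod)[1], dim(x$dod)[2],
              paste(x$wavelengths_nm, collapse = "/"), dim(x$dod)[3], x$fs))
  invisible(x)
}
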