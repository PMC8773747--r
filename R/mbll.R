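#' Hemoglobin molar extinction coefficients
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at the
#' wavelengths used by the recording system, in mM^-1 cm^-1, from the
#' standard Prahl / Cope-Delpy compilations. The table is an editable
#' configuration surface: pass a modified copy to [mbll_inverse()] or
#' [forward_mbll()] to use a different compilation.
#'
#' @return Data frame with columns `wavelength_nm`, `hbo`, `hbr`.
#' @export
#' @examples
#' extinction_coefficients()
extinction_coefficients <- function() {
  data.frame(
    wavelength_nm = c(780, 850),
    hbo = c(0.7354, 1.0580),
    hbr = c(1.1022, 0.6917)
  )
}

# 2x2 extinction system in uM^-1 mm^-1 including pathlength d*DPF(lambda).
# Rows are wavelengths, columns (hbo, hbr).
mbll_matrix <- function(wavelengths_nm, layout, dpf, extinction) {
  idx <- match(wavelengths_nm, extinction$wavelength_nm)
  if (anyNA(idx)) {
    stop_nirslat(sprintf(
      "no extinction coefficients for wavelength(s) %s nm",
      paste(wavelengths_nm[is.na(idx)], collapse = ", ")),
      "nirslat_validation_error")
  }
  dpf <- rep_len(dpf, length(wavelengths_nm))
  # mM^-1 cm^-1 -> uM^-1 mm^-1 is a factor 1e-4
  E <- cbind(extinction$hbo[idx], extinction$hbr[idx]) * 1e-4
  E * layout$source_detector_distance_mm * dpf
}

#' Convert optical-density changes to hemoglobin concentration changes
#'
#' Solves the modified Beer-Lambert law per channel and sample: the 2x2
#' linear system `dOD(lambda) = [e_HbO(lambda) dHbO + e_HbR(lambda) dHbR]
#' * d * DPF(lambda)` for `(dHbO, dHbR)`, with source-detector distance `d`
#' from the layout and per-wavelength differential pathlength factors.
#'
#' @param rec An [optical_recording()].
#' @param layout A [channel_layout()]; supplies `d` and validates channels.
#' @param dpf Differential pathlength factor(s), recycled per wavelength.
#' @param extinction Extinction table; see [extinction_coefficients()].
#' @return A [hemo_ts()] in uM (given the DPF convention).
#' @export
mbll_inverse <- function(rec, layout = channel_layout(), dpf = 6,
                         extinction = extinction_coefficients()) {
  assert_that(inherits(rec, "optical_recording"),
              "rec must be an optical_recording")
  wl <- rec$wavelengths_nm
  assert_that(length(wl) >= 2, "at least two wavelengths are required")
  E <- mbll_matrix(wl, layout, dpf, extinction)
  if (abs(det(E)) < 1e-12 * prod(sqrt(rowSums(E^2)))) {
    stop_nirslat(sprintf(
      "extinction system is singular for wavelengths %s nm",
      paste(wl, collapse = ", ")), "nirslat_numeric_error")
  }
  nch <- dim(rec$dod)[1]; ns <- dim(rec$dod)[3]
  Einv <- solve(E)
  hbo <- matrix(0, nch, ns); hbr <- matrix(0, nch, ns)
  for (ch in seq_len(nch)) {
    conc <- Einv %*% rec$dod[ch, , ]
    hbo[ch, ] <- conc[1, ]
    hbr[ch, ] <- conc[2, ]
  }
  hemo_ts(hbo, hbr, rec$fs, rec$t)
}

#' Forward modified Beer-Lambert model
#'
#' Maps hemoglobin concentration changes to the optical-density changes a
#' two-wavelength system would record: `dOD(lambda) = [e_HbO(lambda) dHbO +
#' e_HbR(lambda) dHbR] * d * DPF(lambda)`. Exact inverse of [mbll_inverse()]
#' up to linear-algebra round-off; used to produce synthetic raw recordings
#' and to round-trip-test the conversion.
#'
#' @inheritParams mbll_inverse
#' @param hemo A [hemo_ts()].
#' @return An [optical_recording()] at the layout's wavelengths.
#' @export
forward_mbll <- function(hemo, layout = channel_layout(), dpf = 6,
                         extinction = extinction_coefficients()) {
  assert_that(inherits(hemo, "hemo_ts"), "hemo must be a hemo_ts")
  wl <- layout$wavelengths_nm
  E <- mbll_matrix(wl, layout, dpf, extinction)
  nch <- nrow(hemo$hbo); ns <- ncol(hemo$hbo)
  dod <- array(0, dim = c(nch, length(wl), ns))
  for (ch in seq_len(nch)) {
    dod[ch, , ] <- E %*% rbind(hemo$hbo[ch, ], hemo$hbr[ch, ])
  }
  optical_recording(dod, wl, hemo$fs)
}
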