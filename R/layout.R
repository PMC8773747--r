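#' Prefrontal 15-channel optode layout
#'
#' Describes the probe montage used throughout the pipeline: 15 channels over
#' the prefrontal cortex, channels 1-7 on the right hemisphere, 9-15 on the
#' left, channel 8 on the midline, 25 mm source-detector separation, two
#' wavelengths (780 and 850 nm), sampled at 8.138 Hz.
#'
#' @param n_channels Total number of channels.
#' @param right_channels,left_channels,midline_channels Integer channel ids;
#'   together they must partition `1:n_channels`.
#' @param source_detector_distance_mm Source-detector separation in mm.
#' @param wavelengths_nm The two measurement wavelengths in nm.
#' @param fs_hz Sampling rate in Hz.
#'
#' @return An object of class `channel_layout`.
#' @export
#' @examples
#' lay <- channel_layout()
#' lay$right_channels
channel_layout <- function(n_channels = 15L,
                           right_channels = 1:7,
                           left_channels = 9:15,
                           midline_channels = 8L,
                           source_detector_distance_mm = 25,
                           wavelengths_nm = c(780, 850),
                           fs_hz = 8.138) {
  all_ch <- sort(c(right_channels, left_channels, midline_channels))
  assert_that(identical(as.integer(all_ch), seq_len(n_channels)),
              "right, left and midline channel sets must partition 1..n_channels")
  assert_that(is_scalar_number(source_detector_distance_mm) &&
                source_detector_distance_mm > 0,
              "source_detector_distance_mm must be a positive scalar")
  assert_that(length(wavelengths_nm) == 2 && all(wavelengths_nm > 0),
              "exactly two positive wavelengths are required")
  assert_that(is_scalar_number(fs_hz) && fs_hz > 0, "fs_hz must be positive")
  structure(list(
    n_channels = as.integer(n_channels),
    right_channels = as.integer(right_channels),
    left_channels = as.integer(left_channels),
    midline_channels = as.integer(midline_channels),
    source_detector_distance_mm = source_detector_distance_mm,
    wavelengths_nm = as.numeric(wavelengths_nm),
    fs_hz = fs_hz
  ), class = "channel_layout")
}

#' @export
print.channel_layout <- function(x, ...) {
  cat(sprintf(
    "<channel_layout> %d channels (R: %s; L: %s; midline: %s), d = %g mm, %g/%g nm, fs = %g Hz\n",
    x$n_channels,
    paste(range(x$right_channels), collapse = "-"),
    paste(range(x$left_channels), collapse = "-"),
    paste(x$midline_channels, collapse = ","),
    x$source_detector_distance_mm,
    x$wavelengths_nm[1], x$wavelengths_nm[2], x$fs_hz))
  invisible(x)
}
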