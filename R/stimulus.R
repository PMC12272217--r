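# Flicker stimulus model: modulation depth <-> gray level, frame-grid square
# waves, and the ideal square-wave line spectrum.

#' Specify a flickering stimulus
#'
#' A flicker alternates between an OFF state at the background gray level and
#' an ON state whose gray level is set by the amplitude modulation depth: the
#' fraction of the background-to-white range that the ON state traverses.
#'
#' @param freq Flicker frequency in Hz. Must be below half the refresh rate.
#' @param modulation_depth Fraction of the maximal modulation depth, in
#'   \[0, 1\]. Depth 1 alternates between the background and `max_gray`;
#'   depth 0 does not flicker at all.
#' @param background_gray Integer gray level of the OFF state (default 130).
#' @param max_gray Brightest gray level (default 255).
#' @param size_px Width x height of the flicker patch in pixels; metadata
#'   only.
#' @param refresh_rate Monitor refresh rate in Hz (default 120).
#' @param background_luminance_cd_m2 Measured background luminance, stored as
#'   metadata only; no gray-to-luminance model is fitted.
#'
#' @return An object of class `flicker_spec`.
#' @examples
#' spec <- flicker_spec(13, 0.70)
#' depth_to_gray(spec) # 217
#' @export
flicker_spec <- function(freq, modulation_depth, background_gray = 130L,
                         max_gray = 255L, size_px = c(640L, 1080L),
                         refresh_rate = 120,
                         background_luminance_cd_m2 = 124) {
  check_number(freq, "freq", lower = 0, allow_zero = FALSE)
  check_number(modulation_depth, "modulation_depth", 0, 1)
  check_number(background_gray, "background_gray", 0)
  check_number(max_gray, "max_gray", 0)
  check_number(refresh_rate, "refresh_rate", lower = 0, allow_zero = FALSE)
  if (background_gray > max_gray)
    stop_invalid("background_gray must not exceed max_gray")
  if (freq >= refresh_rate / 2)
    stop_invalid("freq must be below refresh_rate/2 (Nyquist of the frame grid)")
  structure(
    list(freq = freq, modulation_depth = modulation_depth,
         background_gray = as.integer(background_gray),
         max_gray = as.integer(max_gray), waveform = "square",
         size_px = as.integer(size_px), refresh_rate = refresh_rate,
         background_luminance_cd_m2 = background_luminance_cd_m2),
    class = "flicker_spec")
}

#' @export
print.flicker_spec <- function(x, ...) {
  cat(sprintf(
    "<flicker_spec> %g Hz square, depth %.4g, gray %d (OFF) / %d (ON), %g Hz refresh\n",
    x$freq, x$modulation_depth, x$background_gray, depth_to_gray(x),
    x$refresh_rate))
  invisible(x)
}

#' ON-state gray level for a given modulation depth
#'
#' Maps an amplitude modulation depth to the 8-bit gray level of the ON state:
#' `floor(g0 + (max_gray - g0) * m)` with `g0` the background gray. The OFF
#' state is always the background. Example: a 70% depth flicker on the default
#' background alternates between 130 and 130 + (255 - 130) x 0.7 = 217.
#'
#' @param spec A [flicker_spec()].
#' @return Integer gray level of the ON state.
#' @examples
#' depth_to_gray(flicker_spec(13, 0.70)) # 217
#' depth_to_gray(flicker_spec(13, 0))    # 130
#' @export
depth_to_gray <- function(spec) {
  stopifnot(inherits(spec, "flicker_spec"))
  g0 <- spec$background_gray
  as.integer(floor(g0 + (spec$max_gray - g0) * spec$modulation_depth))
}

#' Per-frame ON/OFF state sequence on the monitor frame grid
#'
#' Samples an ideal 50%-duty square wave at frame midpoints: frame `k`
#' (0-based) is ON when the square wave at time `(k + 0.5) / refresh_rate` is
#' in its positive half-cycle. For frequencies that divide the refresh rate
#' (e.g. 15 Hz on 120 Hz) this yields exact integer half-periods; for others
#' (e.g. 13 Hz, 9.23 frames/cycle) the grid approximates the ideal wave with
#' its dominant spectral line still at `freq`.
#'
#' @param spec A [flicker_spec()].
#' @param duration Duration in seconds (> 0; rounded up to a whole frame).
#' @return A data.frame with columns `frame` (0-based), `time_s` (frame start),
#'   `state` (1 = ON, 0 = OFF) and `gray_level`.
#' @examples
#' fs <- frame_sequence(flicker_spec(15, 0.7), 1/15)
#' fs$state # 4 ON then 4 OFF frames
#' @export
frame_sequence <- function(spec, duration) {
  stopifnot(inherits(spec, "flicker_spec"))
  check_number(duration, "duration", lower = 0, allow_zero = FALSE)
  n <- max(1L, as.integer(ceiling(duration * spec$refresh_rate)))
  k <- seq_len(n) - 1L
  tm <- (k + 0.5) / spec$refresh_rate
  # positive half-cycle of sin(2*pi*f*t) starting ON at t=0
  state <- as.integer(sin(2 * pi * spec$freq * tm) > 0 |
                        (spec$freq * tm) %% 1 == 0)
  data.frame(frame = k, time_s = k / spec$refresh_rate, state = state,
             gray_level = ifelse(state == 1L, depth_to_gray(spec),
                                 spec$background_gray))
}

#' Harmonic line spectrum of the ideal square-wave flicker
#'
#' Fourier amplitudes of an ideal 50%-duty square wave: lines at odd
#' harmonics with amplitude proportional to 1/n, zero at even harmonics. The
#' square shape is what concentrates stimulus energy at the fundamental and
#' makes the SSVEP response strongest there and at its harmonics.
#'
#' @param spec A [flicker_spec()].
#' @param n_harmonics Number of harmonics to return (default 10).
#' @return A data.frame with `harmonic`, `freq_hz` and `amplitude` (relative
#'   to the fundamental).
#' @export
ideal_waveform_spectrum <- function(spec, n_harmonics = 10L) {
  stopifnot(inherits(spec, "flicker_spec"))
  n <- seq_len(n_harmonics)
  amp <- ifelse(n %% 2L == 1L, 1 / n, 0)
  data.frame(harmonic = n, freq_hz = n * spec$freq, amplitude = amp)
}

#' Write a frame sequence to CSV
#'
#' @param fs A data.frame from [frame_sequence()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_frame_sequence <- function(fs, path) {
  utils::write.csv(fs, path, row.names = FALSE)
  invisible(path)
}
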