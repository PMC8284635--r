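#' Split raw acceleration into static and dynamic components
#'
#' Static acceleration (gravity/posture) is estimated by low-pass filtering
#' each axis at `cutoff_hz` with a linear-phase FIR filter (windowed-sinc,
#' Hamming window, order `order`), applied forward and backward for zero
#' phase so that the posture estimate stays time-aligned with the raw
#' signal. Dynamic acceleration is the raw signal minus the static
#' component, so the decomposition reconstructs the input exactly.
#'
#' @param series An [accel_series()].
#' @param cutoff_hz Low-pass cutoff in Hz (default 1.5).
#' @param order FIR filter order (number of taps minus one; default 100).
#' @param zero_phase Compensate the filter's group delay (default `TRUE`):
#'   the symmetric FIR is applied as a centred convolution on
#'   mirror-padded data, which is exactly zero-phase and passes DC without
#'   edge transients. With `FALSE` a single causal pass is used, which
#'   delays the static estimate by half the filter order.
#' @return An object of class `accel_decomposed`: list with `static` and
#'   `dynamic` (each a list of `x`, `y`, `z`), `fs`, and `tag_kind`.
#' @export
decompose_accel <- function(series, cutoff_hz = 1.5, order = 100,
                            zero_phase = TRUE) {
  stopifnot(inherits(series, "accel_series"))
  n <- length(series$x)
  if (n <= order)
    stop("length error: series (", n, " samples) must exceed filter order (",
         order, ")")
  if (cutoff_hz >= series$fs / 2)
    stop("cutoff must be below the Nyquist frequency")
  h <- as.numeric(signal::fir1(order, cutoff_hz / (series$fs / 2),
                               type = "low"))
  h <- h / sum(h)  # force exactly unit DC gain
  half <- length(h) %/% 2L
  lp <- function(v) {
    if (zero_phase) {
      # symmetric (linear-phase) taps + centred convolution = zero phase;
      # mirror padding avoids edge transients and passes DC exactly
      pad_l <- v[pmin(n, 1L + rev(seq_len(half)))]
      pad_r <- v[pmax(1L, n - seq_len(half))]
      vp <- c(pad_l, v, pad_r)
      out <- stats::filter(vp, h, method = "convolution", sides = 2L)
      as.numeric(out[(half + 1L):(half + n)])
    } else {
      # causal pass: half-order group delay, warm-up holds the raw signal
      out <- as.numeric(stats::filter(c(rep(v[1L], length(h) - 1L), v),
                                      h, method = "convolution", sides = 1L))
      out[length(h):(length(h) - 1L + n)]
    }
  }
  st <- list(x = lp(series$x), y = lp(series$y), z = lp(series$z))
  dy <- list(x = series$x - st$x, y = series$y - st$y, z = series$z - st$z)
  structure(list(static = st, dynamic = dy, fs = series$fs,
                 tag_kind = series$tag_kind),
            class = "accel_decomposed")
}

#' @export
print.accel_decomposed <- function(x, ...) {
  cat(sprintf("<accel_decomposed> %d samples at %g Hz\n",
              length(x$static$x), x$fs))
  invisible(x)
}

#' Per-sample pitch angle from static longitudinal acceleration
#'
#' Body pitch is `asin(x_S)` in degrees, with the static longitudinal
#' component clipped to `[-1, 1]` first so that filter overshoot cannot
#' produce undefined angles.
#'
#' @param decomposed An `accel_decomposed`.
#' @return Object of class `pitch_series`: list with `pitch_deg` (values in
#'   `[-90, 90]`) and `fs`.
#' @export
pitch_angle <- function(decomposed) {
  stopifnot(inherits(decomposed, "accel_decomposed"))
  xs <- pmin(1, pmax(-1, decomposed$static$x))
  structure(list(pitch_deg = asin(xs) * 180 / pi, fs = decomposed$fs),
            class = "pitch_series")
}

#' Overall dynamic body acceleration and its moving average
#'
#' ODBA is the sum of the absolute dynamic acceleration in the three axes;
#' `odmn` is its centred moving average over `window_s` seconds, with
#' windows shrinking at the record edges (no padding).
#'
#' @param decomposed An `accel_decomposed`.
#' @param window_s Moving-average window in seconds (default 10).
#' @return Object of class `odba_series`: list with `odba`, `odmn` (both in
#'   g, non-negative) and `fs`.
#' @export
odba <- function(decomposed, window_s = 10) {
  stopifnot(inherits(decomposed, "accel_decomposed"))
  v <- abs(decomposed$dynamic$x) + abs(decomposed$dynamic$y) +
    abs(decomposed$dynamic$z)
  w <- max(1L, round(window_s * decomposed$fs))
  structure(list(odba = v, odmn = moving_mean(v, w), fs = decomposed$fs),
            class = "odba_series")
}

#' Centred moving mean with shrinking edge windows
#'
#' @param v Numeric vector.
#' @param w Window width in samples.
#' @return Vector of the same length; element `i` is the mean of
#'   `v[max(1, i - floor(w/2)) .. min(n, i + ceiling(w/2) - 1)]`.
#' @export
moving_mean <- function(v, w) {
  n <- length(v)
  w <- max(1L, as.integer(w))
  h1 <- w %/% 2L
  h2 <- w - h1 - 1L
  lo <- pmax(1L, seq_len(n) - h1)
  hi <- pmin(n, seq_len(n) + h2)
  cs <- c(0, cumsum(v))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Alternating local extrema of a signal
#'
#' Finds local maxima and minima, collapsing plateaus to their first sample,
#' so that the returned sequence strictly alternates between maxima and
#' minima. A monotone signal yields no extrema.
#'
#' @param v Numeric vector (length >= 3).
#' @return Data frame with columns `index` (1-based sample index), `value`
#'   and `kind` (`"max"` or `"min"`); zero rows when the signal is monotone.
#' @examples
#' local_extrema(c(0, 1, 0, -1, 0))
#' @export
local_extrema <- function(v) {
  empty <- data.frame(index = integer(), value = numeric(),
                      kind = character(), stringsAsFactors = FALSE)
  n <- length(v)
  if (n < 3L) stop("length error: need at least 3 samples")
  keep <- c(TRUE, diff(v) != 0)
  idx <- which(keep)
  vv <- v[keep]
  m <- length(vv)
  if (m < 3L) return(empty)
  s <- sign(diff(vv))
  turn <- which(s[-1L] != s[-(m - 1L)]) + 1L   # position within vv
  if (!length(turn)) return(empty)
  data.frame(index = idx[turn], value = vv[turn],
             kind = ifelse(s[turn - 1L] > 0, "max", "min"),
             stringsAsFactors = FALSE)
}

#' Successive differences between local extrema
#'
#' Convenience wrapper used both in calibration (flap-amplitude and pitch
#' statistics) and event detection: absolute differences between successive
#' alternating extrema.
#'
#' @param v Numeric vector.
#' @return Data frame with one row per successive extremum pair: `i1`, `i2`
#'   (sample indices), `v1`, `v2` (values), `diff` (absolute difference) and
#'   `kind1` (kind of the first extremum of the pair).
#' @export
extremum_diffs <- function(v) {
  ex <- local_extrema(v)
  if (nrow(ex) < 2L)
    return(data.frame(i1 = integer(), i2 = integer(), v1 = numeric(),
                      v2 = numeric(), diff = numeric(), kind1 = character(),
                      stringsAsFactors = FALSE))
  k <- nrow(ex)
  data.frame(i1 = ex$index[-k], i2 = ex$index[-1L], v1 = ex$value[-k],
             v2 = ex$value[-1L], diff = abs(diff(ex$value)),
             kind1 = ex$kind[-k], stringsAsFactors = FALSE)
}

#' Spectrogram band energies of dynamic dorsoventral acceleration
#'
#' Computes a short-time Fourier transform of `z_D` (Hann window of
#' `window_s` seconds, `overlap_frac` overlap) and sums the one-sided power
#' spectral density in a flapping-flight band and a take-off band per frame.
#' Flapping flight concentrates energy near the cruising flap rate (~4 Hz),
#' take-off flapping above it, so the per-frame difference
#' `flap - takeoff` is positive during flight.
#'
#' @param decomposed An `accel_decomposed` with `fs >= 10` Hz.
#' @param window_s FFT window length in seconds (default 4).
#' @param overlap_frac Fractional window overlap (default 0.85).
#' @param flap_band Closed frequency band in Hz assigned to cruising
#'   flapping (default `c(3.5, 5)`; a bin at exactly 5 Hz counts as flap).
#' @param takeoff_band Band in Hz for take-off flapping; `NULL` (default)
#'   means `(5, fs/2]`, open at the lower edge.
#' @return Object of class `band_energy_series`: list with `frame_times`
#'   (window-centre times, s), `flap_band_energy`, `takeoff_band_energy`,
#'   `diff`, `frame_step_s` and `fs`.
#' @export
band_energy <- function(decomposed, window_s = 4, overlap_frac = 0.85,
                        flap_band = c(3.5, 5), takeoff_band = NULL) {
  stopifnot(inherits(decomposed, "accel_decomposed"))
  fs <- decomposed$fs
  if (fs < 10) stop("sampling rate must be at least 10 Hz")
  z <- decomposed$dynamic$z
  nwin <- round(window_s * fs)
  if (length(z) < nwin)
    stop("length error: series shorter than one spectrogram window")
  hop <- max(1L, round(nwin * (1 - overlap_frac)))
  starts <- seq(1L, length(z) - nwin + 1L, by = hop)
  win <- 0.5 * (1 - cos(2 * pi * seq(0, nwin - 1) / (nwin - 1)))  # Hann
  frames <- vapply(starts, function(s) z[s:(s + nwin - 1L)] * win,
                   numeric(nwin))
  spec <- stats::mvfft(frames)
  nf <- nwin %/% 2L + 1L
  pw <- Mod(spec[seq_len(nf), , drop = FALSE])^2
  # one-sided PSD scaling; interior bins carry the folded negative freqs
  scale <- 1 / (fs * sum(win^2))
  pw <- pw * scale
  if (nf > 2L) pw[2:(nf - 1L), ] <- 2 * pw[2:(nf - 1L), ]
  freqs <- (seq_len(nf) - 1L) * fs / nwin
  if (is.null(takeoff_band)) takeoff_band <- c(5, fs / 2)
  flap_ix <- freqs >= flap_band[1L] & freqs <= flap_band[2L]
  toff_ix <- freqs > takeoff_band[1L] & freqs <= takeoff_band[2L]
  flap <- colSums(pw[flap_ix, , drop = FALSE])
  toff <- colSums(pw[toff_ix, , drop = FALSE])
  structure(list(frame_times = (starts - 1 + (nwin - 1) / 2) / fs,
                 flap_band_energy = flap, takeoff_band_energy = toff,
                 diff = flap - toff, frame_step_s = hop / fs, fs = fs),
            class = "band_energy_series")
}
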