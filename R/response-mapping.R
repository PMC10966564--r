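#' Time-lapse optical stack
#'
#' Container for camera count data: a frames x rows x cols array (a single
#' frame may be passed as a matrix) plus acquisition metadata. Counts are
#' non-negative camera counts; no rescaling is ever applied.
#'
#' @param data 3-D array (frames, rows, cols) or a matrix (one frame).
#' @param frame_interval_s time between frame starts in s (default 0.1,
#'   i.e. 10 Hz sampling).
#' @param exposure_s camera exposure per frame in s (default 0.01).
#' @param pixel_size_um pixel size in um, or `NA` if unknown.
#' @param t0_s acquisition start time in s.
#' @return An object of class `optical_stack`.
#' @export
optical_stack <- function(data, frame_interval_s = 0.1, exposure_s = 0.01,
                          pixel_size_um = NA_real_, t0_s = 0) {
  if (is.matrix(data)) data <- array(data, dim = c(1L, dim(data)))
  if (length(dim(data)) != 3L) stop_invalid("data must be frames x rows x cols")
  if (any(data < 0, na.rm = TRUE)) stop_invalid("counts must be non-negative")
  if (frame_interval_s <= 0) stop_invalid("frame_interval_s must be positive")
  structure(
    list(data = data, frame_interval_s = frame_interval_s,
         exposure_s = exposure_s, pixel_size_um = pixel_size_um, t0_s = t0_s),
    class = "optical_stack"
  )
}

#' @export
print.optical_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<optical_stack> %d frame(s) of %d x %d px, dt = %g s, t0 = %g s, pixel = %s um\n",
              d[1], d[2], d[3], x$frame_interval_s, x$t0_s,
              format(x$pixel_size_um)))
  invisible(x)
}

#' @rdname optical_stack
#' @param x an `optical_stack`.
#' @export
frame_times <- function(x) {
  stopifnot(inherits(x, "optical_stack"))
  x$t0_s + (seq_len(dim(x$data)[1]) - 1L) * x$frame_interval_s
}

#' Optogenetic stimulation protocol
#'
#' Defaults describe the reference protocol: 20 s of background recording
#' followed by 10 light pulses at 1 Hz, each 60 ms long, within a 60 s
#' recording. Pulse i fires at `background_s + i/pulse_rate_hz` (one period
#' after the background ends), so the default train spans 21-30 s and the
#' standard 21-31 s analysis window holds exactly ten stimulation periods.
#'
#' @param background_s background recording before the first pulse, s.
#' @param n_pulses number of stimulation pulses.
#' @param pulse_rate_hz pulse repetition rate, Hz.
#' @param pulse_width_s pulse duration, s (must be shorter than one period).
#' @param total_s total recording duration, s.
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(background_s = 20, n_pulses = 10L, pulse_rate_hz = 1,
                          pulse_width_s = 0.06, total_s = 60) {
  if (n_pulses < 1L || pulse_rate_hz <= 0 || pulse_width_s <= 0) {
    stop_invalid("pulse count, rate and width must be positive")
  }
  if (pulse_width_s >= 1 / pulse_rate_hz) {
    stop_invalid("pulse_width_s must be shorter than one stimulation period")
  }
  if (background_s + n_pulses / pulse_rate_hz > total_s) {
    stop_invalid("background + pulse train must fit inside total_s")
  }
  structure(
    list(background_s = background_s, n_pulses = as.integer(n_pulses),
         pulse_rate_hz = pulse_rate_hz, pulse_width_s = pulse_width_s,
         total_s = total_s),
    class = "stim_protocol"
  )
}

#' @rdname stim_protocol
#' @param protocol a `stim_protocol`.
#' @export
pulse_times <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  protocol$background_s + seq_len(protocol$n_pulses) / protocol$pulse_rate_hz
}

#' Extract a time window from a movie
#'
#' Keeps frames whose start timestamps satisfy `start_s <= t < end_s`
#' (half-open interval) and updates `t0_s`. If a stimulation frequency is
#' supplied, a window whose length is not an integer number of stimulation
#' periods triggers a warning, since harmonic scoring then leaks across DFT
#' bins.
#'
#' @param movie an [optical_stack()].
#' @param start_s,end_s window bounds in s.
#' @param f_stim_hz optional stimulation frequency used only for the
#'   integer-period check.
#' @return A new `optical_stack` restricted to the window.
#' @examples
#' mv <- optical_stack(array(0, c(600, 2, 2)))
#' dim(extract_window(mv, 21, 31)$data)[1] # 100 frames
#' @export
extract_window <- function(movie, start_s, end_s, f_stim_hz = NULL) {
  stopifnot(inherits(movie, "optical_stack"))
  if (end_s <= start_s) stop_invalid("end_s must exceed start_s")
  t <- frame_times(movie)
  tol <- movie$frame_interval_s * 1e-6
  keep <- which(t >= start_s - tol & t < end_s - tol)
  if (length(keep) == 0L) {
    stop_invalid(sprintf("window [%g, %g) contains no frames of the recording", start_s, end_s))
  }
  if (min(t) > start_s + tol || max(t) + movie$frame_interval_s < end_s - tol) {
    stop_invalid("window extends beyond the recording")
  }
  if (!is.null(f_stim_hz)) {
    n_per <- (end_s - start_s) * f_stim_hz
    if (abs(n_per - round(n_per)) > 1e-9) {
      warn_photonstim("window length is not an integer multiple of the stimulation period",
                      "photonstim_offgrid_window")
    }
  }
  optical_stack(movie$data[keep, , , drop = FALSE],
                frame_interval_s = movie$frame_interval_s,
                exposure_s = movie$exposure_s,
                pixel_size_um = movie$pixel_size_um,
                t0_s = t[keep[1]])
}

.harmonic_bins <- function(n, fs_hz, f_stim_hz, harmonics) {
  if (any(harmonics < 1L) || any(harmonics != round(harmonics))) {
    stop_invalid("harmonics must be positive integers (DC is excluded)")
  }
  bins <- harmonics * f_stim_hz * n / fs_hz
  off <- abs(bins - round(bins)) > 1e-9
  if (any(off)) {
    stop_invalid(sprintf(
      "harmonic(s) %s Hz do not fall on a DFT bin (N = %d, fs = %g Hz)",
      paste(harmonics[off] * f_stim_hz, collapse = ", "), n, fs_hz))
  }
  bins <- as.integer(round(bins))
  if (any(bins > n %/% 2)) {
    stop_invalid("requested harmonic lies above the Nyquist frequency")
  }
  bins
}

# direct (non-FFT) evaluation of the unnormalized DFT at the given bins;
# identical arithmetic is used for single traces and whole movies so the
# per-pixel map is exactly the pixel-wise score
.dft_rows <- function(n, bins) {
  tt <- seq_len(n) - 1L
  exp(-2i * pi * outer(bins, tt) / n) # length(bins) x n
}

#' Stimulation-locked harmonic response score of a single trace
#'
#' Transforms the raw trace with the unnormalized discrete Fourier transform
#' and sums the magnitudes at the requested integer multiples of the
#' stimulation frequency. The DC bin is never included, so any constant
#' offset of the trace leaves the score unchanged. Every requested harmonic
#' must fall exactly on a DFT bin (i.e. `k * f_stim * N / fs` integer),
#' otherwise the call is refused naming the offending harmonic.
#'
#' @param trace numeric vector of camera counts.
#' @param fs_hz sampling frequency in Hz.
#' @param f_stim_hz stimulation frequency in Hz.
#' @param harmonics integer multiples of `f_stim_hz` to sum (default 1:5).
#' @return Non-negative score (sum of DFT magnitudes).
#' @examples
#' t <- (0:99) / 10
#' harmonic_response_score(cos(2 * pi * t), 10, 1) # 50 = N/2
#' @export
harmonic_response_score <- function(trace, fs_hz, f_stim_hz, harmonics = 1:5) {
  if (anyNA(trace)) stop_invalid("trace must not contain NA")
  n <- length(trace)
  bins <- .harmonic_bins(n, fs_hz, f_stim_hz, harmonics)
  w <- .dft_rows(n, bins)
  sum(Mod(as.vector(w %*% trace)))
}

#' Per-pixel harmonic response map of a stimulation movie
#'
#' Reproduces the frequency-domain responder analysis: for every pixel the
#' trace inside the analysis window is scored with
#' [harmonic_response_score()], and the map is normalized to the pixel with
#' the maximum score in the field of view, so values lie in [0, 1]. An
#' all-zero input stays all zero (no division). Bright pixels respond
#' coherently to the pulse train; dark pixels do not.
#'
#' @param movie an [optical_stack()] covering the full recording.
#' @param protocol a [stim_protocol()]; supplies the stimulation frequency.
#' @param window_s length-2 numeric, analysis window in s (default
#'   `c(21, 31)`, half-open).
#' @param harmonics integer harmonic multiples to sum (default 1:5).
#' @return A list of class `response_map` with `scores` (rows x cols matrix
#'   in [0, 1]), `raw_max_score`, `window_s`, `harmonics`, `f_stim_hz`.
#' @export
response_map <- function(movie, protocol = stim_protocol(),
                         window_s = c(21, 31), harmonics = 1:5) {
  stopifnot(inherits(movie, "optical_stack"), inherits(protocol, "stim_protocol"))
  win <- extract_window(movie, window_s[1], window_s[2],
                        f_stim_hz = protocol$pulse_rate_hz)
  d <- dim(win$data)
  n <- d[1]
  fs <- 1 / win$frame_interval_s
  bins <- .harmonic_bins(n, fs, protocol$pulse_rate_hz, harmonics)
  w <- .dft_rows(n, bins)
  x <- matrix(win$data, nrow = n) # columns are pixels (row-major within frame dims)
  sc <- colSums(Mod(w %*% x))
  raw_max <- max(sc)
  if (raw_max > 0) sc <- sc / raw_max
  structure(
    list(scores = matrix(sc, nrow = d[2], ncol = d[3]),
         raw_max_score = raw_max, window_s = c(window_s[1], window_s[2]),
         harmonics = as.integer(harmonics), f_stim_hz = protocol$pulse_rate_hz),
    class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf("<response_map> %d x %d px, window [%g, %g) s, harmonics {%s} x %g Hz, raw max %.3g\n",
              nrow(x$scores), ncol(x$scores), x$window_s[1], x$window_s[2],
              paste(x$harmonics, collapse = ","), x$f_stim_hz, x$raw_max_score))
  invisible(x)
}

#' Classify responder pixels from a response map
#'
#' Thresholding utility: the threshold is a free parameter (default 0.5 of
#' the normalized score), never hard-coded into reports.
#'
#' @param map a [response_map()].
#' @param threshold normalized score cut-off in (0, 1).
#' @return Logical rows x cols matrix.
#' @export
classify_responders <- function(map, threshold = 0.5) {
  stopifnot(inherits(map, "response_map"))
  if (threshold <= 0 || threshold >= 1) stop_invalid("threshold must lie in (0, 1)")
  map$scores > threshold
}

#' Mean fluorescence trace over a region of interest
#'
#' Per-frame arithmetic mean of the counts over the masked pixels.
#'
#' @param movie an [optical_stack()].
#' @param roi_mask logical rows x cols matrix, at least one `TRUE`.
#' @return Data frame with columns `time_s` and `mean_counts`.
#' @export
roi_average_trace <- function(movie, roi_mask) {
  stopifnot(inherits(movie, "optical_stack"))
  d <- dim(movie$data)
  if (!is.logical(roi_mask) || !all(dim(roi_mask) == d[2:3])) {
    stop_invalid("roi_mask must be a logical matrix matching the frame shape")
  }
  if (!any(roi_mask)) stop_invalid("roi_mask selects no pixels")
  x <- matrix(movie$data, nrow = d[1])
  sel <- which(as.vector(roi_mask))
  data.frame(time_s = frame_times(movie),
             mean_counts = rowMeans(x[, sel, drop = FALSE]))
}
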