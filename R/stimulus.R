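#' Map a code digit to a grey-level opacity
#'
#' Stimuli are rendered by alpha blending a white foreground over a black
#' background, so opacity alpha = 0 is black and alpha = 1 is white.
#' Digit d of a p-ary code maps to the equally spaced level d/(p-1):
#' binary digits give black/white, quintary digits give five shades of
#' grey (0, 0.25, 0.5, 0.75, 1).
#'
#' @param digit Integer digit(s) in `[0, p-1]`.
#' @param p Code base.
#' @return Numeric opacity value(s) in `[0, 1]`.
#' @examples
#' digit_to_alpha(3, 5)  # 0.75
#' @export
digit_to_alpha <- function(digit, p) {
  stopifnot_scalar(p, "p", positive = TRUE)
  digit <- as.integer(digit)
  if (any(digit < 0L | digit >= p))
    stop(sprintf("digits must lie in [0, %d]", as.integer(p) - 1L), call. = FALSE)
  digit / (p - 1)
}

#' Per-frame opacity schedule for one stimulus
#'
#' Repeats the mapped code for the requested number of stimulation
#' cycles; the opacity is updated once per monitor frame, i.e. every
#' 1/refresh_rate seconds (16.67, 8.33 and 4.167 ms at 60, 120 and
#' 240 Hz).
#'
#' @param code Integer digit vector (one target's code) or an
#'   [msequence()].
#' @param refresh_rate Monitor refresh rate in Hz.  60, 120 and 240 are
#'   the supported setups; other values work but raise a warning.
#' @param cycles Number of repetitions of the full code (>= 1).
#' @param p Code base; required when `code` is a bare vector.
#' @return An object of class `"frame_schedule"`: `alphas` (length
#'   `cycles * period`), `digits`, `refresh_rate`, `cycles`, `period`, `p`.
#' @examples
#' fs <- frame_schedule(binary_msequence(), 60, cycles = 2)
#' length(fs$alphas)  # 126 frames
#' @export
frame_schedule <- function(code, refresh_rate, cycles, p = NULL) {
  if (inherits(code, "msequence")) { p <- code$p; code <- code$digits }
  if (is.null(p)) stop("supply 'p' for bare digit vectors", call. = FALSE)
  stopifnot_scalar(refresh_rate, "refresh_rate", positive = TRUE)
  cycles <- as.integer(cycles)
  if (is.na(cycles) || cycles < 1L) stop("'cycles' must be >= 1", call. = FALSE)
  if (!refresh_rate %in% c(60, 120, 240))
    warning("refresh_rate outside the tested 60/120/240 Hz setups")
  digits <- rep(as.integer(code), cycles)
  structure(list(alphas = digit_to_alpha(digits, p), digits = digits,
                 refresh_rate = refresh_rate, cycles = cycles,
                 period = length(code), p = as.integer(p)),
            class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames (%d cycles x period %d) at %g Hz (%.4g ms/frame)\n",
              length(x$alphas), x$cycles, x$period, x$refresh_rate,
              1000 / x$refresh_rate))
  invisible(x)
}

#' Trial duration and sample count
#'
#' A trial spans `cycles` repetitions of the code at the given refresh
#' rate, so it lasts `cycles * period / refresh_rate` seconds and is
#' digitised into `round(duration * fs)` samples.  The study's binary
#' trials (2 cycles of 63 frames at 60 Hz) last 2.1 s = 1260 samples at
#' 600 Hz; quintary trials (1 cycle of 124 frames) give 1240 samples.
#'
#' @param code_period Code length in frames.
#' @param refresh_rate Monitor refresh rate, Hz.
#' @param cycles Stimulation cycles per trial.
#' @param fs EEG sampling rate, Hz (default 600).
#' @return List of class `"trial_timing"` with `duration` (s),
#'   `sample_count` and `samples_per_frame` (= fs / refresh_rate).
#' @examples
#' trial_timing(63, 60, 2)    # 2.1 s, 1260 samples
#' trial_timing(124, 60, 1)   # 1240 samples
#' @export
trial_timing <- function(code_period, refresh_rate, cycles, fs = 600) {
  for (nm in c("code_period", "refresh_rate", "cycles", "fs"))
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  duration <- cycles * code_period / refresh_rate
  structure(list(duration = duration,
                 sample_count = as.integer(round(duration * fs)),
                 samples_per_frame = fs / refresh_rate,
                 refresh_rate = refresh_rate, cycles = cycles,
                 code_period = code_period, fs = fs),
            class = "trial_timing")
}

#' @export
print.trial_timing <- function(x, ...) {
  cat(sprintf("Trial: %.4g s, %d samples at %g Hz (%g samples/frame)\n",
              x$duration, x$sample_count, x$fs, x$samples_per_frame))
  invisible(x)
}

#' Expand a frame schedule to the EEG sampling grid
#'
#' Sample t (0-based) takes the opacity of frame
#' `floor(t * refresh_rate / fs)`.  At 600 Hz this gives exactly 10
#' samples per frame for the 60 Hz setup; at 240 Hz the 2.5
#' samples/frame average is realised by frames alternately spanning 3
#' and 2 samples.  Deterministic and order-preserving; no resampling
#' filter is involved.
#'
#' @param schedule A [frame_schedule()].
#' @param fs Sampling rate in Hz; must be at least the refresh rate.
#' @return Numeric vector of per-sample opacities, of length
#'   `trial_timing(...)$sample_count`.
#' @export
sample_waveform <- function(schedule, fs = 600) {
  if (!inherits(schedule, "frame_schedule"))
    stop("'schedule' must be a frame_schedule", call. = FALSE)
  if (fs < schedule$refresh_rate)
    stop("'fs' must be at least the refresh rate", call. = FALSE)
  tt <- trial_timing(schedule$period, schedule$refresh_rate, schedule$cycles, fs)
  t0 <- seq_len(tt$sample_count) - 1L
  frame <- floor(t0 * schedule$refresh_rate / fs)
  schedule$alphas[frame + 1L]
}

#' Stimulation cycles used per pattern and refresh rate
#'
#' The protocol keeps trial durations near two seconds by repeating the
#' binary 63-frame code 2/4/8 times and the quintary 124-frame code
#' 1/2/4 times at 60/120/240 Hz.
#'
#' @param pattern `"binary"` or `"quintary"`.
#' @param refresh_rate 60, 120 or 240.
#' @return Integer cycle count.
#' @export
default_cycles <- function(pattern = c("binary", "quintary"), refresh_rate) {
  pattern <- match.arg(pattern)
  key <- as.character(refresh_rate)
  tab <- list(binary = c("60" = 2L, "120" = 4L, "240" = 8L),
              quintary = c("60" = 1L, "120" = 2L, "240" = 4L))[[pattern]]
  if (!key %in% names(tab))
    stop("refresh_rate must be one of 60, 120, 240", call. = FALSE)
  tab[[key]]
}

#' Write a frame schedule as CSV
#'
#' Columns `frame_index` (0-based) and `alpha`.
#' @param schedule A [frame_schedule()].
#' @param path Output file.
#' @export
write_frame_schedule <- function(schedule, path) {
  utils::write.csv(data.frame(frame_index = seq_along(schedule$alphas) - 1L,
                              alpha = schedule$alphas),
                   path, row.names = FALSE)
  invisible(path)
}
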