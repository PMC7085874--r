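#' Configuration of the synthetic EEG generator
#'
#' The generator emulates the study's recording setup — 16 channels
#' sampled at 600 Hz — with a code-locked evoked component and coloured
#' background noise.  The evoked component is a gamma-shaped impulse
#' response convolved (circularly, since the flicker is periodic) with
#' the luminance-change drive, scaled per channel by a smooth topography
#' with occipital-like channels weighted highest.  Background noise is a
#' mixture of 1/f-shaped, alpha-band (10 Hz bump) and white components,
#' scaled so that the ratio of mean evoked power to mean noise power
#' across channels equals `snr_db`.
#'
#' @param channels Number of EEG channels (default 16).
#' @param fs Sampling rate, Hz (default 600).
#' @param snr_db Evoked-vs-noise power ratio in dB (default 0; `Inf`
#'   switches the noise off).
#' @param kernel_latency Evoked-response peak latency in seconds
#'   (default 0.10).
#' @param kernel_dispersion Time constant of the gamma kernel's decay in
#'   seconds (default 0.02); must be positive.
#' @param kernel_length Kernel support in seconds (default 0.25).
#' @param topography Per-channel gain vector, or `NULL` for a smooth
#'   ramp from 0.4 to 1 (a stand-in for the posterior gradient of real
#'   VEP topographies, not a claim about scalp physics).
#' @param noise_slope Exponent beta of the 1/f^beta noise component
#'   (default 1).
#' @param alpha_bump Relative amplitude of the 10 Hz spectral bump
#'   (default 0.5).
#' @param white_floor Relative white-noise floor (default 0.02).
#' @param nonlinearity If `TRUE`, the evoked source passes through a
#'   static saturating (tanh) nonlinearity, making the response
#'   autocorrelations of lagged targets nonorthogonal (default `FALSE`).
#' @param seed Integer seed; all randomness in a session/stream derives
#'   deterministically from it.
#' @return An object of class `"cvep_sim_config"`.
#' @export
cvep_sim_config <- function(channels = 16, fs = 600, snr_db = 0,
                            kernel_latency = 0.10, kernel_dispersion = 0.02,
                            kernel_length = 0.25, topography = NULL,
                            noise_slope = 1, alpha_bump = 0.5,
                            white_floor = 0.02, nonlinearity = FALSE,
                            seed = 1L) {
  channels <- as.integer(channels)
  if (channels < 1L) stop("'channels' must be >= 1", call. = FALSE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db))
    stop("'snr_db' must be a numeric scalar (possibly Inf)", call. = FALSE)
  stopifnot_scalar(kernel_latency, "kernel_latency", positive = TRUE)
  if (!is.numeric(kernel_dispersion) || length(kernel_dispersion) != 1L ||
      !is.finite(kernel_dispersion) || kernel_dispersion <= 0)
    stop("'kernel_dispersion' must be positive", call. = FALSE)
  stopifnot_scalar(kernel_length, "kernel_length", positive = TRUE)
  if (is.null(topography)) topography <- seq(0.4, 1, length.out = channels)
  if (length(topography) != channels)
    stop("'topography' length must equal 'channels'", call. = FALSE)
  structure(list(channels = channels, fs = fs, snr_db = snr_db,
                 kernel_latency = kernel_latency,
                 kernel_dispersion = kernel_dispersion,
                 kernel_length = kernel_length,
                 topography = as.numeric(topography),
                 noise_slope = noise_slope, alpha_bump = alpha_bump,
                 white_floor = white_floor,
                 nonlinearity = isTRUE(nonlinearity),
                 seed = as.integer(seed)),
            class = "cvep_sim_config")
}

#' @export
print.cvep_sim_config <- function(x, ...) {
  cat(sprintf(paste0("Synthetic EEG config: %d channels at %g Hz, SNR %g dB, ",
                     "kernel peak %g s, nonlinearity %s, seed %d\n"),
              x$channels, x$fs, x$snr_db, x$kernel_latency,
              if (x$nonlinearity) "on" else "off", x$seed))
  invisible(x)
}

#' Gamma-shaped evoked-response kernel
#'
#' h(t) = t^a exp(-t/theta) with theta = `kernel_dispersion` and
#' a = latency/theta, so the single positive peak sits exactly at the
#' configured latency; the kernel is truncated at `kernel_length` and
#' normalised to unit energy.
#'
#' @param config A [cvep_sim_config()].
#' @return Numeric vector sampled at `config$fs`.
#' @export
vep_kernel <- function(config) {
  stopifnot(inherits(config, "cvep_sim_config"))
  if (config$kernel_length <= config$kernel_latency)
    stop("kernel_length must exceed kernel_latency", call. = FALSE)
  n <- round(config$kernel_length * config$fs)
  t <- (seq_len(n) - 1L) / config$fs
  a <- config$kernel_latency / config$kernel_dispersion
  h <- (t / config$kernel_latency)^a * exp(a * (1 - t / config$kernel_latency))
  h[1L] <- 0
  h / sqrt(sum(h^2))
}

# Luminance-change drive: cyclic first difference of the per-sample
# opacity trace.  VEPs are driven by visual change, not absolute level,
# and the cyclic difference keeps lagged targets exact rotations of one
# another in the noise-free limit.
luminance_drive <- function(schedule, fs) {
  w <- sample_waveform(schedule, fs)
  w - c(w[length(w)], w[-length(w)])
}

# Circular convolution via FFT; kernel zero-padded to length n.
circ_conv <- function(x, h) {
  n <- length(x)
  hp <- c(h, numeric(n - length(h)))
  Re(stats::fft(stats::fft(x) * stats::fft(hp), inverse = TRUE)) / n
}

# Single-channel noise with PSD shape f^-beta + alpha bump + white floor,
# normalised to unit expected power.  White Gaussian noise is shaped in
# the frequency domain by a symmetric amplitude profile, which keeps the
# spectrum Hermitian and the inverse transform exactly real.
shaped_noise <- function(n, fs, slope, alpha_bump, white_floor) {
  k <- seq(0, n - 1)
  f <- pmin(k, n - k) * fs / n             # folded (two-sided) frequency
  shape <- numeric(n)
  pos <- f > 0
  shape[pos] <- f[pos]^(-slope) +
    alpha_bump * exp(-((f[pos] - 10)^2) / (2 * 2.5^2)) +
    white_floor
  amp <- sqrt(shape)
  amp <- amp / sqrt(mean(amp^2))           # unit expected power
  w <- stats::rnorm(n)
  Re(stats::fft(amp * stats::fft(w), inverse = TRUE)) / n
}

#' Simulate one labelled EEG trial
#'
#' The evoked source is the kernel circularly convolved with the
#' luminance-change drive of the supplied frame schedule, optionally
#' saturated, and scaled per channel by the topography; shaped noise is
#' added at the configured SNR.  Deterministic for a fixed seed.
#'
#' @param schedule A [frame_schedule()] for the target's code (already
#'   at its lag).
#' @param config A [cvep_sim_config()].
#' @param label True target index (stored, not used in synthesis).
#' @param block Training-block index (stored).
#' @param seed Trial seed; defaults to `config$seed`.
#' @param keep_components If `TRUE`, attach the separate evoked and
#'   noise matrices as attributes (used for power calibration checks).
#' @return An object of class `"eeg_trial"`: `data` (channels x samples),
#'   `label`, `block`, `fs`, `refresh_rate`.
#' @export
simulate_trial <- function(schedule, config, label = NA_integer_,
                           block = NA_integer_, seed = config$seed,
                           keep_components = FALSE) {
  stopifnot(inherits(schedule, "frame_schedule"),
            inherits(config, "cvep_sim_config"))
  fs <- config$fs
  kernel <- vep_kernel(config)
  drive <- luminance_drive(schedule, fs)
  n <- length(drive)
  if (length(kernel) >= n)
    stop("kernel support must be shorter than the trial", call. = FALSE)
  source <- circ_conv(drive, kernel)
  if (config$nonlinearity) {
    r <- stats::sd(source)
    if (r > 0) source <- r * tanh(source / r)
  }
  evoked <- outer(config$topography, source)
  p_sig <- mean(evoked^2)
  if (is.infinite(config$snr_db)) {
    noise <- matrix(0, config$channels, n)
  } else {
    if (p_sig < .Machine$double.eps)
      warning("evoked power underflows: trial is effectively pure noise")
    p_noise <- p_sig / 10^(config$snr_db / 10)
    noise <- with_seed(seed, {
      t(vapply(seq_len(config$channels), function(ch)
        shaped_noise(n, fs, config$noise_slope, config$alpha_bump,
                     config$white_floor),
        numeric(n)))
    })
    noise <- noise * sqrt(p_noise)
  }
  out <- structure(list(data = evoked + noise, label = as.integer(label),
                        block = as.integer(block), fs = fs,
                        refresh_rate = schedule$refresh_rate),
                   class = "eeg_trial")
  if (keep_components) {
    attr(out, "evoked") <- evoked
    attr(out, "noise") <- noise
  }
  out
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("EEG trial: %d channels x %d samples at %g Hz (label %s, block %s)\n",
              nrow(x$data), ncol(x$data), x$fs, x$label, x$block))
  invisible(x)
}

#' Simulate a full training session
#'
#' Blocks of one trial per target in highlight order (target 1 through
#' K, upper-left to lower-right), giving `n_blocks * K` labelled trials
#' — 48 under the defaults of 6 blocks and 8 targets.  Per-trial seeds
#' are derived deterministically from the config seed.
#'
#' @param codes A [code_set()].
#' @param config A [cvep_sim_config()].
#' @param refresh_rate 60, 120 or 240 Hz (default 60).
#' @param cycles Stimulation cycles per trial; `NULL` selects the
#'   protocol default for the pattern and rate ([default_cycles()]).
#' @param n_blocks Number of training blocks (default 6).
#' @return An object of class `"cvep_session"`.
#' @export
simulate_session <- function(codes, config = cvep_sim_config(),
                             refresh_rate = 60, cycles = NULL, n_blocks = 6) {
  stopifnot(inherits(codes, "cvep_codes"), inherits(config, "cvep_sim_config"))
  pattern <- if (codes$p == 2L) "binary" else "quintary"
  if (is.null(cycles)) cycles <- default_cycles(pattern, refresh_rate)
  n_blocks <- as.integer(n_blocks)
  schedules <- lapply(seq_len(codes$K), function(k)
    frame_schedule(codes$codes[k, ], refresh_rate, cycles, p = codes$p))
  trials <- vector("list", n_blocks * codes$K)
  i <- 0L
  for (b in seq_len(n_blocks)) {
    for (k in seq_len(codes$K)) {
      i <- i + 1L
      trials[[i]] <- simulate_trial(schedules[[k]], config, label = k,
                                    block = b,
                                    seed = derive_seed(config$seed, b, k))
    }
  }
  structure(list(trials = trials, n_blocks = n_blocks, K = codes$K,
                 fs = config$fs, codes = codes, schedules = schedules,
                 config = config, pattern = pattern,
                 refresh_rate = refresh_rate, cycles = cycles),
            class = "cvep_session")
}

#' @export
print.cvep_session <- function(x, ...) {
  cat(sprintf(paste0("Training session: %d blocks x %d targets = %d trials, ",
                     "%s pattern at %g Hz (%d samples/trial)\n"),
              x$n_blocks, x$K, length(x$trials), x$pattern, x$refresh_rate,
              ncol(x$trials[[1]]$data)))
  invisible(x)
}

#' Session labels in recording order
#' @param session A [simulate_session()] result.
#' @return Integer vector of true target labels.
#' @export
session_labels <- function(session) {
  vapply(session$trials, function(tr) tr$label, integer(1))
}

#' Simulate a continuous online EEG stream
#'
#' Alternates code-locked flicker segments (one per scripted target)
#' with pause segments of pure noise, emulating the gaze-shifting
#' phases.  The stream is delivered in 30-sample blocks, matching the
#' amplifier's transfer granularity.
#'
#' @param script Integer vector of intended target labels.
#' @param codes A [code_set()].
#' @param config A [cvep_sim_config()].
#' @param refresh_rate Monitor refresh rate (default 60).
#' @param cycles Cycles per flicker segment; `NULL` for the protocol
#'   default trial length.
#' @param flicker_seconds Flicker-segment duration; `NULL` uses the
#'   trial duration implied by `cycles`.
#' @param pause_seconds Pause between selections (default 2, the
#'   gaze-shift duration).
#' @param seed Stream seed; defaults to `config$seed`.
#' @return An object of class `"cvep_stream"`: `data`
#'   (channels x samples), `annotations` (data.frame with segment type,
#'   true label, start/end sample), `fs`, `block_size = 30`.
#' @export
simulate_stream <- function(script, codes, config = cvep_sim_config(),
                            refresh_rate = 60, cycles = NULL,
                            flicker_seconds = NULL, pause_seconds = 2,
                            seed = config$seed) {
  stopifnot(inherits(codes, "cvep_codes"), inherits(config, "cvep_sim_config"))
  script <- as.integer(script)
  if (length(script) == 0L) stop("'script' must be nonempty", call. = FALSE)
  if (any(script < 1L | script > codes$K)) stop("script labels out of range", call. = FALSE)
  pattern <- if (codes$p == 2L) "binary" else "quintary"
  if (is.null(cycles)) cycles <- default_cycles(pattern, refresh_rate)
  fs <- config$fs
  if (!is.null(flicker_seconds)) {
    cycles <- max(1L, ceiling(flicker_seconds * refresh_rate / codes$period))
  }
  n_pause <- round(pause_seconds * fs)
  segments <- list(); ann <- list(); pos <- 0L
  for (s in seq_along(script)) {
    k <- script[s]
    sch <- frame_schedule(codes$codes[k, ], refresh_rate, cycles, p = codes$p)
    tr <- simulate_trial(sch, config, label = k,
                         seed = derive_seed(seed, 7L, s))
    seg <- tr$data
    if (!is.null(flicker_seconds)) {
      n_keep <- min(ncol(seg), round(flicker_seconds * fs))
      seg <- seg[, seq_len(n_keep), drop = FALSE]
    }
    segments[[length(segments) + 1L]] <- seg
    ann[[length(ann) + 1L]] <- data.frame(type = "flicker", label = k,
                                          start = pos + 1L,
                                          end = pos + ncol(seg))
    pos <- pos + ncol(seg)
    if (n_pause > 0L && s < length(script) + 1L) {
      pn <- with_seed(derive_seed(seed, 11L, s), {
        t(vapply(seq_len(config$channels), function(ch)
          shaped_noise(n_pause, fs, config$noise_slope, config$alpha_bump,
                       config$white_floor),
          numeric(n_pause)))
      })
      # pause noise at the same absolute power as in-flicker noise
      if (!is.infinite(config$snr_db)) {
        p_sig <- mean(outer(config$topography,
                            circ_conv(luminance_drive(sch, fs),
                                      vep_kernel(config)))^2)
        pn <- pn * sqrt(p_sig / 10^(config$snr_db / 10))
      } else pn <- pn * 0
      segments[[length(segments) + 1L]] <- pn
      ann[[length(ann) + 1L]] <- data.frame(type = "pause", label = NA_integer_,
                                            start = pos + 1L,
                                            end = pos + n_pause)
      pos <- pos + n_pause
    }
  }
  structure(list(data = do.call(cbind, segments),
                 annotations = do.call(rbind, ann),
                 fs = fs, block_size = 30L),
            class = "cvep_stream")
}

#' @export
print.cvep_stream <- function(x, ...) {
  cat(sprintf("Online stream: %d channels x %d samples (%d blocks of %d), %d segments\n",
              nrow(x$data), ncol(x$data), ncol(x$data) %/% x$block_size,
              x$block_size, nrow(x$annotations)))
  invisible(x)
}

#' Split a stream into amplifier blocks
#'
#' @param stream A [simulate_stream()] result.
#' @return List of channels x 30 matrices; a trailing partial block is
#'   dropped.
#' @export
stream_blocks <- function(stream) {
  stopifnot(inherits(stream, "cvep_stream"))
  nb <- ncol(stream$data) %/% stream$block_size
  lapply(seq_len(nb), function(i) {
    cols <- ((i - 1L) * stream$block_size + 1L):(i * stream$block_size)
    stream$data[, cols, drop = FALSE]
  })
}
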