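#' Bandpass or notch filter specification
#'
#' Bandpass specs are Butterworth designs of the given overall order
#' (an "8th-order bandpass" is `order = 8`); notch specs are
#' second-order IIR notches characterised by centre frequency and
#' quality factor.
#'
#' @param kind `"bandpass"` or `"notch"`.
#' @param low,high Band edges in Hz (bandpass), with `0 < low < high`.
#' @param order Overall filter order for bandpass designs (default 8).
#' @param centre,q Notch centre frequency (Hz) and quality factor.
#' @return An object of class `"filter_spec"`.
#' @export
filter_spec <- function(kind = c("bandpass", "notch"), low = NULL, high = NULL,
                        order = 8, centre = NULL, q = 35) {
  kind <- match.arg(kind)
  if (kind == "bandpass") {
    stopifnot_scalar(low, "low", positive = TRUE)
    stopifnot_scalar(high, "high", positive = TRUE)
    if (low >= high) stop("'low' must be below 'high'", call. = FALSE)
    if (order %% 2 != 0) stop("bandpass 'order' must be even", call. = FALSE)
  } else {
    stopifnot_scalar(centre, "centre", positive = TRUE)
    stopifnot_scalar(q, "q", positive = TRUE)
  }
  structure(list(kind = kind, low = low, high = high, order = order,
                 centre = centre, q = q),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  if (x$kind == "bandpass")
    cat(sprintf("Butterworth bandpass %g-%g Hz, order %d\n", x$low, x$high, x$order))
  else
    cat(sprintf("IIR notch at %g Hz, Q = %g\n", x$centre, x$q))
  invisible(x)
}

.design_cache <- new.env(parent = emptyenv())

# Filter coefficients (signal::Arma) for a spec at sampling rate fs.
# Designs are cached: LOOCV and online decoding re-filter thousands of
# buffers with the same handful of specs.
design_filter <- function(spec, fs) {
  key <- paste(spec$kind, spec$low, spec$high, spec$order, spec$centre,
               spec$q, fs, sep = "|")
  cached <- .design_cache[[key]]
  if (!is.null(cached)) return(cached)
  ba <- design_filter_impl(spec, fs)
  .design_cache[[key]] <- ba
  ba
}

design_filter_impl <- function(spec, fs) {
  nyq <- fs / 2
  if (spec$kind == "bandpass") {
    if (spec$high >= nyq)
      stop("upper cutoff must be below the Nyquist frequency", call. = FALSE)
    ba <- signal::butter(spec$order / 2, c(spec$low, spec$high) / nyq,
                         type = "pass")
  } else {
    # constrained second-order notch (biquad), unit gain away from centre
    w0 <- 2 * pi * spec$centre / fs
    alpha <- sin(w0) / (2 * spec$q)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    ba <- signal::Arma(b = b / a[1], a = a / a[1])
  }
  if (max(Mod(polyroot(rev(ba$a)))) >= 1)
    stop("designed filter is unstable at this sampling rate", call. = FALSE)
  ba
}

apply_arma <- function(ba, x, zero_phase = FALSE) {
  # x: channels x samples matrix; filter each channel, state reset per call
  out <- x
  for (ch in seq_len(nrow(x))) {
    out[ch, ] <- if (zero_phase) signal::filtfilt(ba, x[ch, ])
                 else as.numeric(signal::filter(ba, x[ch, ]))
  }
  out
}

trial_data <- function(x) if (inherits(x, "eeg_trial")) x$data else x

rewrap <- function(x, data) {
  if (inherits(x, "eeg_trial")) { x$data <- data; x } else data
}

#' Emulate the amplifier's analog filtering
#'
#' Applies the acquisition chain used during recording: a 2–100 Hz
#' Butterworth bandpass (4th order) followed by a 50 Hz notch
#' (second-order IIR, Q = 35).  Causal by default, matching an online
#' system; `zero_phase = TRUE` gives forward-backward filtering for
#' offline use.
#'
#' @param x An `eeg_trial` or a channels x samples matrix.
#' @param fs Sampling rate; a warning is raised when not 600 Hz.
#' @param zero_phase Use forward-backward filtering.
#' @return Object of the same shape as `x`.
#' @export
amplifier_filter <- function(x, fs = if (inherits(x, "eeg_trial")) x$fs else 600,
                             zero_phase = FALSE) {
  if (fs != 600) warning("amplifier emulation is specified for fs = 600 Hz")
  d <- trial_data(x)
  bp <- design_filter(filter_spec("bandpass", 2, 100, order = 4), fs)
  nt <- design_filter(filter_spec("notch", centre = 50, q = 35), fs)
  rewrap(x, apply_arma(nt, apply_arma(bp, d, zero_phase), zero_phase))
}

#' Subband filter bank
#'
#' The default bank is the three 8th-order Butterworth bandpass filters
#' used before template matching: 8–60 Hz (alpha through gamma),
#' 12–60 Hz (beta and gamma) and 30–60 Hz (gamma only).
#'
#' @param specs List of bandpass [filter_spec()]s.
#' @return An object of class `"filter_bank"`.
#' @export
filter_bank <- function(specs) {
  if (!length(specs)) stop("bank must contain at least one filter", call. = FALSE)
  if (!all(vapply(specs, inherits, logical(1), "filter_spec")))
    stop("all bank entries must be filter_spec objects", call. = FALSE)
  structure(list(specs = specs, M = length(specs)), class = "filter_bank")
}

#' @rdname filter_bank
#' @export
default_filter_bank <- function() {
  filter_bank(list(filter_spec("bandpass", 8, 60, order = 8),
                   filter_spec("bandpass", 12, 60, order = 8),
                   filter_spec("bandpass", 30, 60, order = 8)))
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("Filter bank with %d subbands:\n", x$M))
  for (s in x$specs) { cat("  "); print(s) }
  invisible(x)
}

#' Apply every subband filter of a bank
#'
#' Each trial (or buffer) is filtered independently by every spec, with
#' filter state reset per call, so training trials, templates and online
#' buffers all see identical processing.
#'
#' @param x An `eeg_trial` or channels x samples matrix.
#' @param bank A [filter_bank()].
#' @param fs Sampling rate in Hz.
#' @param zero_phase Use forward-backward filtering (offline option);
#'   the default is causal, as required online.
#' @return List of `bank$M` filtered copies, in bank order.
#' @export
apply_filter_bank <- function(x, bank,
                              fs = if (inherits(x, "eeg_trial")) x$fs else 600,
                              zero_phase = FALSE) {
  stopifnot(inherits(bank, "filter_bank"))
  d <- trial_data(x)
  lapply(bank$specs, function(spec)
    rewrap(x, apply_arma(design_filter(spec, fs), d, zero_phase)))
}
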