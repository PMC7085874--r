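# Independent oracles and small fixtures built in code.

# O(n^2) shift-and-correlate oracle for the cyclic autocorrelation.
oracle_autocorr <- function(v, normalize = c("pearson", "inner")) {
  normalize <- match.arg(normalize)
  n <- length(v)
  vapply(0:(n - 1), function(tau) {
    shifted <- c(v[-seq_len(tau)], v[seq_len(tau)])
    if (tau == 0) shifted <- v
    switch(normalize,
           pearson = stats::cor(v, shifted),
           inner = sum(v * shifted) / sum(v * v))
  }, numeric(1))
}

# Explicit-loop evaluation of the ensemble correlation: stack the buffer
# and template projections class by class, element by element, then take
# a Pearson correlation computed from first principles.
oracle_ensemble_corr <- function(Y, templates, W, k) {
  K <- length(W)
  n_y <- ncol(Y)
  y_stack <- numeric(0)
  t_stack <- numeric(0)
  for (j in seq_len(K)) {
    for (t in seq_len(n_y)) {
      y_stack <- c(y_stack, sum(Y[, t] * W[[j]]))
      t_stack <- c(t_stack, sum(templates[[k]][, t] * W[[j]]))
    }
  }
  my <- mean(y_stack); mt <- mean(t_stack)
  sum((y_stack - my) * (t_stack - mt)) /
    sqrt(sum((y_stack - my)^2) * sum((t_stack - mt)^2))
}

# Hand-assembled model carrying arbitrary templates and weights, for
# exercising the correlation algebra without a fit.
toy_model <- function(templates, W_by_band, fs = 600, threshold = 0.15) {
  # templates[[k]][[m]], W_by_band[[k]][[m]]
  K <- length(templates); M <- length(templates[[1]])
  proj <- lapply(seq_len(M), function(m)
    lapply(seq_len(K), function(k)
      sapply(seq_len(K), function(j)
        as.numeric(crossprod(templates[[k]][[m]], W_by_band[[j]][[m]])))))
  structure(list(templates = templates, w = W_by_band,
                 proj_templates = proj, bank = NULL, fs = fs,
                 n = ncol(templates[[1]][[1]]), K = K, M = M,
                 channels = nrow(templates[[1]][[1]]),
                 threshold = threshold, block_size = 30L, gaze_shift = 2,
                 amplifier = FALSE, zero_phase = FALSE),
            class = "cvep_model")
}

# Power of x in a narrow band around f0 Hz, from the raw periodogram.
band_power <- function(x, fs, f0, half_width = 2) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= f0 - half_width & f <= f0 + half_width
  sum(p[sel])
}

# A short primitive binary sequence (x^3 + x + 1, period 7) for fast
# structural tests.
tiny_msequence <- function() {
  msequence(gen_poly(2, c(1, 1, 0)), c(0, 0, 1))
}

# Small, fast synthetic session: tiny code, few channels, short kernel.
quick_session <- function(channels = 4, snr_db = Inf, n_blocks = 2,
                          K = 3, shift_step = 2, cycles = 4, seed = 11,
                          nonlinearity = FALSE) {
  codes <- code_set(tiny_msequence(), K = K, shift_step = shift_step)
  cfg <- cvep_sim_config(channels = channels, snr_db = snr_db,
                         kernel_length = 0.1, kernel_latency = 0.05,
                         kernel_dispersion = 0.01, seed = seed,
                         nonlinearity = nonlinearity)
  suppressWarnings(
    simulate_session(codes, cfg, refresh_rate = 60, cycles = cycles,
                     n_blocks = n_blocks))
}

# One full-protocol binary/60 Hz session at 0 dB, fitted once and
# memoised for reuse across test files.
.protocol_cache <- new.env()
protocol_session <- function() {
  if (is.null(.protocol_cache$session)) {
    codes <- code_set(binary_msequence())
    cfg <- cvep_sim_config(snr_db = 0, seed = 2024)
    .protocol_cache$session <- simulate_session(codes, cfg)
    .protocol_cache$codes <- codes
    .protocol_cache$config <- cfg
  }
  .protocol_cache$session
}
protocol_model <- function() {
  if (is.null(.protocol_cache$model))
    .protocol_cache$model <- cvep_fit(protocol_session())
  .protocol_cache$model
}
protocol_codes <- function() { protocol_session(); .protocol_cache$codes }
protocol_config <- function() { protocol_session(); .protocol_cache$config }
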