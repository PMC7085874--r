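test_that("the evoked kernel has unit energy and the configured peak latency", {
  cfg <- cvep_sim_config()
  h <- vep_kernel(cfg)
  expect_equal(sum(h^2), 1, tolerance = 1e-9)
  peak_t <- (which.max(h) - 1) / cfg$fs
  expect_lt(abs(peak_t - 0.10), 0.010)
  expect_length(h, round(0.25 * cfg$fs))
  expect_true(all(h >= 0))
  expect_error(cvep_sim_config(kernel_dispersion = 0), "positive")
})

test_that("noise-free trials are the kernel circularly convolved with the drive", {
  codes <- code_set(tiny_msequence(), K = 2, shift_step = 2)
  cfg <- cvep_sim_config(channels = 3, snr_db = Inf, kernel_length = 0.1,
                         kernel_latency = 0.05, kernel_dispersion = 0.01,
                         topography = c(1, 2, 0.5))
  sch <- frame_schedule(codes$codes[1, ], 60, 4, p = 2)
  tr <- simulate_trial(sch, cfg)
  drive <- cvepr:::luminance_drive(sch, cfg$fs)
  expected <- cvepr:::circ_conv(drive, vep_kernel(cfg))
  expect_equal(tr$data[1, ], 1.0 * expected, tolerance = 1e-12)
  expect_equal(tr$data[2, ], 2.0 * expected, tolerance = 1e-12)
  expect_equal(tr$data[3, ], 0.5 * expected, tolerance = 1e-12)
})

test_that("trials are bit-identical under a fixed seed", {
  codes <- code_set(tiny_msequence(), K = 2, shift_step = 2)
  cfg <- cvep_sim_config(channels = 4, snr_db = 0, kernel_length = 0.1,
                         kernel_latency = 0.05, kernel_dispersion = 0.01)
  sch <- frame_schedule(codes$codes[1, ], 60, 4, p = 2)
  t1 <- simulate_trial(sch, cfg, seed = 77)
  t2 <- simulate_trial(sch, cfg, seed = 77)
  expect_identical(t1$data, t2$data)
  t3 <- simulate_trial(sch, cfg, seed = 78)
  expect_false(identical(t1$data, t3$data))
})

test_that("realized SNR matches the configured value within 0.5 dB on 20 s of data", {
  b <- binary_msequence()
  # ~20 s: 19 cycles of 63 frames at 60 Hz = 19.95 s
  sch <- frame_schedule(b, 60, 19)
  for (snr in c(-5, 0, 5)) {
    cfg <- cvep_sim_config(snr_db = snr, seed = 31)
    tr <- simulate_trial(sch, cfg, keep_components = TRUE)
    realized <- 10 * log10(mean(attr(tr, "evoked")^2) /
                           mean(attr(tr, "noise")^2))
    expect_lt(abs(realized - snr), 0.5)
  }
})

test_that("noise-free trials of lagged targets are exact cyclic shifts", {
  codes <- code_set(binary_msequence(), K = 4, shift_step = 4)
  cfg <- cvep_sim_config(channels = 2, snr_db = Inf)
  # at 60 Hz a 4-frame shift is exactly 40 samples
  trials <- lapply(seq_len(4), function(k)
    simulate_trial(frame_schedule(codes$codes[k, ], 60, 2, p = 2), cfg))
  n <- ncol(trials[[1]]$data)
  for (k in 2:4) {
    shift <- (k - 1) * 4 * 10  # frames * samples-per-frame
    idx <- ((seq_len(n) - 1 + shift) %% n) + 1
    expect_equal(trials[[k]]$data, trials[[1]]$data[, idx], tolerance = 1e-10)
  }
})

test_that("the saturating nonlinearity bends large responses but stays optional", {
  codes <- code_set(tiny_msequence(), K = 2, shift_step = 2)
  sch <- frame_schedule(codes$codes[1, ], 60, 4, p = 2)
  base <- cvep_sim_config(channels = 1, snr_db = Inf, kernel_length = 0.1,
                          kernel_latency = 0.05, kernel_dispersion = 0.01,
                          topography = 1)
  lin <- simulate_trial(sch, base)
  nl_cfg <- cvep_sim_config(channels = 1, snr_db = Inf, kernel_length = 0.1,
                            kernel_latency = 0.05, kernel_dispersion = 0.01,
                            topography = 1, nonlinearity = TRUE)
  nl <- simulate_trial(sch, nl_cfg)
  expect_false(isTRUE(all.equal(lin$data, nl$data)))
  expect_true(all(abs(nl$data) <= abs(lin$data) + 1e-12))
  expect_gt(cor(as.numeric(lin$data), as.numeric(nl$data)), 0.9)
})

test_that("training sessions follow the block-by-target protocol", {
  sess <- protocol_session()
  expect_length(sess$trials, 48L)
  labels <- session_labels(sess)
  blocks <- vapply(sess$trials, function(tr) tr$block, integer(1))
  for (b in 1:6) expect_setequal(labels[blocks == b], 1:8)
  expect_equal(as.integer(table(labels)), rep(6L, 8))
  expect_equal(ncol(sess$trials[[1]]$data), 1260L)
  expect_equal(nrow(sess$trials[[1]]$data), 16L)
  small <- quick_session(n_blocks = 1, K = 3)
  expect_length(small$trials, 3L)
  expect_setequal(session_labels(small), 1:3)
})

test_that("the noise spectrum follows the configured 1/f slope", {
  set.seed(60)
  fs <- 600
  for (beta in c(0.5, 1, 1.5)) {
    x <- cvepr:::shaped_noise(fs * 60, fs, beta, alpha_bump = 0, white_floor = 0)
    n <- length(x)
    p <- Mod(stats::fft(x))^2 / n
    f <- (seq_len(n) - 1) * fs / n
    sel <- f >= 2 & f <= 80
    # log-binned periodogram regression
    bins <- cut(log(f[sel]), 30)
    lp <- tapply(log(p[sel]), bins, mean)
    lf <- tapply(log(f[sel]), bins, mean)
    slope <- coef(lm(lp ~ lf))[2]
    expect_lt(abs(slope + beta), 0.2)
  }
})

test_that("online streams chunk into 30-sample blocks with faithful annotations", {
  codes <- code_set(binary_msequence())
  cfg <- cvep_sim_config(snr_db = 0, seed = 5)
  # one target, no pause: 2.1 s of flicker = 42 blocks
  st <- simulate_stream(1, codes, cfg, pause_seconds = 0)
  expect_length(stream_blocks(st), 42L)
  expect_equal(dim(stream_blocks(st)[[1]]), c(16L, 30L))
  st2 <- simulate_stream(1, codes, cfg, pause_seconds = 0)
  expect_identical(st$data, st2$data)

  st <- simulate_stream(c(2, 7), codes, cfg, pause_seconds = 2)
  ann <- st$annotations
  expect_equal(ann$type, c("flicker", "pause", "flicker", "pause"))
  expect_equal(ann$label[ann$type == "flicker"], c(2L, 7L))
  expect_equal(ann$end[4], ncol(st$data))
  expect_equal(diff(c(0, ann$end)), ann$end - ann$start + 1)
})

test_that("pause segments carry no code-locked evoked power", {
  sess <- protocol_session()
  model <- protocol_model()
  st <- simulate_stream(3, protocol_codes(), protocol_config(),
                        pause_seconds = 2, seed = 404)
  ann <- st$annotations
  pause <- st$data[, ann$start[2]:ann$end[2], drop = FALSE]
  flick <- st$data[, ann$start[1]:ann$end[1], drop = FALSE]
  lam_pause <- classify_window(pause[, 1:1200], model)$lambda
  lam_flick <- classify_window(flick[, 1:1200], model)$lambda
  expect_lt(max(abs(lam_pause)), 0.3)       # matched filters see ~nothing
  expect_gt(max(lam_flick), 0.6)            # but lock onto the flicker
  expect_equal(which.max(lam_flick), 3L)
})
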