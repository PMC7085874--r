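test_that("templates are class means with the protocol's dimensions", {
  model <- protocol_model()
  expect_equal(model$K * model$M, 24L)
  expect_equal(dim(model$templates[[1]][[1]]), c(16L, 1260L))
  # when every trial of a class is identical, the template equals the
  # filtered trial exactly
  sess <- quick_session(channels = 3, snr_db = Inf, n_blocks = 3, K = 2)
  m <- cvep_fit(sess, ridge = 1e-8)
  tr1 <- sess$trials[[1]]  # class 1, and noise-free classes repeat exactly
  f1 <- apply_filter_bank(tr1$data, default_filter_bank(), sess$fs)
  expect_equal(m$templates[[1]][[1]], f1[[1]], tolerance = 1e-10)
  expect_error(cvep_fit(list(trials = sess$trials[1], K = 2, fs = 600)),
               "every class")
})

test_that("CCA spatial filters recover a shared source and match cancor", {
  # all channels are scaled copies of one source: the filtered template
  # must correlate near-perfectly with the source
  sess <- quick_session(channels = 4, snr_db = 25, n_blocks = 3, K = 2,
                        seed = 21)
  model <- cvep_fit(sess)
  cfg <- cvep_sim_config(channels = 4, snr_db = Inf, kernel_length = 0.1,
                         kernel_latency = 0.05, kernel_dispersion = 0.01,
                         seed = 21)
  sch <- sess$schedules[[1]]
  source_tr <- simulate_trial(sch, cfg)
  src <- apply_filter_bank(source_tr$data, default_filter_bank(),
                           600)[[1]][4, ]  # any channel: same source
  proj <- as.numeric(crossprod(model$templates[[1]][[1]], model$w[[1]][[1]]))
  expect_gt(abs(cor(proj, src)), 0.999)

  # independent oracle: stats::cancor on the same concatenated series
  set.seed(33)
  X <- matrix(rnorm(3 * 400), 3)
  S <- rbind(colMeans(X), rnorm(400), rnorm(400)) + 0.1 * matrix(rnorm(3 * 400), 3)
  w_pkg <- cca_weights(X, S, ridge = 1e-10)
  cc <- stats::cancor(t(X), t(S))
  w_ref <- cc$xcoef[, 1]
  expect_gt(abs(cor(as.numeric(crossprod(X, w_pkg)),
                    as.numeric(crossprod(X, w_ref)))), 1 - 1e-6)

  # single channel: the weight reduces to a scalar
  w1 <- cca_weights(matrix(rnorm(50), 1), matrix(rnorm(50), 1))
  expect_equal(abs(w1), 1)
  expect_error(cca_weights(matrix(rnorm(10), 2), matrix(rnorm(20), 4)),
               "dimension")
})

test_that("fits are deterministic for a fixed seed", {
  m1 <- cvep_fit(quick_session(seed = 12, snr_db = 0))
  m2 <- cvep_fit(quick_session(seed = 12, snr_db = 0))
  expect_identical(coef(m1), coef(m2))
})

test_that("ensemble correlation matches the explicit-loop oracle", {
  set.seed(99)
  for (case in 1:25) {
    K <- sample(1:3, 1); ch <- sample(1:4, 1)
    n <- 20L; n_y <- sample(2:20, 1)
    templates <- lapply(seq_len(K), function(k) list(matrix(rnorm(ch * n), ch)))
    W <- lapply(seq_len(K), function(k) list(rnorm(ch)))
    model <- toy_model(templates, W)
    Y <- matrix(rnorm(ch * n_y), ch)
    for (k in seq_len(K)) {
      got <- ensemble_correlation(Y, model, k, 1)
      want <- oracle_ensemble_corr(Y, lapply(templates, function(tk)
        tk[[1]][, 1:n_y, drop = FALSE]), lapply(W, `[[`, 1), k)
      expect_equal(got, want, tolerance = 1e-12)
      expect_true(got >= -1 && got <= 1)
    }
  }
})

test_that("ensemble correlation degenerates to plain Pearson for K = M = 1", {
  set.seed(4)
  tmpl <- matrix(rnorm(2 * 30), 2)
  w <- rnorm(2)
  model <- toy_model(list(list(tmpl)), list(list(w)))
  Y <- matrix(rnorm(2 * 30), 2)
  expect_equal(ensemble_correlation(Y, model, 1, 1),
               cor(as.numeric(crossprod(Y, w)),
                   as.numeric(crossprod(tmpl, w))),
               tolerance = 1e-12)
  # buffer = the template itself: perfect self-correlation
  expect_equal(ensemble_correlation(tmpl, model, 1, 1), 1, tolerance = 1e-12)
})

test_that("correlations are invariant to positive rescaling of the weights", {
  set.seed(14)
  templates <- lapply(1:2, function(k) list(matrix(rnorm(3 * 25), 3)))
  W <- lapply(1:2, function(k) list(rnorm(3)))
  W_scaled <- lapply(W, function(wk) list(wk[[1]] * 7.3))
  Y <- matrix(rnorm(3 * 25), 3)
  m1 <- toy_model(templates, W)
  m2 <- toy_model(templates, W_scaled)
  for (k in 1:2)
    expect_equal(ensemble_correlation(Y, m1, k, 1),
                 ensemble_correlation(Y, m2, k, 1), tolerance = 1e-12)
})

test_that("subband averaging is an order-invariant mean", {
  expect_equal(subband_average(0.4), 0.4)
  expect_equal(subband_average(c(0.3, 0.6, 0.9)), 0.6)
  expect_equal(subband_average(c(0.9, 0.3, 0.6)), 0.6)
  expect_error(subband_average(numeric(0)), "no subband")
})

test_that("fixed-window classification is self-consistent and breaks ties low", {
  sess <- quick_session(channels = 4, snr_db = Inf, n_blocks = 2, K = 3)
  model <- cvep_fit(sess)
  pred <- predict(model, sess)
  expect_equal(pred$pred, pred$true)                    # 100% noise-free
  dec <- classify_window(sess$trials[[2]]$data, model)  # class 2
  expect_equal(dec$label, 2L)
  expect_true(all(abs(dec$lambda) <= 1 + 1e-12))
  # tie-break contract
  expect_equal(which.max(c(0.5, 0.5, 0.5)), 1L)
  lam <- classify_window(sess$trials[[1]]$data, model)$lambda
  expect_equal(which.max(lam), 1L)
})

test_that("trained-session predictions recover every target at full windows", {
  model <- protocol_model()
  sess <- protocol_session()
  pred <- predict(model, sess)
  expect_gt(mean(pred$pred == pred$true), 0.97)
  pred1s <- predict(model, sess, window = 1)
  expect_gt(mean(pred1s$pred == pred1s$true), 0.95)
  expect_error(predict(model, sess, window = 3), "longer than")
})

test_that("models round-trip through the JSON archive", {
  sess <- quick_session(channels = 3, snr_db = 5, n_blocks = 2, K = 2)
  m <- cvep_fit(sess)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$templates, m$templates, tolerance = 1e-12)
  expect_equal(coef(m2), coef(m), tolerance = 1e-12)
  expect_equal(m2$threshold, m$threshold)
  p1 <- predict(m, sess); p2 <- predict(m2, sess)
  expect_identical(p1$pred, p2$pred)
  expect_equal(attr(p1, "lambda"), attr(p2, "lambda"), tolerance = 1e-12)
})

test_that("the online rule slides FIFO and withholds under an infinite threshold", {
  sess <- quick_session(channels = 4, snr_db = 0, n_blocks = 2, K = 3,
                        cycles = 5, seed = 42)
  model <- cvep_fit(sess)
  n <- model$n
  blocks_per_trial <- n %/% 30L
  state <- online_state(model)
  tr <- sess$trials[[1]]
  n_steps <- 2L * blocks_per_trial
  trial_span <- (ncol(tr$data) %/% 30L) * 30L
  for (i in seq_len(n_steps)) {
    cols <- (((i - 1L) * 30L) %% trial_span) + 1:30
    step <- online_step(state, tr$data[, cols, drop = FALSE], model,
                        threshold = Inf)
    state <- step$state
    expect_false(step$decision$emitted)
    expect_equal(ncol(state$buffer), min(i * 30L, (n %/% 30L) * 30L))
  }
  expect_error(online_step(state, tr$data[, 1:10, drop = FALSE], model),
               "block must be")
})

test_that("noise-free streams always emit the true target and clear the buffer", {
  sess <- quick_session(channels = 4, snr_db = Inf, n_blocks = 2, K = 3)
  model <- cvep_fit(sess)
  for (k in 1:3) {
    tr <- sess$trials[[k]]  # block 1, class k
    state <- online_state(model)
    emitted <- NULL
    for (i in seq_len(ncol(tr$data) %/% 30L)) {
      cols <- ((i - 1L) * 30L) + 1:30
      step <- online_step(state, tr$data[, cols, drop = FALSE], model,
                          threshold = 0.15)
      state <- step$state
      if (step$decision$emitted) { emitted <- step$decision; break }
    }
    expect_equal(emitted$label, k)
    expect_equal(ncol(state$buffer), 0L)
    expect_gt(state$pause_remaining, 0L)
    # blocks during the gaze shift are discarded
    step <- online_step(state, tr$data[, 1:30, drop = FALSE], model)
    expect_false(step$decision$emitted)
    expect_equal(ncol(step$state$buffer), 0L)
  }
})

test_that("decode_stream logs one evaluation per block", {
  sess <- quick_session(channels = 4, snr_db = Inf, n_blocks = 2, K = 3)
  model <- cvep_fit(sess)
  codes <- code_set(tiny_msequence(), K = 3, shift_step = 2)
  cfg <- cvep_sim_config(channels = 4, snr_db = Inf, kernel_length = 0.1,
                         kernel_latency = 0.05, kernel_dispersion = 0.01,
                         seed = 11)
  st <- suppressWarnings(simulate_stream(2, codes, cfg, cycles = 4,
                                         pause_seconds = 0))
  log <- decode_stream(st, model)
  expect_equal(nrow(log), ncol(st$data) %/% 30L)
  first <- log[log$emitted == 1, ][1, ]
  expect_equal(first$label, 2)
})
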