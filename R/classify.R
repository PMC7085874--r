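#' Ensemble correlation of a subband buffer against one template
#'
#' Projects the buffer through the spatial filters of *all* K targets,
#' stacks the K projections into one long vector, does the same with the
#' first n_y columns of target k's template, and returns the Pearson
#' correlation of the two stacked vectors.  Stacking order is class
#' order j = 1..K on both sides; the Pearson value is invariant to the
#' common ordering.
#'
#' @param Yf A channels x n_y buffer already filtered to subband `m`.
#' @param model A [cvep_fit()] model.
#' @param k Target index whose template is scored.
#' @param m Subband index.
#' @return Scalar correlation in `[-1, 1]`.
#' @export
ensemble_correlation <- function(Yf, model, k, m) {
  n_y <- ncol(Yf)
  if (n_y < 2L) stop("buffer too short", call. = FALSE)
  if (n_y > model$n) stop("buffer longer than the templates", call. = FALSE)
  W <- do.call(cbind, lapply(seq_len(model$K), function(j) model$w[[j]][[m]]))
  y_stack <- as.numeric(crossprod(Yf, W))
  t_stack <- as.numeric(model$proj_templates[[m]][[k]][seq_len(n_y), , drop = FALSE])
  if (stats::sd(y_stack) == 0 || stats::sd(t_stack) == 0)
    stop("zero-variance projection", call. = FALSE)
  stats::cor(y_stack, t_stack)
}

#' Average subband correlations
#'
#' The per-subband ensemble correlations of one target are combined by
#' an unweighted mean over the M subbands.
#'
#' @param values Numeric vector of per-subband correlations.
#' @return Scalar mean.
#' @export
subband_average <- function(values) {
  if (!length(values)) stop("no subband values supplied", call. = FALSE)
  mean(values)
}

# lambda profile for a buffer given as a list of M subband-filtered
# copies; shared by classify_window() and the summary method.  The
# buffer projections are computed once per subband and reused for all K
# template comparisons.
lambda_from_filtered <- function(yf, model) {
  n_y <- ncol(yf[[1]])
  lam <- matrix(NA_real_, model$K, model$M)
  for (m in seq_len(model$M)) {
    W <- do.call(cbind, lapply(seq_len(model$K), function(j) model$w[[j]][[m]]))
    y_stack <- as.numeric(crossprod(yf[[m]], W))
    if (stats::sd(y_stack) == 0)
      stop("zero-variance projection", call. = FALSE)
    for (k in seq_len(model$K)) {
      t_stack <- as.numeric(
        model$proj_templates[[m]][[k]][seq_len(n_y), , drop = FALSE])
      lam[k, m] <- stats::cor(y_stack, t_stack)
    }
  }
  apply(lam, 1, subband_average)
}

#' Classify one buffer at its current length
#'
#' Applies the model's filter bank to the raw buffer, computes the
#' subband-averaged ensemble correlation for every target, and returns
#' the argmax (ties broken deterministically by the lowest index).
#' This is the fixed-window decision of the offline analysis; the online
#' variant with the threshold rule is [online_step()].
#'
#' @param Y Raw channels x n_y buffer (matrix or `eeg_trial`).
#' @param model A [cvep_fit()] model.
#' @return A `"cvep_decision"`: `emitted = TRUE`, `label`, `lambda`
#'   (length-K correlation vector), `n_y`.
#' @export
classify_window <- function(Y, model) {
  d <- trial_data(Y)
  if (model$amplifier) d <- trial_data(amplifier_filter(d, model$fs, model$zero_phase))
  yf <- lapply(model$bank$specs, function(spec)
    apply_arma(design_filter(spec, model$fs), d, model$zero_phase))
  lambda <- lambda_from_filtered(yf, model)
  new_decision(TRUE, which.max(lambda), lambda, ncol(d))
}

new_decision <- function(emitted, label, lambda, n_y) {
  structure(list(emitted = emitted,
                 label = if (emitted) as.integer(label) else NA_integer_,
                 lambda = lambda, n_y = as.integer(n_y)),
            class = "cvep_decision")
}

#' @export
print.cvep_decision <- function(x, ...) {
  if (x$emitted)
    cat(sprintf("Decision: target %d (n_y = %d, lambda = %s)\n", x$label, x$n_y,
                paste(sprintf("%.3f", x$lambda), collapse = " ")))
  else
    cat(sprintf("No decision (n_y = %d, max gap %.3f)\n", x$n_y,
                if (length(x$lambda)) {
                  s <- sort(x$lambda, decreasing = TRUE); s[1] - s[2]
                } else NA))
  invisible(x)
}

#' Online sliding-window decoder state
#'
#' Holds the growing data buffer and the gaze-shift pause counter.  The
#' buffer fills in 30-sample increments up to the template length n; once
#' full, the oldest 30-sample block is shuffled out FIFO-style for every
#' new block.
#'
#' @param model A [cvep_fit()] model.
#' @return A `"cvep_online"` state list.
#' @export
online_state <- function(model) {
  structure(list(buffer = matrix(numeric(0), model$channels, 0),
                 pause_remaining = 0L),
            class = "cvep_online")
}

#' Process one incoming 30-sample block
#'
#' Appends the block to the buffer (discarding the oldest block first
#' when full), recomputes the subband-averaged correlations, and emits a
#' decision only when the gap between the highest and the second highest
#' correlation exceeds the threshold.  On emission the buffer is cleared
#' and a 2 s gaze-shift pause begins, during which incoming blocks are
#' discarded.
#'
#' @param state A [online_state()] (as returned by the previous step).
#' @param block A channels x 30 matrix of new samples.
#' @param model A [cvep_fit()] model.
#' @param threshold Decision threshold; defaults to the model's (0.15).
#'   `Inf` disables emission entirely (the buffer then just slides).
#' @return `list(state = <updated state>, decision = <cvep_decision>)`;
#'   `decision$emitted` is `FALSE` while the rule withholds output or a
#'   pause is active.
#' @export
online_step <- function(state, block, model, threshold = model$threshold) {
  stopifnot(inherits(state, "cvep_online"))
  if (!is.matrix(block) || nrow(block) != model$channels ||
      ncol(block) != model$block_size)
    stop(sprintf("block must be %d x %d", model$channels, model$block_size),
         call. = FALSE)
  if (state$pause_remaining > 0L) {
    state$pause_remaining <- state$pause_remaining - ncol(block)
    return(list(state = state,
                decision = new_decision(FALSE, NA, numeric(0),
                                        ncol(state$buffer))))
  }
  buf <- cbind(state$buffer, block)
  while (ncol(buf) > model$n)
    buf <- buf[, -seq_len(model$block_size), drop = FALSE]
  state$buffer <- buf
  dec <- classify_window(buf, model)
  gap <- { s <- sort(dec$lambda, decreasing = TRUE); s[1] - s[2] }
  if (gap > threshold) {
    state$buffer <- matrix(numeric(0), model$channels, 0)
    state$pause_remaining <- as.integer(round(model$gaze_shift * model$fs))
    list(state = state, decision = dec)
  } else {
    list(state = state,
         decision = new_decision(FALSE, NA, dec$lambda, ncol(buf)))
  }
}

#' Decode a simulated stream block by block
#'
#' Convenience driver feeding [stream_blocks()] through [online_step()]
#' and logging every evaluation.
#'
#' @param stream A [simulate_stream()] result.
#' @param model A [cvep_fit()] model.
#' @param threshold Decision threshold (default the model's).
#' @return A data.frame log with one row per block: `time_s` (end of
#'   block), `n_y`, `emitted`, `label` and the K correlation columns
#'   `lambda_1..lambda_K` (NA during pauses).
#' @export
decode_stream <- function(stream, model, threshold = model$threshold) {
  blocks <- stream_blocks(stream)
  state <- online_state(model)
  rows <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    step <- online_step(state, blocks[[i]], model, threshold)
    state <- step$state
    dec <- step$decision
    lam <- if (length(dec$lambda)) dec$lambda else rep(NA_real_, model$K)
    rows[[i]] <- c(time_s = i * stream$block_size / model$fs,
                   n_y = dec$n_y, emitted = as.integer(dec$emitted),
                   label = dec$label, stats::setNames(lam, paste0("lambda_", seq_len(model$K))))
  }
  as.data.frame(do.call(rbind, rows))
}
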