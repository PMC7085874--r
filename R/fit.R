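#' Fit a filter-bank CCA template-matching classifier
#'
#' For every target k and subband m, the template X_k^(m) is the
#' element-wise mean of the class-k training trials after subband
#' filtering, and the spatial filter w_k^(m) is the first canonical
#' weight vector (EEG side) of a canonical-correlation analysis between
#' the class-k trials concatenated along time and the template tiled to
#' the same length.  A small ridge term stabilises the covariance
#' blocks; the sign of each weight vector is fixed so that the filtered
#' training data correlate positively with the filtered template.
#'
#' @param session A [simulate_session()] result (or any list with the
#'   same structure: `trials` of `eeg_trial`s, `K`, `fs`).
#' @param bank Subband [filter_bank()]; default the three-band
#'   8–60 / 12–60 / 30–60 Hz bank.
#' @param ridge Relative ridge added to the covariance diagonals
#'   (default 1e-8, scaled by the mean diagonal).
#' @param threshold Online decision threshold on the gap between the two
#'   highest correlations (default 0.15).
#' @param amplifier Also apply the 2–100 Hz + 50 Hz-notch acquisition
#'   chain before the bank (default `FALSE`; the subbands already lie
#'   inside that passband).
#' @param zero_phase Use forward-backward filtering throughout
#'   (offline option; default causal).
#' @return An object of class `"cvep_model"`.
#' @seealso [predict.cvep_model()], [online_state()], [cvep_loocv()]
#' @export
cvep_fit <- function(session, bank = default_filter_bank(), ridge = 1e-8,
                     threshold = 0.15, amplifier = FALSE, zero_phase = FALSE) {
  stopifnot(inherits(bank, "filter_bank"))
  labels <- session_labels(session)
  K <- session$K %||% max(labels)
  if (!all(seq_len(K) %in% labels))
    stop("every class must have at least one training trial", call. = FALSE)
  fs <- session$fs
  filtered <- lapply(session$trials, function(tr) {
    d <- trial_data(tr)
    if (amplifier) d <- trial_data(amplifier_filter(d, fs, zero_phase))
    lapply(bank$specs, function(spec)
      apply_arma(design_filter(spec, fs), d, zero_phase))
  })
  fit_from_filtered(filtered, labels, K, bank, fs, ridge, threshold,
                    amplifier, zero_phase)
}

# Core fit on pre-filtered trials: filtered[[i]][[m]] is trial i in
# subband m.  Shared with cvep_loocv(), which pre-filters once.
fit_from_filtered <- function(filtered, labels, K, bank, fs, ridge,
                              threshold, amplifier, zero_phase) {
  M <- bank$M
  n <- ncol(filtered[[1]][[1]])
  channels <- nrow(filtered[[1]][[1]])
  templates <- vector("list", K)
  w <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    templates[[k]] <- vector("list", M)
    w[[k]] <- vector("list", M)
    for (m in seq_len(M)) {
      cls <- lapply(filtered[idx], `[[`, m)
      tmpl <- Reduce(`+`, cls) / length(cls)
      X <- do.call(cbind, cls)
      TT <- do.call(cbind, rep(list(tmpl), length(cls)))
      templates[[k]][[m]] <- tmpl
      w[[k]][[m]] <- cca_weights(X, TT, ridge)
    }
  }
  # template projections X_k^(m)' w_j^(m), precomputed full length:
  # proj[[m]][[k]] is an n x K matrix with column j = t(X_k) %*% w_j
  proj <- lapply(seq_len(M), function(m)
    lapply(seq_len(K), function(k) {
      sapply(seq_len(K), function(j)
        as.numeric(crossprod(templates[[k]][[m]], w[[j]][[m]])))
    }))
  structure(list(templates = templates, w = w, proj_templates = proj,
                 bank = bank, fs = fs, n = n, K = K, M = M,
                 channels = channels, threshold = threshold,
                 block_size = 30L, gaze_shift = 2, ridge = ridge,
                 amplifier = amplifier, zero_phase = zero_phase),
            class = "cvep_model")
}

#' Ridge-regularised first canonical weight vector
#'
#' Solves the canonical-correlation problem between two multichannel
#' series (rows = channels, columns = time) and returns the first
#' canonical weight vector on the `X` side.  The covariance blocks get
#' `ridge * mean(diag)` added to their diagonals.
#'
#' @param X,Y channels x time matrices with matching dimensions.
#' @param ridge Relative ridge (default 1e-8).
#' @return Numeric weight vector of length `nrow(X)`, sign-fixed so that
#'   the projections of `X` and `Y` correlate positively.
#' @export
cca_weights <- function(X, Y, ridge = 1e-8) {
  if (!all(dim(X) == dim(Y))) stop("dimension mismatch", call. = FALSE)
  L <- ncol(X)
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  Cxx <- tcrossprod(Xc) / L
  Cyy <- tcrossprod(Yc) / L
  Cxy <- tcrossprod(Xc, Yc) / L
  d <- nrow(X)
  Cxx <- Cxx + diag(ridge * mean(diag(Cxx)) + 1e-300, d)
  Cyy <- Cyy + diag(ridge * mean(diag(Cyy)) + 1e-300, d)
  Mmat <- tryCatch(solve(Cxx, Cxy) %*% solve(Cyy, t(Cxy)),
                   error = function(e)
                     stop("rank-deficient covariance even after ridge",
                          call. = FALSE))
  eig <- eigen(Mmat)
  wx <- Re(eig$vectors[, which.max(Re(eig$values))])
  if (sum(wx^2) == 0) stop("degenerate canonical weights", call. = FALSE)
  if (stats::cor(as.numeric(crossprod(Xc, wx)),
                 as.numeric(crossprod(Yc, wx))) < 0) wx <- -wx
  wx / sqrt(sum(wx^2))
}

#' @export
print.cvep_model <- function(x, ...) {
  cat(sprintf(paste0("c-VEP filter-bank CCA model: %d targets, %d subbands, ",
                     "%d channels, templates of %d samples at %g Hz\n"),
              x$K, x$M, x$channels, x$n, x$fs))
  cat(sprintf("  online rule: 30-sample blocks, threshold %g, %g s gaze shift\n",
              x$threshold, x$gaze_shift))
  invisible(x)
}

#' @export
summary.cvep_model <- function(object, ...) {
  # self-correlation structure: lambda profile of each template against
  # the model, a quick separability diagnostic
  lam <- t(sapply(seq_len(object$K), function(k) {
    yf <- lapply(seq_len(object$M), function(m) object$templates[[k]][[m]])
    lambda_from_filtered(yf, object)
  }))
  dimnames(lam) <- list(paste0("template_", seq_len(object$K)),
                        paste0("lambda_", seq_len(object$K)))
  margin <- apply(lam, 1, function(r) {
    s <- sort(r, decreasing = TRUE); s[1] - s[2]
  })
  out <- list(model = object, lambda = lam, margin = margin)
  class(out) <- "summary.cvep_model"
  out
}

#' @export
print.summary.cvep_model <- function(x, ...) {
  print(x$model)
  cat("\nTemplate self-correlation matrix (rows: buffer = template k):\n")
  print(round(x$lambda, 3))
  cat(sprintf("\nMinimum decision margin across templates: %.3f (threshold %g)\n",
              min(x$margin), x$model$threshold))
  invisible(x)
}

#' @export
coef.cvep_model <- function(object, ...) {
  # channels x (K*M) matrix of spatial filters, columns k1m1, k1m2, ...
  out <- do.call(cbind, lapply(seq_len(object$K), function(k)
    do.call(cbind, object$w[[k]])))
  colnames(out) <- as.vector(outer(seq_len(object$M), seq_len(object$K),
                                   function(m, k) sprintf("k%d_m%d", k, m)))
  out
}

#' @export
plot.cvep_model <- function(x, subband = 1, ...) {
  t_s <- (seq_len(x$n) - 1L) / x$fs
  proj <- sapply(seq_len(x$K), function(k)
    as.numeric(crossprod(x$templates[[k]][[subband]], x$w[[k]][[subband]])))
  graphics::matplot(t_s, proj, type = "l", lty = 1,
                    xlab = "time (s)",
                    ylab = "spatially filtered template",
                    main = sprintf("Filtered templates, subband %d", subband),
                    ...)
  invisible(x)
}

#' Save / load a fitted model as JSON
#'
#' The archive holds the decision constants, the bank specification and
#' the template and spatial-filter matrices in plain text.  Template
#' projections are recomputed on load, so the file stores only primary
#' quantities.
#'
#' @param model A [cvep_fit()] model.
#' @param path Output `.json` file.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cvep_model"))
  payload <- list(
    K = model$K, M = model$M, channels = model$channels, n = model$n,
    fs = model$fs, threshold = model$threshold,
    block_size = model$block_size, gaze_shift = model$gaze_shift,
    ridge = model$ridge, amplifier = model$amplifier,
    zero_phase = model$zero_phase,
    bank = lapply(model$bank$specs, function(s)
      list(low = s$low, high = s$high, order = s$order)),
    w = model$w,
    templates = model$templates)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "columnmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path)  # keep the nested list structure as-is
  num <- function(x) as.numeric(unlist(x))
  bank <- filter_bank(lapply(p$bank, function(s)
    filter_spec("bandpass", num(s$low), num(s$high), order = num(s$order))))
  K <- num(p$K); M <- num(p$M); channels <- num(p$channels)
  templates <- lapply(seq_len(K), function(k)
    lapply(seq_len(M), function(m)
      matrix(num(p$templates[[k]][[m]]), nrow = channels)))
  w <- lapply(seq_len(K), function(k)
    lapply(seq_len(M), function(m) num(p$w[[k]][[m]])))
  proj <- lapply(seq_len(M), function(m)
    lapply(seq_len(K), function(k)
      sapply(seq_len(K), function(j)
        as.numeric(crossprod(templates[[k]][[m]], w[[j]][[m]])))))
  structure(list(templates = templates, w = w, proj_templates = proj,
                 bank = bank, fs = num(p$fs), n = num(p$n),
                 K = as.integer(K), M = as.integer(M),
                 channels = as.integer(channels),
                 threshold = num(p$threshold),
                 block_size = as.integer(num(p$block_size)),
                 gaze_shift = num(p$gaze_shift), ridge = num(p$ridge),
                 amplifier = isTRUE(unlist(p$amplifier)),
                 zero_phase = isTRUE(unlist(p$zero_phase))),
            class = "cvep_model")
}

#' Classify trials with a fitted model
#'
#' Each trial (optionally truncated to a classification window) is
#' subband-filtered and scored against every target's template by the
#' ensemble correlation; the predicted label is the argmax of the
#' subband-averaged correlations.
#'
#' @param object A [cvep_fit()] model.
#' @param newdata An `eeg_trial`, a channels x samples matrix, a list of
#'   trials, or a `cvep_session`.
#' @param window Optional classification window in seconds; trials are
#'   truncated to `round(window * fs)` samples.
#' @param ... Unused.
#' @return A data.frame with columns `pred`, `true` (NA when unknown)
#'   and `margin` (gap between the two highest correlations), with the
#'   K-column correlation matrix attached as attribute `"lambda"`.
#' @export
predict.cvep_model <- function(object, newdata, window = NULL, ...) {
  trials <- if (inherits(newdata, "cvep_session")) newdata$trials
            else if (inherits(newdata, "eeg_trial")) list(newdata)
            else if (is.matrix(newdata)) list(list(data = newdata))
            else newdata
  n_y <- if (is.null(window)) NULL else round(window * object$fs)
  res <- lapply(trials, function(tr) {
    d <- trial_data(tr)
    if (!is.null(n_y)) {
      if (n_y > ncol(d)) stop("window longer than trial", call. = FALSE)
      d <- d[, seq_len(n_y), drop = FALSE]
    }
    dec <- classify_window(d, object)
    true <- if (is.list(tr) && !is.null(tr$label)) tr$label else NA_integer_
    list(pred = dec$label, true = true, lambda = dec$lambda)
  })
  lambda <- do.call(rbind, lapply(res, `[[`, "lambda"))
  margin <- apply(lambda, 1, function(r) {
    s <- sort(r, decreasing = TRUE); s[1] - s[2]
  })
  out <- data.frame(pred = vapply(res, `[[`, integer(1), "pred"),
                    true = vapply(res, function(r) as.integer(r$true), integer(1)),
                    margin = margin)
  attr(out, "lambda") <- lambda
  out
}
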