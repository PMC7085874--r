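#' Leave-one-block-out cross-validation
#'
#' Each fold trains templates and spatial filters on all but one
#' recording block and classifies every trial of the left-out block at
#' a range of classification windows.  With the default protocol this
#' gives 6 folds of 8 validation trials each.  Because filtering is
#' causal, trials are subband-filtered once and truncated per window
#' (identical to truncating first, then filtering).
#'
#' @param session A [simulate_session()] result.
#' @param windows Classification windows in seconds
#'   (default `seq(0.1, 1, by = 0.1)`, mirroring the up-to-1-s analysis).
#' @param bank Subband [filter_bank()].
#' @param ridge,threshold,amplifier Passed to the per-fold fits.
#' @return An object of class `"cvep_loocv"`: `accuracy` (folds x
#'   windows matrix, percent), `mean`, `sd`, `windows`, `n_folds`.
#' @export
cvep_loocv <- function(session, windows = seq(0.1, 1, by = 0.1),
                       bank = default_filter_bank(), ridge = 1e-8,
                       threshold = 0.15, amplifier = FALSE) {
  labels <- session_labels(session)
  blocks <- vapply(session$trials, function(tr) tr$block, integer(1))
  fold_ids <- sort(unique(blocks))
  if (length(fold_ids) < 2L) stop("need at least 2 blocks", call. = FALSE)
  fs <- session$fs
  n <- ncol(session$trials[[1]]$data)
  n_ys <- round(windows * fs)
  if (any(n_ys > n)) stop("window longer than trial", call. = FALSE)
  if (any(n_ys < 2L)) stop("window too short", call. = FALSE)
  filtered <- lapply(session$trials, function(tr) {
    d <- trial_data(tr)
    if (amplifier) d <- trial_data(amplifier_filter(d, fs))
    lapply(bank$specs, function(spec)
      apply_arma(design_filter(spec, fs), d, FALSE))
  })
  acc <- matrix(NA_real_, length(fold_ids), length(windows),
                dimnames = list(paste0("fold_", fold_ids),
                                sprintf("%.2fs", windows)))
  for (f in seq_along(fold_ids)) {
    test <- blocks == fold_ids[f]
    model <- fit_from_filtered(filtered[!test], labels[!test], session$K,
                               bank, fs, ridge, threshold,
                               amplifier, zero_phase = FALSE)
    for (wi in seq_along(n_ys)) {
      pred <- vapply(which(test), function(i) {
        yf <- lapply(filtered[[i]], function(fm)
          fm[, seq_len(n_ys[wi]), drop = FALSE])
        which.max(lambda_from_filtered(yf, model))
      }, integer(1))
      acc[f, wi] <- 100 * mean(pred == labels[test])
    }
  }
  structure(list(accuracy = acc,
                 mean = colMeans(acc),
                 sd = apply(acc, 2, stats::sd),
                 windows = windows, n_folds = length(fold_ids),
                 pattern = session$pattern,
                 refresh_rate = session$refresh_rate),
            class = "cvep_loocv")
}

#' @export
print.cvep_loocv <- function(x, ...) {
  cat(sprintf("Leave-one-block-out CV: %d folds (%s pattern, %g Hz)\n",
              x$n_folds, x$pattern %||% "?", x$refresh_rate %||% NA))
  cat("Mean accuracy (%) by window:\n")
  print(round(x$mean, 1))
  invisible(x)
}

#' @export
plot.cvep_loocv <- function(x, ...) {
  graphics::plot(x$windows, x$mean, type = "b", ylim = c(0, 100),
                 xlab = "classification window (s)",
                 ylab = "mean accuracy (%)",
                 main = "LOOCV accuracy vs window length", ...)
  se <- x$sd / sqrt(x$n_folds)
  graphics::arrows(x$windows, x$mean - se, x$windows, x$mean + se,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 100 / 8, lty = 3)
  invisible(x)
}

#' Write an accuracy-vs-window curve as CSV
#' @param x A [cvep_loocv()] report.
#' @param path Output file.
#' @export
write_loocv_csv <- function(x, path) {
  utils::write.csv(data.frame(window_s = x$windows, mean_accuracy = x$mean,
                              sd_accuracy = x$sd),
                   path, row.names = FALSE)
  invisible(path)
}

#' Information transfer rate (bits per minute)
#'
#' The Wolpaw-style rate for a K-class selection with accuracy p and
#' mean selection time t seconds:
#' \deqn{B = [\log_2 K + p \log_2 p + (1-p)\log_2\frac{1-p}{K-1}] / (t/60).}
#' The p = 1 and p = (1-p) = 0 terms are handled by their continuous
#' limits; accuracies below chance (p < 1/K) are clipped to 0 bits/min
#' with a warning.
#'
#' @param K Number of classes (>= 2).
#' @param p Accuracy in `(0, 1]` (vectorised).
#' @param t Mean seconds per selection (> 0, vectorised).
#' @return Bits per minute.
#' @examples
#' itr(8, 1, 60)   # 3 bits/min: log2(8) bits per minute-long selection
#' itr(8, 1/8, 5)  # 0 at chance level
#' @export
itr <- function(K, p, t) {
  K <- as.integer(K)
  if (K < 2L) stop("'K' must be >= 2", call. = FALSE)
  if (any(t <= 0)) stop("'t' must be positive", call. = FALSE)
  if (any(p <= 0 | p > 1)) stop("'p' must be in (0, 1]", call. = FALSE)
  xlog2 <- function(z) ifelse(z > 0, z * log2(z), 0)
  bits <- log2(K) + xlog2(p) + ifelse(p < 1, (1 - p) * log2((1 - p) / (K - 1)), 0)
  below <- p < 1 / K
  if (any(below)) {
    warning("accuracy below chance 1/K: ITR clipped to 0")
    bits[below] <- 0
  }
  bits[bits < 0] <- 0
  bits / (t / 60)
}

#' Selection ledger of the two-step speller interface
#'
#' Reduces the eight-target letter-group interface to its selection
#' arithmetic: the 26 letters sit in four 7-letter groups (targets 1–4),
#' a letter costs one group selection (layer 1) plus one letter
#' selection (layer 2), and target 8 is UNDO.  A misclassified
#' selection is recovered by one UNDO intent followed by a restart of
#' the current letter from its group step, so a letter-stage error
#' costs three extra selections and a group-stage error two.
#'
#' @param word Uppercase word to spell.
#' @param decide Either a function `function(intended) -> label`
#'   (optionally `-> list(label, time_s)`) or an integer vector of
#'   decided labels consumed in order.
#' @param max_selections Safety cap (default 40 * nchar(word)).
#' @return A data.frame ledger with columns `intended`, `decided`,
#'   `correct`, `time_s` (NA unless the decider reports times).
#' @export
spelling_ledger <- function(word, decide, max_selections = 40L * nchar(word)) {
  letters_idx <- match(strsplit(toupper(word), "")[[1]], LETTERS)
  if (anyNA(letters_idx))
    stop("word must contain letters A-Z only", call. = FALSE)
  group_of <- (letters_idx - 1L) %/% 7L + 1L
  slot_of <- (letters_idx - 1L) %% 7L + 1L
  if (is.numeric(decide)) {
    queue <- as.integer(decide)
    qi <- 0L
    decide <- function(intended) {
      qi <<- qi + 1L
      if (qi > length(queue)) stop("decision queue exhausted", call. = FALSE)
      queue[qi]
    }
  }
  rows <- list()
  li <- 1L; stage <- "group"; need_undo <- 0L
  while (li <= length(letters_idx)) {
    if (length(rows) >= max_selections)
      stop("selection cap reached: decoder never completes the word",
           call. = FALSE)
    intended <- if (need_undo > 0L) 8L
                else if (stage == "group") group_of[li] else slot_of[li]
    res <- decide(intended)
    if (is.list(res)) { decided <- res$label; t_s <- res$time_s %||% NA_real_ }
    else { decided <- res; t_s <- NA_real_ }
    correct <- decided == intended
    rows[[length(rows) + 1L]] <-
      data.frame(intended = intended, decided = as.integer(decided),
                 correct = correct, time_s = t_s)
    if (correct) {
      if (need_undo > 0L) need_undo <- need_undo - 1L
      else if (stage == "group") stage <- "letter"
      else { li <- li + 1L; stage <- "group" }
    } else {
      need_undo <- need_undo + 1L
      stage <- "group"  # current letter restarts after recovery
    }
  }
  do.call(rbind, rows)
}

#' Simulated copy-spelling with the online decoder
#'
#' Drives the spelling interface with synthesised EEG: for each intended
#' selection a fresh code-locked flicker stream is generated and fed to
#' the online sliding-window rule until a decision is emitted (or a cap
#' of `max_seconds` of flicker is reached, after which the current
#' argmax is emitted).  Each selection's time includes the flicker time
#' actually consumed plus the 2 s gaze shift.
#'
#' @param word Word to spell (default `"POWERFUL"`).
#' @param model A [cvep_fit()] model.
#' @param codes The [code_set()] driving the stimuli.
#' @param config A [cvep_sim_config()] for the synthetic EEG.
#' @param refresh_rate Monitor refresh rate (default 60).
#' @param threshold Online decision threshold (default the model's).
#' @param max_seconds Flicker cap per selection (default 10).
#' @param seed Simulation seed; defaults to `config$seed`.
#' @return An object of class `"cvep_spelling"`: the selection `ledger`,
#'   `accuracy` (correct/total), `total_time_s`, `mean_time_s`, `itr`
#'   (bits/min) and counts.
#' @export
simulate_spelling <- function(word = "POWERFUL", model, codes,
                              config = cvep_sim_config(),
                              refresh_rate = 60,
                              threshold = model$threshold,
                              max_seconds = 10, seed = config$seed) {
  stopifnot(inherits(model, "cvep_model"), inherits(codes, "cvep_codes"))
  fs <- model$fs
  sel <- 0L
  decide <- function(intended) {
    sel <<- sel + 1L
    pattern <- if (codes$p == 2L) "binary" else "quintary"
    cyc <- max(default_cycles(pattern, refresh_rate),
               ceiling(max_seconds * refresh_rate / codes$period))
    sch <- frame_schedule(codes$codes[intended, ], refresh_rate, cyc,
                          p = codes$p)
    tr <- simulate_trial(sch, config, label = intended,
                         seed = derive_seed(seed, 13L, sel))
    n_max <- min(ncol(tr$data), round(max_seconds * fs))
    state <- online_state(model)
    label <- NA_integer_; used <- 0L
    for (b in seq_len(n_max %/% model$block_size)) {
      cols <- ((b - 1L) * model$block_size + 1L):(b * model$block_size)
      step <- online_step(state, tr$data[, cols, drop = FALSE], model,
                          threshold)
      state <- step$state
      used <- b * model$block_size
      if (step$decision$emitted) { label <- step$decision$label; break }
    }
    if (is.na(label)) {  # cap reached: fall back to the current argmax
      label <- classify_window(state$buffer, model)$label
    }
    list(label = label, time_s = used / fs + model$gaze_shift)
  }
  ledger <- spelling_ledger(word, decide)
  p <- mean(ledger$correct)
  t_mean <- mean(ledger$time_s)
  structure(list(word = toupper(word), ledger = ledger,
                 selections = nrow(ledger), correct = sum(ledger$correct),
                 accuracy = p, total_time_s = sum(ledger$time_s),
                 mean_time_s = t_mean,
                 itr = itr(model$K, max(p, 1e-12), t_mean)),
            class = "cvep_spelling")
}

#' @export
print.cvep_spelling <- function(x, ...) {
  cat(sprintf(paste0("Copy-spelling '%s': %d/%d selections correct ",
                     "(%.1f%%), %.1f s total, %.1f bits/min\n"),
              x$word, x$correct, x$selections, 100 * x$accuracy,
              x$total_time_s, x$itr))
  invisible(x)
}
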