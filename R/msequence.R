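#' Generator (feedback) polynomial for a p-ary LFSR
#'
#' Describes the feedback taps of a linear-feedback shift register over
#' GF(p).  The polynomial is stored in weight form: `coef[j]` is the weight
#' a_{j-1} of register cell R_{j-1}, so a degree-N polynomial is given by
#' its N coefficients a_0, ..., a_{N-1}.
#'
#' The binary sequence used throughout the package examples comes from
#' x^6 + x^5 + 1 (weights a_0 = 1, a_5 = 1); the quintary one from
#' x^3 + 3x + 2, stored as weights a_0 = 3, a_1 = 2, a_2 = 0 under the
#' convention G(X) = X^N - sum_j a_j X^j.
#'
#' @param p Prime base of the field (2 or 5 in the shipped defaults).
#' @param coef Integer vector `c(a_0, ..., a_{N-1})`, each in `[0, p-1]`.
#' @return An object of class `"cvep_poly"`.
#' @examples
#' gen_poly(2, c(1, 0, 0, 0, 0, 1))  # x^6 + x^5 + 1
#' gen_poly(5, c(3, 2, 0))           # x^3 + 3x + 2
#' @export
gen_poly <- function(p, coef) {
  stopifnot_scalar(p, "p", positive = TRUE)
  p <- as.integer(p)
  if (p < 2L || any(p %% seq(2L, max(2L, p - 1L)) == 0L & seq(2L, max(2L, p - 1L)) < p))
    stop("'p' must be a prime", call. = FALSE)
  coef <- as.integer(coef)
  if (length(coef) < 1L) stop("polynomial degree must be >= 1", call. = FALSE)
  if (any(coef < 0L | coef >= p))
    stop(sprintf("all coefficients must lie in [0, %d]", p - 1L), call. = FALSE)
  structure(list(p = p, degree = length(coef), coef = coef), class = "cvep_poly")
}

#' @export
print.cvep_poly <- function(x, ...) {
  terms <- c(sprintf("x^%d", x$degree),
             rev(sprintf("%d x^%d", x$coef, seq_along(x$coef) - 1L)[x$coef != 0L]))
  cat(sprintf("Generator polynomial over GF(%d), degree %d: %s\n",
              x$p, x$degree, paste(terms, collapse = " + ")))
  invisible(x)
}

#' Single clock pulse of a p-ary linear-feedback shift register
#'
#' The register holds cells (R_{N-1}, ..., R_1, R_0), given here left to
#' right.  At each pulse the content of R_i moves to R_{i-1}, R_0 is
#' emitted as the output digit, and the new R_{N-1} is the weighted sum
#' sum_j a_j R_j (old values) reduced modulo p.
#'
#' @param state Integer vector `c(R_{N-1}, ..., R_0)`, digits in `[0, p-1]`.
#' @param poly A [gen_poly()] object; its degree must equal `length(state)`.
#' @return `list(state = <new state>, digit = <emitted R_0>)`.
#' @examples
#' qp <- gen_poly(5, c(3, 2, 0))
#' lfsr_step(c(0, 3, 0), qp)  # emits 0, new state (1, 0, 3)
#' @export
lfsr_step <- function(state, poly) {
  if (!inherits(poly, "cvep_poly")) stop("'poly' must be a gen_poly()", call. = FALSE)
  state <- as.integer(state)
  if (length(state) != poly$degree)
    stop("state length must equal the polynomial degree", call. = FALSE)
  if (any(state < 0L | state >= poly$p))
    stop("state digits out of range", call. = FALSE)
  # state is (R_{N-1}, ..., R_0): R_j sits at index N - j
  feedback <- sum(poly$coef * rev(state)) %% poly$p
  list(state = c(feedback, state[-poly$degree]), digit = state[poly$degree])
}

#' Generate one period of a p-ary maximal-length sequence
#'
#' Clocks the LFSR from the given nonzero seed until the register state
#' first returns to the seed, and checks that the observed period equals
#' p^N - 1.  A shorter cycle means the polynomial is not primitive under
#' this register convention, and an error is raised rather than silently
#' returning a non-maximal sequence.
#'
#' @param poly A [gen_poly()] object.
#' @param seed Nonzero initial register state `c(R_{N-1}, ..., R_0)`.
#' @return An object of class `"msequence"` with elements `digits` (one
#'   full period), `p`, `period`, `poly` and `seed`.
#' @examples
#' msequence(gen_poly(2, c(1, 0, 0, 0, 0, 1)), c(1, 1, 0, 1, 0, 1))  # period 63
#' msequence(gen_poly(5, c(3, 2, 0)), c(0, 3, 0))                    # period 124
#' @export
msequence <- function(poly, seed) {
  if (!inherits(poly, "cvep_poly")) stop("'poly' must be a gen_poly()", call. = FALSE)
  seed <- as.integer(seed)
  if (length(seed) != poly$degree)
    stop("seed length must equal the polynomial degree", call. = FALSE)
  if (all(seed == 0L)) stop("seed must be nonzero", call. = FALSE)
  max_period <- poly$p^poly$degree - 1
  digits <- integer(max_period)
  state <- seed
  n <- 0L
  repeat {
    step <- lfsr_step(state, poly)
    n <- n + 1L
    if (n > max_period)
      stop("register did not return to the seed within p^N - 1 steps", call. = FALSE)
    digits[n] <- step$digit
    state <- step$state
    if (identical(state, seed)) break
  }
  if (n != max_period)
    stop(sprintf(paste0("observed period %d != p^N - 1 = %d: ",
                        "polynomial is not primitive under this convention"),
                 n, max_period), call. = FALSE)
  structure(list(digits = digits[seq_len(n)], p = poly$p, period = n,
                 poly = poly, seed = seed),
            class = "msequence")
}

#' @export
print.msequence <- function(x, ...) {
  cat(sprintf("%d-ary m-sequence, period %d (degree %d)\n",
              x$p, x$period, x$poly$degree))
  head_n <- min(20L, x$period)
  cat("  digits:", paste(x$digits[seq_len(head_n)], collapse = " "),
      if (x$period > head_n) "..." else "", "\n")
  invisible(x)
}

#' The study's published binary and quintary m-sequences
#'
#' Convenience constructors for the two stimulation codes used throughout:
#' the 63-bit binary sequence from x^6 + x^5 + 1 with seed
#' (R_5, ..., R_0) = (1,1,0,1,0,1), and the 124-digit quintary sequence
#' from x^3 + 3x + 2 with seed (R_2, R_1, R_0) = (0,3,0).
#'
#' @return An `"msequence"` object.
#' @export
binary_msequence <- function() {
  msequence(gen_poly(2, c(1, 0, 0, 0, 0, 1)), c(1, 1, 0, 1, 0, 1))
}

#' @rdname binary_msequence
#' @export
quintary_msequence <- function() {
  msequence(gen_poly(5, c(3, 2, 0)), c(0, 3, 0))
}

as_digits <- function(x) {
  if (inherits(x, "msequence")) x$digits else as.integer(x)
}

#' Longest cyclic run of identical digits
#'
#' Treats the sequence as periodic, so a run may wrap around the end.
#' For a degree-N binary m-sequence the answer is N (six for the 63-bit
#' code), which is why its flicker is still visually perceivable even at
#' a 240 Hz update rate.
#'
#' @param x An [msequence()] or an integer vector.
#' @return Integer run length.
#' @examples
#' max_run_length(binary_msequence())  # 6
#' max_run_length(c(1, 1, 0, 1))       # 3 (wraps around)
#' @export
max_run_length <- function(x) {
  d <- as_digits(x)
  if (length(d) == 0L) stop("sequence must be nonempty", call. = FALSE)
  if (length(unique(d)) == 1L) return(length(d))
  r <- rle(c(d, d))$lengths  # doubling captures the wraparound run
  min(max(r), length(d))
}

#' Cyclic autocorrelation of a mapped m-sequence
#'
#' Maps the digits to real values and correlates the mapped sequence with
#' each of its cyclic shifts.  Two normalisations are available:
#' `"pearson"` (the default) computes the Pearson correlation of the
#' sequence against its shift, and matches a peak-normalised presentation
#' with value exactly 1 at lag 0; `"inner"` computes the raw circular
#' inner product divided by its lag-0 value, which for a ±1-mapped binary
#' m-sequence reproduces the classical constant −1/n at every nonzero lag.
#'
#' The default mapping is the equally spaced grey-level mapping
#' digit/(p−1) used for the stimuli; any function of the digit vector can
#' be supplied instead (e.g. `function(d) ifelse(d == 1, 1, -1)`).
#'
#' Implemented via FFT-based circular correlation (O(n log n)).
#'
#' @param x An [msequence()] or integer digit vector.
#' @param mapping Function applied to the digit vector, or `NULL` for
#'   digit/(p−1).
#' @param normalize `"pearson"` or `"inner"`.
#' @param p Base, required only when `x` is a bare vector and `mapping`
#'   is `NULL`.
#' @return A `data.frame` with columns `lag` (0..period−1) and `value`.
#' @examples
#' ac <- cyclic_autocorrelation(binary_msequence(),
#'                              mapping = function(d) ifelse(d == 1, 1, -1),
#'                              normalize = "inner")
#' unique(round(ac$value[-1], 6))  # -1/63
#' @export
cyclic_autocorrelation <- function(x, mapping = NULL,
                                   normalize = c("pearson", "inner"),
                                   p = NULL) {
  normalize <- match.arg(normalize)
  d <- as_digits(x)
  if (is.null(mapping)) {
    base <- if (inherits(x, "msequence")) x$p else p
    if (is.null(base)) stop("supply 'p' or a mapping for bare digit vectors", call. = FALSE)
    v <- d / (base - 1)
  } else {
    v <- mapping(d)
  }
  n <- length(v)
  if (stats::sd(v) == 0)
    stop("mapped sequence is constant: correlation undefined", call. = FALSE)
  # circular correlation via FFT: r[tau+1] = sum_i v[i] v[(i+tau) mod n]
  f <- stats::fft(v)
  raw <- Re(stats::fft(Conj(f) * f, inverse = TRUE)) / n
  value <- switch(normalize,
    inner = raw / raw[1L],
    pearson = {
      m <- mean(v)
      (raw - n * m^2) / (sum(v^2) - n * m^2)
    })
  value[1L] <- 1  # lag 0 is the identity shift; clear FFT round-off
  data.frame(lag = seq_len(n) - 1L, value = value)
}

#' Rotate a digit vector left by `shift` positions
#' @noRd
rotate_left <- function(d, shift) {
  n <- length(d)
  shift <- shift %% n
  if (shift == 0L) d else c(d[-seq_len(shift)], d[seq_len(shift)])
}

#' Lagged code set for a K-target speller
#'
#' Target codes are left circular shifts of one base m-sequence: code i
#' (1-based) is the base rotated left by `shift_step * (i - 1)` frames, so
#' code 1 is the base itself and code 8 under the defaults is shifted by
#' 28 frames.  Element j (0-based) of code i reads
#' `base[(j + shift) mod period]`.
#'
#' @param base An [msequence()].
#' @param K Number of targets (default 8).
#' @param shift_step Shift between consecutive targets, in frames
#'   (default 4).
#' @return An object of class `"cvep_codes"`: list with `codes` (a K-row
#'   integer matrix, one code per row), `K`, `shift_step`, `p`, `period`
#'   and the base sequence.
#' @examples
#' cs <- code_set(binary_msequence())
#' identical(cs$codes[1, ], binary_msequence()$digits)
#' @export
code_set <- function(base, K = 8, shift_step = 4) {
  if (!inherits(base, "msequence")) stop("'base' must be an msequence", call. = FALSE)
  K <- as.integer(K); shift_step <- as.integer(shift_step)
  if (K < 1L || shift_step < 1L) stop("'K' and 'shift_step' must be positive", call. = FALSE)
  if (K * shift_step >= base$period)
    stop("K * shift_step must be smaller than the period (lags would collide)",
         call. = FALSE)
  codes <- t(vapply(seq_len(K) - 1L,
                    function(i) rotate_left(base$digits, i * shift_step),
                    integer(base$period)))
  if (anyDuplicated(apply(codes, 1L, paste, collapse = ",")))
    stop("shift collision: two target codes are identical", call. = FALSE)
  structure(list(codes = codes, K = K, shift_step = shift_step,
                 p = base$p, period = base$period, base = base),
            class = "cvep_codes")
}

#' @export
print.cvep_codes <- function(x, ...) {
  cat(sprintf("Code set: %d targets, %d-ary base of period %d, shift step %d frames\n",
              x$K, x$p, x$period, x$shift_step))
  invisible(x)
}

#' Write / read an m-sequence as plain text
#'
#' CSV layout: comment header lines (`# p=...`, `# coef=...`, `# seed=...`)
#' followed by a single `digit` column; `format = "json"` writes the same
#' fields as a JSON object.  Reading regenerates nothing: the stored
#' digits are returned, with provenance, and are checked against a fresh
#' regeneration from the stored polynomial and seed.
#'
#' @param x An [msequence()].
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @export
write_msequence <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!inherits(x, "msequence")) stop("'x' must be an msequence", call. = FALSE)
  if (format == "csv") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c(sprintf("# p=%d", x$p),
                 sprintf("# coef=%s", paste(x$poly$coef, collapse = ",")),
                 sprintf("# seed=%s", paste(x$seed, collapse = ",")),
                 "digit",
                 as.character(x$digits)), con)
  } else {
    jsonlite::write_json(list(p = x$p, coef = x$poly$coef, seed = x$seed,
                              digits = x$digits),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_msequence
#' @export
read_msequence <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    get <- function(key) sub(sprintf("^# %s=", key), "", grep(sprintf("^# %s=", key), hdr, value = TRUE))
    p <- as.integer(get("p"))
    coef <- as.integer(strsplit(get("coef"), ",")[[1]])
    seed <- as.integer(strsplit(get("seed"), ",")[[1]])
    digits <- as.integer(lines[-c(which(grepl("^#", lines)), grep("^digit$", lines))])
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    p <- as.integer(obj$p); coef <- as.integer(obj$coef)
    seed <- as.integer(obj$seed); digits <- as.integer(obj$digits)
  }
  out <- msequence(gen_poly(p, coef), seed)
  if (!identical(out$digits, digits))
    stop("stored digits do not match regeneration from stored provenance", call. = FALSE)
  out
}
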