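# Time-resolved TLI over the first block: sliding windows of 30
# consecutive 5.4-s epochs stepped by one epoch, and a logarithmic fit
# y = a*log(x) + b describing the learning curve.

#' Sliding-window TLI time course
#'
#' Slides a window of `window` consecutive epochs in steps of one epoch
#' over a single block's surviving epochs and computes the TLI (ratio of
#' ITC at the triplet to the tone rate) within each window. The learning
#' coordinate `x` is the number of triplets up to the window's last
#' epoch: by default counted in retained standard triplets (6 per
#' epoch); `x_convention = "presented"` instead uses the
#' experiment-level index of the last triplet as presented, including
#' excluded ones.
#'
#' @param epochs A single-channel `epoch_set` restricted to (or
#'   containing) one block; if several blocks are present, `block`
#'   selects one (default: the first).
#' @param window Epochs per window (default 30, i.e. 162 s).
#' @param block Which block to analyze.
#' @param x_convention `"retained"` or `"presented"`.
#' @param itc_mode Passed to the ITC computation.
#' @return A `learning_curve` tibble: `window`, `x`, `tli`,
#'   `itc_triplet`, `itc_tone`.
#' @export
sliding_tli <- function(epochs, window = 30L, block = NULL,
                        x_convention = c("retained", "presented"),
                        itc_mode = "standard") {
  x_convention <- match.arg(x_convention)
  if (length(epochs$channels) != 1) {
    stop("sliding_tli expects a single-channel epoch set", call. = FALSE)
  }
  if (is.null(block)) block <- epochs$info$block[1]
  sel <- which(epochs$info$block == block)
  n <- length(sel)
  if (n < window) {
    stop("block ", block, " has ", n, " epochs; at least ", window,
         " are required for one window", call. = FALSE)
  }
  sub <- epochs
  sub$data <- epochs$data[sel, , , drop = FALSE]
  info <- epochs$info[sel, ]
  ord <- order(info$epoch_in_block)
  sub$data <- sub$data[ord, , , drop = FALSE]
  info <- info[ord, ]

  Z <- epoch_fft(sub)                         # epochs x freqs
  ns <- dim(sub$data)[3]
  freqs <- (seq_len(ns %/% 2 + 1) - 1) * sub$srate / ns
  fake <- list(freqs = freqs)
  kt <- exact_bin(fake, TRIPLET_RATE_HZ)
  ks <- exact_bin(fake, TONE_RATE_HZ)

  n_win <- n - window + 1L
  out <- tibble::tibble(window = seq_len(n_win), x = NA_real_,
                        tli = NA_real_, itc_triplet = NA_real_,
                        itc_tone = NA_real_)
  for (w in seq_len(n_win)) {
    idx <- w:(w + window - 1L)
    Zw <- Z[idx, c(kt, ks), drop = FALSE]
    itc <- itc_from_phasors(Zw, itc_mode)
    out$itc_triplet[w] <- itc[1]
    out$itc_tone[w] <- itc[2]
    out$tli[w] <- itc[1] / itc[2]
    last <- idx[window]
    out$x[w] <- if (x_convention == "retained") {
      info$retained_triplets[last]
    } else info$presented_triplets[last]
  }
  attr(out, "window") <- window
  attr(out, "x_convention") <- x_convention
  class(out) <- c("learning_curve", class(out))
  out
}

#' Fit a logarithmic learning curve
#'
#' Ordinary least squares of `y = a * log(x) + b` (natural logarithm);
#' the base of the logarithm only rescales `a`.
#'
#' @param curve A `learning_curve` tibble (or any data frame with
#'   columns `x` and `tli`), or a numeric vector `x` together with `y`.
#' @param y Optional response vector when `curve` is the `x` vector.
#' @return List with `a` (slope), `b` (intercept), `rss`, and `fitted`.
#' @export
fit_log <- function(curve, y = NULL) {
  if (is.null(y)) {
    x <- curve$x
    y <- curve$tli
  } else {
    x <- curve
  }
  if (length(x) < 3) stop("need at least 3 points to fit", call. = FALSE)
  if (any(x <= 0)) stop("x must be strictly positive for log(x)", call. = FALSE)
  fit <- stats::lm(y ~ log(x))
  list(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
       rss = sum(stats::residuals(fit)^2), fitted = unname(stats::fitted(fit)))
}
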