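# Continuous-data preprocessing: bad-channel handling, Kaiser-windowed
# FIR band-pass filtering, and mastoid re-referencing.

#' Preprocessing configuration
#'
#' @param bad_channel_z Variance z-score threshold for bad-channel
#'   detection.
#' @param hp_cutoff,hp_transition High-pass cutoff and transition
#'   bandwidth in Hz.
#' @param lp_cutoff,lp_transition Low-pass cutoff and transition
#'   bandwidth in Hz.
#' @param max_passband_deviation Maximum passband ripple / stopband
#'   deviation of the Kaiser design.
#' @param reference Reference channel pair (mastoids).
#' @return A `preproc_config` list.
#' @export
preproc_config <- function(bad_channel_z = 3.0, hp_cutoff = 0.2,
                           hp_transition = 0.4, lp_cutoff = 30,
                           lp_transition = 5, max_passband_deviation = 0.001,
                           reference = c("M1", "M2")) {
  stopifnot(hp_cutoff > 0, hp_cutoff < lp_cutoff, max_passband_deviation > 0,
            length(reference) == 2)
  structure(list(bad_channel_z = bad_channel_z, hp_cutoff = hp_cutoff,
                 hp_transition = hp_transition, lp_cutoff = lp_cutoff,
                 lp_transition = lp_transition,
                 max_passband_deviation = max_passband_deviation,
                 reference = reference),
            class = "preproc_config")
}

#' Detect noisy channels by variance z-score
#'
#' Flags channels whose signal variance, z-scored across channels,
#' exceeds the threshold in absolute value.
#'
#' @param recording An `eeg_recording`.
#' @param z Threshold (default 3.0).
#' @return Character vector of flagged channel names (possibly empty).
#' @export
detect_bad_channels <- function(recording, z = 3.0) {
  if (nrow(recording$signal) < 3) {
    stop("bad-channel detection needs at least 3 channels", call. = FALSE)
  }
  v <- apply(recording$signal, 1, stats::var)
  zs <- (v - mean(v)) / stats::sd(v)
  bad <- rownames(recording$signal)[abs(zs) > z]
  if (length(bad) == nrow(recording$signal)) {
    stop("all channels flagged as bad; degenerate recording", call. = FALSE)
  }
  bad
}

#' Repair bad channels by inverse-distance weighted interpolation
#'
#' Each bad channel is replaced by the inverse-distance weighted mean of
#' its 4 nearest good channels (fewer if fewer exist). Good channels are
#' untouched.
#'
#' @param recording An `eeg_recording`.
#' @param bad Character vector of bad channel names.
#' @param k Number of nearest good neighbors to average.
#' @return The repaired recording.
#' @export
repair_channels <- function(recording, bad, k = 4) {
  if (!length(bad)) return(recording)
  stopifnot(all(bad %in% rownames(recording$signal)))
  good <- setdiff(rownames(recording$signal), bad)
  if (!length(good)) stop("no good channels left to interpolate from", call. = FALSE)
  m <- recording$montage
  pos <- as.matrix(m[match(rownames(recording$signal), m$channel), c("x", "y")])
  rownames(pos) <- rownames(recording$signal)
  for (ch in bad) {
    d <- sqrt(rowSums((pos[good, , drop = FALSE] -
                         matrix(pos[ch, ], length(good), 2, byrow = TRUE))^2))
    nn <- good[order(d)][seq_len(min(k, length(good)))]
    w <- 1 / pmax(d[order(d)][seq_len(length(nn))], 1e-12)
    w <- w / sum(w)
    recording$signal[ch, ] <- as.vector(w %*% recording$signal[nn, , drop = FALSE])
  }
  recording$repaired <- union(recording$repaired, bad)
  recording
}

# Kaiser FIR design via the standard formulae:
# A = -20*log10(dev); beta from A; order N = (A - 7.95) / (2.285 * dw),
# rounded up to the next even integer (Type I linear phase).
kaiser_fir <- function(cutoff_hz, transition_hz, dev, srate, type) {
  nyq <- srate / 2
  if (cutoff_hz >= nyq) stop("filter cutoff at or above Nyquist", call. = FALSE)
  A <- -20 * log10(dev)
  beta <- if (A > 50) 0.1102 * (A - 8.7) else if (A >= 21) {
    0.5842 * (A - 21)^0.4 + 0.07886 * (A - 21)
  } else 0
  dw <- 2 * pi * transition_hz / srate
  n <- ceiling((A - 7.95) / (2.285 * dw))
  if (n %% 2 == 1) n <- n + 1
  b <- as.numeric(signal::fir1(n, cutoff_hz / nyq, "low",
                               window = signal::kaiser(n + 1, beta),
                               scale = FALSE))
  b <- b / sum(b)                       # exact unit DC gain
  if (type == "high") {
    # spectral inversion: complementary filter with an exact null at DC
    b <- -b
    b[n / 2 + 1] <- b[n / 2 + 1] + 1
  }
  b
}

# linear-phase FIR applied with exact group-delay compensation
# (zero-phase overall); x is channels x samples
fir_apply <- function(x, b) {
  L <- ncol(x)
  nb <- length(b)
  delay <- (nb - 1) / 2
  nfft <- stats::nextn(L + nb - 1)
  B <- stats::fft(c(b, numeric(nfft - nb)))
  out <- x
  for (ch in seq_len(nrow(x))) {
    X <- stats::fft(c(x[ch, ], numeric(nfft - L)))
    y <- Re(stats::fft(X * B, inverse = TRUE)) / nfft
    out[ch, ] <- y[delay + seq_len(L)]
  }
  out
}

#' Band-pass filter a recording (high-pass then low-pass)
#'
#' Kaiser-windowed linear-phase FIR filters, applied with exact
#' group-delay compensation so the net filter is zero-phase (phase
#' distortion would corrupt downstream phase-coherence estimates).
#' Filter orders are derived from the transition bandwidths and maximum
#' deviation via the Kaiser design formula, so they adapt to the
#' sampling rate. Each block is filtered independently.
#'
#' @param recording An `eeg_recording`.
#' @param config A [preproc_config()].
#' @return The filtered recording; applied filter orders are stored in
#'   `$filter_orders`.
#' @export
bandpass <- function(recording, config = preproc_config()) {
  srate <- recording$srate
  hp <- kaiser_fir(config$hp_cutoff, config$hp_transition,
                   config$max_passband_deviation, srate, "high")
  lp <- kaiser_fir(config$lp_cutoff, config$lp_transition,
                   config$max_passband_deviation, srate, "low")
  for (bi in seq_len(nrow(recording$block_bounds))) {
    idx <- recording$block_bounds$start_sample[bi]:recording$block_bounds$end_sample[bi]
    seg <- recording$signal[, idx, drop = FALSE]
    seg <- fir_apply(seg, hp)
    seg <- fir_apply(seg, lp)
    recording$signal[, idx] <- seg
  }
  recording$filter_orders <- c(highpass = length(hp) - 1, lowpass = length(lp) - 1)
  recording
}

#' Re-reference to the algebraic mean of the two mastoids
#'
#' Subtracts the mean of the two reference channels from every channel.
#' Note this is not idempotent: after one application the mastoid mean is
#' zero, so a second application is a no-op in value but conceptually a
#' different reference.
#'
#' @param recording An `eeg_recording`.
#' @param reference Character vector of the two reference channel names.
#' @return The re-referenced recording.
#' @export
rereference <- function(recording, reference = c("M1", "M2")) {
  missing <- setdiff(reference, rownames(recording$signal))
  if (length(missing)) {
    stop("reference channel(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ref <- colMeans(recording$signal[reference, , drop = FALSE])
  recording$signal <- sweep(recording$signal, 2, ref, "-")
  recording$reference <- reference
  recording
}
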