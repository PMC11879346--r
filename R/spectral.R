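# Inter-trial coherence and the Triplet Learning Index.
#
# Epochs are Hanning-windowed, Fourier-transformed, and phase coherence
# across epochs is computed per frequency bin. With 5.4-s epochs the
# spectral resolution is 1/5.4 Hz, so the triplet rate (1.11 Hz) and
# tone rate (3.33 Hz) fall on exact bins 6 and 18.

hanning_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# epochs x n_freq complex FFT coefficients (positive frequencies) for a
# single-channel epoch set, Hanning-windowed
epoch_fft <- function(epochs, channel = 1L) {
  ns <- dim(epochs$data)[3]
  w <- hanning_window(ns)
  mat <- matrix(epochs$data[, channel, ], ncol = ns) *
    matrix(w, nrow = dim(epochs$data)[1], ncol = ns, byrow = TRUE)
  Z <- stats::mvfft(t(mat))           # ns x epochs
  t(Z[seq_len(ns %/% 2 + 1), , drop = FALSE])
}

itc_from_phasors <- function(Z, mode = "standard") {
  if (mode == "standard") {
    # modulus of the mean unit phasor across epochs (classical ITC)
    abs(colMeans(Z / pmax(abs(Z), .Machine$double.xmin)))
  } else if (mode == "complex_average") {
    # literal complex-average reading: normalized evoked amplitude
    abs(colMeans(Z)) / colMeans(abs(Z))
  } else stop("unknown itc mode: ", mode, call. = FALSE)
}

#' Compute inter-trial coherence spectra
#'
#' Separately for each block, epochs are multiplied with a Hanning
#' window, Fourier-transformed, and ITC(f) is computed as the modulus of
#' the mean unit phasor of the per-epoch phase angles. Block spectra are
#' then averaged (unweighted). `itc_mode = "complex_average"` instead
#' averages the complex spectra across epochs first and reports the
#' normalized evoked amplitude |mean(Z)| / mean(|Z|), an alternative
#' reading of phase-consistency estimation after spectral averaging.
#'
#' @param epochs A single-channel `epoch_set` (e.g. after
#'   [cluster_average()]).
#' @param itc_mode `"standard"` (default) or `"complex_average"`.
#' @param min_epochs Minimum epochs a block must contribute (default 2);
#'   blocks below this are skipped.
#' @return An `itc_spectrum`: list with `freqs`, `itc` (block-averaged),
#'   `itc_by_block` (freq x block matrix), `n_epochs` per block,
#'   `epoch_length`, `srate`, `itc_mode`.
#' @export
compute_itc <- function(epochs, itc_mode = "standard", min_epochs = 2L) {
  if (length(epochs$channels) != 1) {
    stop("compute_itc expects a single-channel epoch set; ",
         "use cluster_average() or itc_topography()", call. = FALSE)
  }
  blocks <- unique(epochs$info$block)
  use <- blocks[vapply(blocks,
                       function(b) sum(epochs$info$block == b) >= min_epochs,
                       logical(1))]
  if (!length(use)) {
    stop("no block has at least ", min_epochs, " epochs", call. = FALSE)
  }
  ns <- dim(epochs$data)[3]
  freqs <- (seq_len(ns %/% 2 + 1) - 1) * epochs$srate / ns
  itc_by_block <- matrix(NA_real_, nrow = length(freqs), ncol = length(use),
                         dimnames = list(NULL, paste0("block", use)))
  n_ep <- integer(length(use))
  for (j in seq_along(use)) {
    sel <- epochs$info$block == use[j]
    sub <- epochs
    sub$data <- epochs$data[sel, , , drop = FALSE]
    Z <- epoch_fft(sub)
    itc_by_block[, j] <- itc_from_phasors(Z, itc_mode)
    n_ep[j] <- sum(sel)
  }
  out <- list(freqs = freqs, itc = rowMeans(itc_by_block),
              itc_by_block = itc_by_block,
              n_epochs = stats::setNames(n_ep, paste0("block", use)),
              epoch_length = epochs$epoch_length, srate = epochs$srate,
              itc_mode = itc_mode)
  class(out) <- "itc_spectrum"
  out
}

# index (1-based) of the FFT bin at frequency f on the spectrum's grid;
# errors unless f sits on an exact bin
exact_bin <- function(spectrum, f, tol = 1e-6) {
  df <- spectrum$freqs[2] - spectrum$freqs[1]
  k <- f / df
  if (abs(k - round(k)) > tol * max(1, k)) {
    stop(sprintf("%.4f Hz does not fall on an exact FFT bin (resolution %.4f Hz); epoch length must be 5.4 s",
                 f, df), call. = FALSE)
  }
  as.integer(round(k)) + 1L
}

#' Extract ITC at the tone and triplet rates (and harmonics)
#'
#' Reads ITC at the exact bins of the triplet rate (1.11 Hz, bin 6), its
#' harmonics (2.22 and 4.44 Hz), and the tone rate (3.33 Hz, bin 18);
#' errors if the frequency grid does not contain these bins exactly.
#'
#' @param spectrum An `itc_spectrum`.
#' @return A list with `itc_triplet`, `itc_tone`, `harmonics` (named
#'   values at 2.22 and 4.44 Hz), and the bin indices used.
#' @export
extract_rate_bins <- function(spectrum) {
  kt <- exact_bin(spectrum, TRIPLET_RATE_HZ)
  ks <- exact_bin(spectrum, TONE_RATE_HZ)
  kh <- c(exact_bin(spectrum, 2 * TRIPLET_RATE_HZ),
          exact_bin(spectrum, 4 * TRIPLET_RATE_HZ))
  list(itc_triplet = unname(spectrum$itc[kt]),
       itc_tone = unname(spectrum$itc[ks]),
       harmonics = stats::setNames(spectrum$itc[kh], c("2.22Hz", "4.44Hz")),
       bins = c(triplet = kt - 1L, tone = ks - 1L))
}

#' Peak-vs-control-bin test across subjects
#'
#' Per subject, contrasts ITC at a peak bin against the mean ITC in
#' symmetric control bins `offset` bins away (at 5.4-s epochs, +-2 bins
#' around the tone rate are 2.96 and 3.70 Hz), then tests the contrasts
#' against zero with a one-sample one-sided t-test.
#'
#' @param spectra List of `itc_spectrum` objects, one per subject.
#' @param peak_hz Peak frequency (e.g. 3.33 or 1.11).
#' @param offset Control-bin offset in bins (default 2).
#' @return List with `t`, `df`, `p` (one-sided), `d` (Cohen's d of the
#'   contrasts), `contrasts`, `control_freqs`.
#' @export
peak_vs_neighbors <- function(spectra, peak_hz = TONE_RATE_HZ, offset = 2L) {
  if (length(spectra) < 3) stop("need at least 3 subjects", call. = FALSE)
  k <- exact_bin(spectra[[1]], peak_hz)
  nf <- length(spectra[[1]]$freqs)
  if (k - offset < 1 || k + offset > nf) {
    stop("control bins fall outside the frequency grid", call. = FALSE)
  }
  contrasts <- vapply(spectra, function(sp) {
    sp$itc[k] - mean(sp$itc[c(k - offset, k + offset)])
  }, numeric(1))
  res <- one_sample_t(contrasts, alternative = "greater")
  res$contrasts <- contrasts
  res$control_freqs <- spectra[[1]]$freqs[c(k - offset, k + offset)]
  res
}

one_sample_t <- function(x, alternative = "greater") {
  n <- length(x)
  s <- stats::sd(x)
  m <- mean(x)
  if (s == 0) {
    # degenerate: all contrasts equal; define t = 0 (p = 0.5) at m = 0,
    # +-Inf otherwise
    t <- if (m == 0) 0 else sign(m) * Inf
  } else {
    t <- m / (s / sqrt(n))
  }
  p <- if (alternative == "greater") stats::pt(t, n - 1, lower.tail = FALSE)
       else 2 * stats::pt(-abs(t), n - 1)
  list(t = t, df = n - 1, p = p, d = if (s == 0) NA_real_ else m / s)
}

#' Triplet Learning Index
#'
#' `TLI = ITC_triplet / ITC_tone`: the ratio of inter-trial coherence at
#' the triplet rate (1.11 Hz) to that at the tone rate (3.33 Hz). Values
#' above the stimulus-driven baseline indicate relatively stronger
#' tracking of the hidden triplet structure.
#'
#' @param itc_triplet,itc_tone ITC values at the two rates, or pass an
#'   `itc_spectrum` as the first argument to have both extracted.
#' @return A `tli_result`: list with `tli`, `itc_triplet`, `itc_tone`.
#' @export
compute_tli <- function(itc_triplet, itc_tone = NULL) {
  if (inherits(itc_triplet, "itc_spectrum")) {
    bins <- extract_rate_bins(itc_triplet)
    itc_tone <- bins$itc_tone
    itc_triplet <- bins$itc_triplet
  }
  if (itc_tone <= 0) {
    stop("ITC at the tone rate is zero; TLI undefined", call. = FALSE)
  }
  structure(list(tli = itc_triplet / itc_tone, itc_triplet = itc_triplet,
                 itc_tone = itc_tone), class = "tli_result")
}

#' Per-channel ITC topography
#'
#' Recomputes ITC for every channel of a multichannel epoch set and
#' extracts the triplet- and tone-rate bins, for topographic maps.
#'
#' @param epochs A multichannel `epoch_set`.
#' @param itc_mode Passed to the ITC computation.
#' @return A tibble: `channel`, `itc_triplet`, `itc_tone`, `in_cluster`.
#' @export
itc_topography <- function(epochs, itc_mode = "standard") {
  res <- lapply(seq_along(epochs$channels), function(ch) {
    sub <- epochs
    sub$data <- epochs$data[, ch, , drop = FALSE]
    sub$channels <- epochs$channels[ch]
    sp <- compute_itc(sub, itc_mode = itc_mode)
    b <- extract_rate_bins(sp)
    tibble::tibble(channel = epochs$channels[ch],
                   itc_triplet = b$itc_triplet, itc_tone = b$itc_tone)
  })
  out <- dplyr::bind_rows(res)
  out$in_cluster <- out$channel %in% FC_CLUSTER
  out
}
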