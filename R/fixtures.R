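# Deterministic miniature fixtures: hand-writable toy event tables,
# epochs with exactly controlled FFT phases, and fast mini cohorts.
# Everything regenerates bit-identically from its seed.

#' Build a deterministic toy block of triplets
#'
#' A hand-specifiable single-block event table for rule-based tests:
#' chosen triplets carry a (statistical) deviant on their final tone,
#' others contain a target tone.
#'
#' @param n_triplets Number of triplets in the block.
#' @param deviant_positions Triplet indices carrying a deviant.
#' @param target_positions Triplet indices containing a target tone (at
#'   within-triplet position 2).
#' @param triplet_ids Optional vector of triplet identities (1 or 2);
#'   defaults to alternating 1, 2, 1, 2, ...
#' @param deviant_type `"statistical"`, `"acoustic"`, or `"double"`.
#' @return An `event_table` (block 1).
#' @export
make_toy_block <- function(n_triplets, deviant_positions = integer(0),
                           target_positions = integer(0), triplet_ids = NULL,
                           deviant_type = "statistical") {
  if (any(c(deviant_positions, target_positions) > n_triplets) ||
      any(c(deviant_positions, target_positions) < 1)) {
    stop("deviant/target positions outside 1..", n_triplets, call. = FALSE)
  }
  if (length(intersect(deviant_positions, target_positions))) {
    stop("a triplet cannot carry both a deviant and a target", call. = FALSE)
  }
  if (is.null(triplet_ids)) triplet_ids <- rep_len(1:2, n_triplets)
  stopifnot(length(triplet_ids) == n_triplets, all(triplet_ids %in% 1:2))
  cb <- counterbalance_tones(1L)
  category <- rep("standard", n_triplets)
  category[deviant_positions] <- deviant_type

  tone_id <- matrix("", 3, n_triplets)
  for (k in seq_len(n_triplets)) {
    tone_id[, k] <- if (triplet_ids[k] == 1) cb$triplet1 else cb$triplet2
  }
  repl <- category %in% c("statistical", "double")
  tone_id[3, repl] <- ifelse(triplet_ids[repl] == 1, cb$triplet2[3],
                             cb$triplet1[3])
  is_target <- matrix(FALSE, 3, n_triplets)
  tone_id[2, target_positions] <- "target"
  is_target[2, target_positions] <- TRUE

  pos3 <- rep(1:3, n_triplets) == 3
  events <- tibble::tibble(
    onset = (rep(seq_len(n_triplets), each = 3) - 1) * TRIPLET_S +
      (rep(1:3, n_triplets) - 1) * SOA_S,
    block = 1L,
    tone_id = as.vector(tone_id),
    triplet_index = rep(seq_len(n_triplets), each = 3),
    triplet_id = rep(triplet_ids, each = 3),
    position = rep(1:3, n_triplets),
    is_statistical_deviant = rep(category == "statistical", each = 3) & pos3,
    is_acoustic_deviant = rep(category == "acoustic", each = 3) & pos3,
    is_double_deviant = rep(category == "double", each = 3) & pos3,
    is_target = as.vector(is_target),
    category = rep(category, each = 3)
  )
  class(events) <- c("event_table", class(events))
  events
}

#' Construct epochs with exactly controlled FFT phase at one bin
#'
#' Each epoch is a pure sinusoid at the frequency of the chosen bin, so
#' its (Hanning-windowed) FFT phase at that bin equals the constructed
#' phase exactly. Phase rules: `"identical"` (all zero; ITC = 1),
#' `"uniform"` (i.i.d. uniform on `[0, 2*pi)`; ITC follows the Rayleigh
#' null), `"alternating"` (0, pi, 0, pi, ...; ITC = 0 for even counts).
#'
#' @param n_epochs Number of epochs.
#' @param bin FFT bin index (frequency = `bin / 5.4` Hz; default 6, the
#'   triplet rate).
#' @param phase_rule One of `"identical"`, `"uniform"`, `"alternating"`.
#' @param srate Sampling rate (default 150 Hz).
#' @param seed Seed for the `"uniform"` rule.
#' @return A single-channel `epoch_set` (all epochs in block 1).
#' @export
make_phase_epochs <- function(n_epochs, bin = 6L,
                              phase_rule = c("identical", "uniform",
                                             "alternating"),
                              srate = 150, seed = 1L) {
  phase_rule <- match.arg(phase_rule)
  ep_len <- 5.4
  ns <- round(ep_len * srate)
  f <- bin / ep_len
  phases <- switch(phase_rule,
                   identical = rep(0, n_epochs),
                   alternating = rep(c(0, pi), length.out = n_epochs),
                   uniform = {
                     set.seed(seed)
                     stats::runif(n_epochs, 0, 2 * pi)
                   })
  t <- (seq_len(ns) - 1) / srate
  data <- array(NA_real_, dim = c(n_epochs, 1, ns))
  for (e in seq_len(n_epochs)) data[e, 1, ] <- cos(2 * pi * f * t + phases[e])
  structure(list(data = data, channels = "cluster", srate = srate,
                 epoch_length = ep_len, triplets_per_epoch = 6L,
                 info = tibble::tibble(epoch = seq_len(n_epochs), block = 1L,
                                       epoch_in_block = seq_len(n_epochs),
                                       retained_triplets = 6L * seq_len(n_epochs),
                                       presented_triplets = 6L * seq_len(n_epochs)),
                 phases = phases),
            class = "epoch_set")
}

#' Simulate a fast miniature cohort
#'
#' A small cohort (default 8 + 8 subjects, 2 short blocks at 150 Hz)
#' for end-to-end runs in seconds to minutes. The `"null"` preset has no
#' group difference and no brain-behavior correlation; the
#' `"paper_like"` preset injects a standardized latent TLI group
#' difference of 0.64 (control > dyslexia), extra tone-rate phase jitter
#' in the control group (so dyslexia tone-rate ITC is higher), and a
#' TLI-spelling correlation of 0.35 with reading scores uncorrelated.
#'
#' @param preset `"null"` or `"paper_like"`.
#' @param seed Integer seed.
#' @param n_per_group Subjects per group.
#' @param n_blocks,triplets_per_block Sequence size.
#' @param srate Sampling rate in Hz.
#' @param simulate_signal Passed through to [simulate_cohort()].
#' @return See [simulate_cohort()].
#' @export
make_mini_cohort <- function(preset = c("null", "paper_like"), seed = 1L,
                             n_per_group = 8L, n_blocks = 2L,
                             triplets_per_block = 80L, srate = 150,
                             simulate_signal = TRUE) {
  preset <- match.arg(preset)
  eff <- if (preset == "null") {
    cohort_effects(d = 0, rho = 0, rho_reading = 0, tone_lock_diff = 0)
  } else {
    cohort_effects(d = 0.64, rho = 0.35, rho_reading = 0)
  }
  spec <- sequence_spec(n_blocks = n_blocks,
                        triplets_per_block = triplets_per_block,
                        targets_per_block = 2L, seed = seed)
  simulate_cohort(n_per_group, n_per_group, effect_spec = eff, seed = seed,
                  spec = spec, srate = srate,
                  simulate_signal = simulate_signal)
}
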