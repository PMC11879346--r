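# Shared builders for toy recordings and small simulation runs.

# deterministic toy recording: signal filled from a function of the
# sample index, aligned with an event table at the given rate
toy_recording <- function(events, srate = 150, channels = NULL,
                          fill = function(i) seq_along(i)) {
  montage <- default_montage()
  if (!is.null(channels)) montage <- montage[montage$channel %in% channels, ]
  blocks <- sort(unique(events$block))
  n_tr <- max(events$triplet_index)
  span <- round(0.9 * srate)
  L <- n_tr * span + round(0.6 * srate)
  sig_list <- list()
  bounds <- tibble::tibble(block = blocks, start_sample = NA_integer_,
                           end_sample = NA_integer_)
  off <- 0L
  for (bi in seq_along(blocks)) {
    base <- matrix(rep(fill(seq_len(L)), each = nrow(montage)),
                   nrow = nrow(montage))
    sig_list[[bi]] <- base
    bounds$start_sample[bi] <- off + 1L
    bounds$end_sample[bi] <- off + L
    off <- off + L
  }
  rec <- list(signal = do.call(cbind, sig_list), srate = srate,
              montage = montage, events = events, block_bounds = bounds)
  rownames(rec$signal) <- montage$channel
  class(rec) <- "eeg_recording"
  rec
}

# stack two epoch arrays along the epoch dimension
abind_epochs <- function(a, b) {
  out <- array(NA_real_, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# fast single-subject measurement: simulate one subject and return the
# pipeline TLI result
measure_subject <- function(triplet_lock, tone_lock = 0.8, seed = 1,
                            learn_a = 0.25, learn_b = 0, n_blocks = 1,
                            triplets_per_block = 120, srate = 150,
                            noise_amplitude = 10) {
  spec <- sequence_spec(n_blocks = n_blocks,
                        triplets_per_block = triplets_per_block,
                        targets_per_block = 2L, seed = seed)
  ev <- generate_sequence(spec)
  prof <- subject_profile(seed = seed + 500, triplet_lock = triplet_lock,
                          tone_lock = tone_lock, learn_a = learn_a,
                          learn_b = learn_b,
                          noise_amplitude = noise_amplitude,
                          artifact_rate = 0)
  rec <- simulate_recording(ev, prof, srate = srate)
  process_subject(rec, pipeline_config())
}
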