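# Epoch construction: keep only standard triplets, excise everything
# else from the continuous data, de-mean per tone, cut non-overlapping
# 5.4-s epochs (6 triplets) within blocks, reject high-amplitude epochs.

#' Select standard triplets for analysis
#'
#' Drops every triplet that (i) contains any deviant (statistical,
#' acoustic, or double), (ii) immediately follows a deviant triplet
#' within the same block, or (iii) contains a target tone. When several
#' rules apply, the recorded reason follows the priority
#' deviant > post_deviant > target.
#'
#' @param events An `event_table`.
#' @return A tibble with one row per triplet: `block`, `triplet_index`,
#'   `keep`, `reason` (`NA` for kept triplets).
#' @export
select_standard_triplets <- function(events) {
  first <- events[events$position == 1L, ]
  has_target <- tapply(events$is_target,
                       list(events$block, events$triplet_index), any)
  sel <- tibble::tibble(
    block = first$block,
    triplet_index = first$triplet_index,
    deviant = first$category != "standard",
    target = mapply(function(b, k) has_target[as.character(b), as.character(k)],
                    first$block, first$triplet_index)
  )
  sel <- sel[order(sel$block, sel$triplet_index), ]
  post_dev <- logical(nrow(sel))
  for (b in unique(sel$block)) {
    i <- which(sel$block == b)
    post_dev[i] <- c(FALSE, sel$deviant[i][-length(i)])
  }
  sel$reason <- rep(NA_character_, nrow(sel))
  sel$reason[sel$target] <- "target"
  sel$reason[post_dev] <- "post_deviant"
  sel$reason[sel$deviant] <- "deviant"
  sel$keep <- is.na(sel$reason)
  sel[, c("block", "triplet_index", "keep", "reason")]
}

# samples per tone window; requires the SOA to fall on an integer number
# of samples so that tone windows tile the excised stream exactly
tone_samples <- function(srate) {
  n <- SOA_S * srate
  if (abs(n - round(n)) > 1e-9) {
    stop("sampling rate ", srate, " Hz does not place the 300 ms SOA on an ",
         "integer number of samples; use a multiple of 10/3 Hz (e.g. 150, ",
         "250, 500)", call. = FALSE)
  }
  as.integer(round(n))
}

#' Excise excluded triplets and concatenate the standard-only stream
#'
#' Removes every to-be-excluded triplet's 0.9-s span from the continuous
#' data and concatenates the retained spans in original order within each
#' block. Retained samples are copied bit-identically. A registry maps
#' every retained tone to its onset sample in the new stream.
#'
#' @param recording An `eeg_recording`.
#' @param selection Output of [select_standard_triplets()] computed from
#'   `recording$events`.
#' @return A `standard_stream`: list with `signal` (channels x samples),
#'   `srate`, `montage`, `registry` (tibble: block, triplet_index,
#'   position, sample, retained_triplet, presented_triplet), and
#'   `block_bounds` in the new sample space.
#' @export
excise_and_concatenate <- function(recording, selection) {
  srate <- recording$srate
  ntone <- tone_samples(srate)
  nspan <- 3L * ntone
  kept <- selection[selection$keep, ]
  if (!nrow(kept)) stop("no standard triplets retained", call. = FALSE)

  pieces <- list()
  reg <- list()
  bounds <- list()
  offset <- 0L
  tpb <- max(recording$events$triplet_index)
  retained_count <- 0L
  for (bi in seq_len(nrow(recording$block_bounds))) {
    b <- recording$block_bounds$block[bi]
    bstart <- recording$block_bounds$start_sample[bi]
    bend <- recording$block_bounds$end_sample[bi]
    kb <- kept$triplet_index[kept$block == b]
    if (!length(kb)) next
    idx <- integer(0)
    for (k in sort(kb)) {
      s0 <- bstart + (k - 1L) * nspan
      if (s0 + nspan - 1L > bend) {
        stop("kept triplet ", k, " of block ", b,
             " extends beyond the recorded samples", call. = FALSE)
      }
      idx <- c(idx, s0:(s0 + nspan - 1L))
    }
    pieces[[length(pieces) + 1L]] <- recording$signal[, idx, drop = FALSE]
    nk <- length(kb)
    retained <- retained_count + seq_len(nk)
    retained_count <- retained_count + nk
    reg[[length(reg) + 1L]] <- tibble::tibble(
      block = b,
      triplet_index = rep(sort(kb), each = 3),
      position = rep(1:3, nk),
      sample = offset + (rep(seq_len(nk) - 1L, each = 3)) * nspan +
        (rep(1:3, nk) - 1L) * ntone + 1L,
      retained_triplet = rep(retained, each = 3),
      presented_triplet = rep((b - 1L) * tpb + sort(kb), each = 3)
    )
    bounds[[length(bounds) + 1L]] <- tibble::tibble(
      block = b, start_sample = offset + 1L, end_sample = offset + nk * nspan)
    offset <- offset + nk * nspan
  }
  out <- list(signal = do.call(cbind, pieces), srate = srate,
              montage = recording$montage,
              registry = dplyr::bind_rows(reg),
              block_bounds = dplyr::bind_rows(bounds))
  class(out) <- "standard_stream"
  out
}

#' De-mean the stream at the level of single tones
#'
#' Subtracts, per channel, the mean over each tone's 0-300 ms window
#' (tone plus silent interval), attenuating baseline discontinuities
#' where excluded triplets were excised.
#'
#' @param stream A `standard_stream`.
#' @return The de-meaned stream.
#' @export
demean_per_tone <- function(stream) {
  ntone <- tone_samples(stream$srate)
  s <- sort(stream$registry$sample)
  if (length(s) * ntone != ncol(stream$signal) ||
      any(diff(s) != ntone) || s[1] != 1L) {
    stop("tone registry does not tile the stream exactly", call. = FALSE)
  }
  L <- ncol(stream$signal)
  win <- rep(seq_len(L / ntone), each = ntone)
  for (ch in seq_len(nrow(stream$signal))) {
    mu <- tapply(stream$signal[ch, ], win, mean)
    stream$signal[ch, ] <- stream$signal[ch, ] - mu[win]
  }
  stream
}

#' Cut non-overlapping epochs of six triplets
#'
#' Groups consecutive retained triplets within each block into epochs of
#' `triplets_per_epoch` triplets (5.4 s at the default 6); leftover
#' triplets at a block end are discarded. Epoch starts coincide with
#' triplet-initial tone onsets.
#'
#' @param stream A de-meaned `standard_stream`.
#' @param triplets_per_epoch Triplets per epoch (default 6).
#' @return An `epoch_set`: list with `data` (epochs x channels x
#'   samples), `channels`, `srate`, `epoch_length` seconds, and `info`
#'   (tibble: epoch, block, epoch_in_block, retained_triplets = 6 x index
#'   of the epoch's last retained triplet within its block,
#'   presented_triplets = experiment-wide index of the last covered
#'   triplet as presented).
#' @export
cut_epochs <- function(stream, triplets_per_epoch = 6L) {
  ntone <- tone_samples(stream$srate)
  nspan <- 3L * ntone
  ep_samp <- triplets_per_epoch * nspan
  first_tones <- stream$registry[stream$registry$position == 1L, ]
  data_list <- list()
  info <- list()
  e <- 0L
  for (b in unique(stream$block_bounds$block)) {
    fb <- first_tones[first_tones$block == b, ]
    fb <- fb[order(fb$sample), ]
    n_full <- nrow(fb) %/% triplets_per_epoch
    if (n_full == 0) next
    for (w in seq_len(n_full)) {
      e <- e + 1L
      tri <- (w - 1L) * triplets_per_epoch + seq_len(triplets_per_epoch)
      s0 <- fb$sample[tri[1]]
      data_list[[e]] <- stream$signal[, s0:(s0 + ep_samp - 1L), drop = FALSE]
      info[[e]] <- tibble::tibble(
        epoch = e, block = b, epoch_in_block = w,
        retained_triplets = triplets_per_epoch * w,
        presented_triplets = fb$presented_triplet[tri[triplets_per_epoch]])
    }
  }
  if (e == 0L) {
    data <- array(numeric(0), dim = c(0, nrow(stream$signal), ep_samp))
  } else {
    data <- array(NA_real_, dim = c(e, nrow(stream$signal), ep_samp))
    for (k in seq_len(e)) data[k, , ] <- data_list[[k]]
  }
  out <- list(data = data, channels = rownames(stream$signal),
              srate = stream$srate,
              epoch_length = ep_samp / stream$srate,
              triplets_per_epoch = triplets_per_epoch,
              info = if (e) dplyr::bind_rows(info) else
                tibble::tibble(epoch = integer(), block = integer(),
                               epoch_in_block = integer(),
                               retained_triplets = integer(),
                               presented_triplets = integer()))
  class(out) <- "epoch_set"
  out
}

#' Reject epochs by peak-to-peak amplitude
#'
#' Drops any epoch whose peak-to-peak difference (max minus min over the
#' epoch's samples, on any channel present in the set) exceeds the
#' threshold. Apply after [cluster_average()] to evaluate the criterion
#' on the analysis signal, or before it for a per-channel criterion.
#'
#' @param epochs An `epoch_set`.
#' @param threshold Peak-to-peak threshold in microvolts (default 300).
#' @return The pruned `epoch_set`; the number of dropped epochs is stored
#'   in `$n_rejected`.
#' @export
reject_epochs <- function(epochs, threshold = 300) {
  n <- dim(epochs$data)[1]
  if (n == 0) return(epochs)
  p2p <- vapply(seq_len(n), function(e) {
    max(vapply(seq_along(epochs$channels), function(ch) {
      x <- epochs$data[e, ch, ]
      max(x) - min(x)
    }, numeric(1)))
  }, numeric(1))
  keep <- p2p <= threshold
  if (!any(keep)) {
    stop("all ", n, " epochs exceed the ", threshold,
         " uV peak-to-peak threshold", call. = FALSE)
  }
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$info <- epochs$info[keep, ]
  epochs$n_rejected <- sum(!keep)
  epochs
}

#' Average epochs over the fronto-central electrode cluster
#'
#' Unweighted mean, per sample, across the nine fronto-central channels
#' (F1, F2, Fz, FC1, FC2, FCz, C1, C2, Cz), yielding a single virtual
#' channel.
#'
#' @param epochs A multichannel `epoch_set`.
#' @param channels Channels to average (default the 9-channel cluster).
#' @return An `epoch_set` with one channel named `"cluster"`.
#' @export
cluster_average <- function(epochs, channels = FC_CLUSTER) {
  missing <- setdiff(channels, epochs$channels)
  if (length(missing)) {
    stop("channel(s) missing from epochs: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(channels, epochs$channels)
  n <- dim(epochs$data)[1]
  ns <- dim(epochs$data)[3]
  avg <- array(NA_real_, dim = c(n, 1, ns))
  for (e in seq_len(n)) {
    m <- matrix(epochs$data[e, idx, ], nrow = length(idx))
    avg[e, 1, ] <- colMeans(m)
  }
  epochs$data <- avg
  epochs$channels <- "cluster"
  epochs
}
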