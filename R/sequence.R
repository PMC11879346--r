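# Triplet-structured tone sequence design.
#
# Six tones partition into two hidden triplets; triplets are drawn i.i.d.
# (50% each) so transitional probabilities are 100% within a triplet
# (position 1 -> 2), 90% from position 2 -> 3 under the default deviant
# rates, and 50% across triplet boundaries. Tones play at a constant
# 3.33 Hz (SOA 300 ms), giving a triplet rate of 1.11 Hz.

SOA_S <- 0.300
TRIPLET_S <- 0.900
TONE_RATE_HZ <- 1 / SOA_S
TRIPLET_RATE_HZ <- 1 / TRIPLET_S

#' Specify a triplet-structured tone sequence
#'
#' Captures the design parameters of the passive statistical-learning
#' stream: six tones arranged into two triplets of three, presented at a
#' constant stimulus onset asynchrony of `tone_duration + isi` = 300 ms,
#' with occasional deviants on triplet-final tones and rare target tones
#' for the cover task.
#'
#' @param n_blocks Number of experimental blocks.
#' @param triplets_per_block Triplets per block.
#' @param tone_duration Tone duration in seconds.
#' @param isi Silent inter-stimulus interval in seconds.
#' @param p_statistical,p_acoustic,p_double Fractions of triplets per block
#'   carrying a statistical deviant (triplet-final tone replaced by the
#'   other triplet's final tone), an acoustic deviant (same tone from a
#'   different location), or both combined. Categories are mutually
#'   exclusive and assigned by exact counts (`round(p * triplets_per_block)`).
#' @param targets_per_block Tones per block replaced by the target tone,
#'   balanced across within-triplet positions over the experiment.
#' @param seed Integer seed; required for reproducible generation.
#' @param counterbalance_id Integer selecting one of six tone-to-triplet
#'   assignment schemes (cyclic rotations of the tone labels).
#' @return A `sequence_spec` object (list).
#' @export
sequence_spec <- function(n_blocks = 6L, triplets_per_block = 400L,
                          tone_duration = 0.220, isi = 0.080,
                          p_statistical = 0.08, p_acoustic = 0.18,
                          p_double = 0.02, targets_per_block = 8L,
                          seed = 1L, counterbalance_id = 1L) {
  spec <- list(
    n_blocks = as.integer(n_blocks),
    triplets_per_block = as.integer(triplets_per_block),
    tone_duration = tone_duration, isi = isi,
    n_tones = 6L,
    p_statistical = p_statistical, p_acoustic = p_acoustic,
    p_double = p_double,
    targets_per_block = as.integer(targets_per_block),
    seed = as.integer(seed),
    counterbalance_id = as.integer(counterbalance_id)
  )
  class(spec) <- "sequence_spec"
  validate_sequence_spec(spec)
  spec
}

validate_sequence_spec <- function(spec) {
  stopifnot(inherits(spec, "sequence_spec"))
  if (spec$n_blocks < 1L || spec$triplets_per_block < 1L) {
    stop("need at least one block of at least one triplet", call. = FALSE)
  }
  soa <- spec$tone_duration + spec$isi
  if (abs(soa - SOA_S) > 1e-9) {
    stop("tone_duration + isi must equal the 0.300 s stimulus onset asynchrony",
         call. = FALSE)
  }
  p <- c(spec$p_statistical, spec$p_acoustic, spec$p_double)
  if (any(p < 0) || sum(p) >= 1) {
    stop("deviant probabilities must be non-negative and sum to < 1", call. = FALSE)
  }
  counts <- deviant_counts(spec)
  if (sum(counts) > spec$triplets_per_block) {
    stop("deviant counts after rounding exceed triplets_per_block; ",
         "the block cannot be partitioned", call. = FALSE)
  }
  n_std <- spec$triplets_per_block - sum(counts)
  if (spec$targets_per_block > n_std) {
    stop("not enough standard triplets to host ", spec$targets_per_block,
         " targets", call. = FALSE)
  }
  invisible(spec)
}

# exact per-block deviant counts (statistical, acoustic, double)
deviant_counts <- function(spec) {
  c(statistical = round(spec$p_statistical * spec$triplets_per_block),
    acoustic = round(spec$p_acoustic * spec$triplets_per_block),
    double = round(spec$p_double * spec$triplets_per_block))
}

# counterbalancing scheme: cyclic rotation of the six tone labels by
# (id - 1) positions; first three rotated labels form triplet 1.
counterbalance_tones <- function(counterbalance_id) {
  tones <- LETTERS[1:6]
  shift <- (counterbalance_id - 1L) %% 6L
  rot <- tones[((seq_len(6) - 1L + shift) %% 6L) + 1L]
  list(triplet1 = rot[1:3], triplet2 = rot[4:6])
}

#' Generate the tone-level event table for a sequence specification
#'
#' Draws triplet identities i.i.d. (probability 0.5 each, immediate
#' repetitions allowed), assigns deviant categories by exact counts per
#' block (mutually exclusive: statistical, acoustic, double, standard),
#' replaces triplet-final tones for statistical and double deviants, and
#' places `targets_per_block` target tones in standard, deviant-free
#' triplets (at most one per triplet), balanced across within-triplet
#' positions over the whole experiment.
#'
#' @param spec A [sequence_spec()].
#' @return An `event_table`: a tibble with one row per tone (`onset`
#'   seconds from block start, `block`, `tone_id`, `triplet_index`,
#'   `triplet_id`, `position`, deviant/target flags) carrying the spec as
#'   an attribute.
#' @export
generate_sequence <- function(spec) {
  validate_sequence_spec(spec)
  set.seed(spec$seed)
  cb <- counterbalance_tones(spec$counterbalance_id)
  counts <- deviant_counts(spec)
  n_tr <- spec$triplets_per_block

  # target positions balanced over the experiment
  n_targets <- spec$targets_per_block * spec$n_blocks
  target_pos_pool <- sample(rep(1:3, length.out = n_targets))

  blocks <- vector("list", spec$n_blocks)
  for (b in seq_len(spec$n_blocks)) {
    triplet_id <- sample(1:2, n_tr, replace = TRUE)
    category <- rep("standard", n_tr)
    if (sum(counts) > 0) {
      dev_idx <- sample.int(n_tr, sum(counts))
      category[dev_idx] <- rep(names(counts), counts)
    }

    tone_id <- matrix("", nrow = 3, ncol = n_tr)
    for (k in seq_len(n_tr)) {
      tone_id[, k] <- if (triplet_id[k] == 1L) cb$triplet1 else cb$triplet2
    }
    # statistical and double deviants: final tone replaced by the other
    # triplet's final tone (low transitional probability)
    repl <- category %in% c("statistical", "double")
    if (any(repl)) {
      other_final <- ifelse(triplet_id[repl] == 1L, cb$triplet2[3], cb$triplet1[3])
      tone_id[3, repl] <- other_final
    }

    # targets live in standard triplets only, one per triplet
    is_target <- matrix(FALSE, nrow = 3, ncol = n_tr)
    if (spec$targets_per_block > 0) {
      host <- sample(which(category == "standard"), spec$targets_per_block)
      pos <- target_pos_pool[(b - 1L) * spec$targets_per_block +
                               seq_len(spec$targets_per_block)]
      for (j in seq_along(host)) {
        tone_id[pos[j], host[j]] <- "target"
        is_target[pos[j], host[j]] <- TRUE
      }
    }

    blocks[[b]] <- tibble::tibble(
      onset = (rep(seq_len(n_tr), each = 3) - 1) * TRIPLET_S +
        (rep(1:3, n_tr) - 1) * SOA_S,
      block = b,
      tone_id = as.vector(tone_id),
      triplet_index = rep(seq_len(n_tr), each = 3),
      triplet_id = rep(triplet_id, each = 3),
      position = rep(1:3, n_tr),
      is_statistical_deviant = rep(category == "statistical", each = 3) &
        rep(1:3, n_tr) == 3,
      is_acoustic_deviant = rep(category == "acoustic", each = 3) &
        rep(1:3, n_tr) == 3,
      is_double_deviant = rep(category == "double", each = 3) &
        rep(1:3, n_tr) == 3,
      is_target = as.vector(is_target),
      category = rep(category, each = 3)
    )
  }
  events <- dplyr::bind_rows(blocks)
  attr(events, "spec") <- spec
  class(events) <- c("event_table", class(events))
  events
}

#' Empirical design statistics of an event table
#'
#' Verification helper: tabulates first-order tone-identity transition
#' probabilities (within blocks), per-category triplet counts, and
#' triplet-to-triplet transition frequencies.
#'
#' @param events An `event_table` from [generate_sequence()] or
#'   [make_toy_block()].
#' @return A list with `tone_transitions` (row-stochastic matrix over
#'   observed successors), `category_counts` (tibble per block),
#'   `triplet_transitions` (2x2 probability matrix P(next | current)), and
#'   `p_next_triplet` (marginal successor frequencies).
#' @export
empirical_statistics <- function(events) {
  if (!nrow(events)) stop("empty event table", call. = FALSE)
  # tone identity transitions within blocks
  from <- character(0); to <- character(0)
  tri_from <- integer(0); tri_to <- integer(0)
  for (b in unique(events$block)) {
    eb <- events[events$block == b, ]
    eb <- eb[order(eb$onset), ]
    from <- c(from, eb$tone_id[-nrow(eb)])
    to <- c(to, eb$tone_id[-1])
    tid <- eb$triplet_id[eb$position == 1]
    tri_from <- c(tri_from, tid[-length(tid)])
    tri_to <- c(tri_to, tid[-1])
  }
  tone_tab <- table(factor(from), factor(to))
  tone_transitions <- sweep(unclass(tone_tab), 1, rowSums(tone_tab), "/")

  first <- events[events$position == 1, ]
  category_counts <- dplyr::count(
    tibble::tibble(block = first$block, category = first$category),
    .data$block, .data$category)

  tri_tab <- table(factor(tri_from, levels = 1:2), factor(tri_to, levels = 1:2))
  triplet_transitions <- sweep(unclass(tri_tab), 1, pmax(rowSums(tri_tab), 1), "/")
  p_next <- as.vector(table(factor(tri_to, levels = 1:2))) / length(tri_to)

  list(tone_transitions = tone_transitions,
       category_counts = category_counts,
       triplet_transitions = triplet_transitions,
       p_next_triplet = stats::setNames(p_next, c("triplet1", "triplet2")),
       n_triplet_transitions = length(tri_to))
}

#' Total exposure duration of a sequence
#'
#' @param spec A [sequence_spec()].
#' @return Seconds of stimulation: `n_blocks * triplets_per_block * 0.9`.
#' @export
total_exposure <- function(spec) {
  validate_sequence_spec(spec)
  spec$n_blocks * spec$triplets_per_block * 3 * SOA_S
}

#' Write / read an event table as BIDS-style events TSV
#'
#' Columns: onset, duration, trial_type, block, tone_id, triplet_index,
#' triplet_id, position, plus the deviant/target flag columns.
#'
#' @param events An `event_table`.
#' @param path File path.
#' @return `write_events_tsv()` returns `path` invisibly;
#'   `read_events_tsv()` returns a tibble.
#' @export
write_events_tsv <- function(events, path) {
  out <- tibble::tibble(
    onset = events$onset,
    duration = rep(attr(events, "spec")$tone_duration %||% 0.220, nrow(events)),
    trial_type = events$category,
    block = events$block,
    tone_id = events$tone_id,
    triplet_index = events$triplet_index,
    triplet_id = events$triplet_id,
    position = events$position,
    is_statistical_deviant = events$is_statistical_deviant,
    is_acoustic_deviant = events$is_acoustic_deviant,
    is_double_deviant = events$is_double_deviant,
    is_target = events$is_target
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
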