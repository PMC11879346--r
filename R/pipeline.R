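# End-to-end pipeline: simulate (or accept) a cohort, preprocess, epoch,
# compute ITC/TLI and learning curves per subject, then run the group
# statistics and brain-behavior correlations.

#' Build a pipeline configuration
#'
#' One flat configuration object with paper-faithful defaults; every
#' documented analysis choice (ITC estimator, learning-curve x
#' convention, rejection signal) is surfaced here.
#'
#' @param n_control,n_dyslexia Group sizes.
#' @param effects A [cohort_effects()] specification.
#' @param sequence Named list of overrides for [sequence_spec()]
#'   arguments (e.g. `list(n_blocks = 2, triplets_per_block = 80)`).
#' @param srate Sampling rate for simulation, Hz.
#' @param preproc A [preproc_config()].
#' @param epoch_threshold Peak-to-peak rejection threshold, microvolts.
#' @param reject_on `"cluster"` (evaluate rejection on the
#'   cluster-average analysis signal) or `"channels"` (any channel).
#' @param triplets_per_epoch Triplets per 5.4-s epoch.
#' @param itc_mode `"standard"` or `"complex_average"`.
#' @param lc_window Sliding-window length in epochs.
#' @param x_convention `"retained"` or `"presented"`.
#' @param n_perm,alpha,min_len Cluster-permutation parameters.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_control = 8L, n_dyslexia = 8L,
                            effects = cohort_effects(),
                            sequence = list(n_blocks = 2L,
                                            triplets_per_block = 80L,
                                            targets_per_block = 2L),
                            srate = 150, preproc = preproc_config(),
                            epoch_threshold = 300,
                            reject_on = "cluster",
                            triplets_per_epoch = 6L,
                            itc_mode = "standard", lc_window = 4L,
                            x_convention = "retained", n_perm = 1000L,
                            alpha = 0.05, min_len = 2L, seed = 1L) {
  cfg <- list(n_control = n_control, n_dyslexia = n_dyslexia,
              effects = effects, sequence = sequence, srate = srate,
              preproc = preproc, epoch_threshold = epoch_threshold,
              reject_on = reject_on,
              triplets_per_epoch = triplets_per_epoch, itc_mode = itc_mode,
              lc_window = lc_window, x_convention = x_convention,
              n_perm = n_perm, alpha = alpha, min_len = min_len,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @return Character vector of problems; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  allowed <- names(formals(pipeline_config))
  extra <- setdiff(names(config), allowed)
  if (length(extra)) {
    errs <- c(errs, paste("unknown config entries:", paste(extra, collapse = ", ")))
  }
  need <- c("n_control", "n_dyslexia", "effects", "sequence", "srate",
            "preproc", "epoch_threshold", "itc_mode", "lc_window",
            "n_perm", "alpha", "min_len", "seed")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    errs <- c(errs, paste("missing config entries:", paste(missing, collapse = ", ")))
    return(errs)
  }
  if (config$n_control < 2 || config$n_dyslexia < 2) {
    errs <- c(errs, "each group needs at least 2 subjects")
  }
  if (config$n_perm < 1) errs <- c(errs, "n_perm must be >= 1")
  if (config$alpha <= 0 || config$alpha >= 1) {
    errs <- c(errs, "alpha must be in (0, 1)")
  }
  if (!config$itc_mode %in% c("standard", "complex_average")) {
    errs <- c(errs, "itc_mode must be 'standard' or 'complex_average'")
  }
  if (!is.null(config$x_convention) &&
      !config$x_convention %in% c("retained", "presented")) {
    errs <- c(errs, "x_convention must be 'retained' or 'presented'")
  }
  if (!is.null(config$reject_on) &&
      !config$reject_on %in% c("cluster", "channels")) {
    errs <- c(errs, "reject_on must be 'cluster' or 'channels'")
  }
  if (config$epoch_threshold <= 0) {
    errs <- c(errs, "epoch_threshold must be positive")
  }
  pc <- config$preproc
  if (!is.null(pc$hp_cutoff) && !is.null(pc$lp_cutoff) &&
      pc$hp_cutoff >= pc$lp_cutoff) {
    errs <- c(errs, "hp_cutoff must be below lp_cutoff")
  }
  if (!is.null(pc$lp_cutoff) && pc$lp_cutoff >= config$srate / 2) {
    errs <- c(errs, "lp_cutoff must be below the Nyquist frequency")
  }
  errs
}

#' Run the full analysis for one subject's recording
#'
#' Fixed stage order: bad-channel detection and repair, band-pass
#' filtering, standard-triplet selection, excision, mastoid
#' re-referencing, per-tone de-meaning, epoching, peak-to-peak
#' rejection, fronto-central cluster averaging, ITC and TLI.
#'
#' @param recording An `eeg_recording`.
#' @param config A [pipeline_config()].
#' @return List with `spectrum`, `tli` (a `tli_result`), `curve` (or
#'   `NULL` if the first block has fewer than `lc_window` epochs),
#'   `n_epochs`, `n_rejected`, `bad_channels`.
#' @export
process_subject <- function(recording, config = pipeline_config()) {
  bad <- detect_bad_channels(recording, config$preproc$bad_channel_z)
  rec <- repair_channels(recording, bad)
  rec <- bandpass(rec, config$preproc)
  selection <- select_standard_triplets(rec$events)
  stream <- excise_and_concatenate(rec, selection)
  stream <- rereference(stream, config$preproc$reference)
  stream <- demean_per_tone(stream)
  epochs <- cut_epochs(stream, config$triplets_per_epoch)
  if (identical(config$reject_on, "channels")) {
    epochs <- reject_epochs(epochs, config$epoch_threshold)
    avg <- cluster_average(epochs)
  } else {
    avg <- cluster_average(epochs)
    avg <- reject_epochs(avg, config$epoch_threshold)
  }
  spectrum <- compute_itc(avg, itc_mode = config$itc_mode)
  tli <- compute_tli(spectrum)
  first_block <- avg$info$block[1]
  n_first <- sum(avg$info$block == first_block)
  curve <- if (n_first >= config$lc_window) {
    sliding_tli(avg, window = config$lc_window, block = first_block,
                x_convention = config$x_convention,
                itc_mode = config$itc_mode)
  } else NULL
  list(spectrum = spectrum, tli = tli, curve = curve,
       n_epochs = dim(avg$data)[1], n_rejected = avg$n_rejected %||% 0L,
       bad_channels = bad)
}

#' Run the full pipeline on a simulated cohort
#'
#' Simulates a cohort under the configured effects, processes every
#' subject, and computes the group-level statistics: peak-vs-control-bin
#' tests at the tone and triplet rates (per group), two-sided group
#' comparisons of ITC at both rates, the one-sided group comparison of
#' the TLI (control > dyslexia), the cluster-based permutation test on
#' the TLI time courses, and one-sided Pearson correlations of the TLI
#' with the three behavioral scores.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list: `subjects` tibble, `stats`,
#'   `config`, `version`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  spec <- do.call(sequence_spec, c(config$sequence, list(seed = config$seed)))
  cohort <- simulate_cohort(config$n_control, config$n_dyslexia,
                            effect_spec = config$effects, seed = config$seed,
                            spec = spec, srate = config$srate)
  n <- config$n_control + config$n_dyslexia
  results <- vector("list", n)
  for (i in seq_len(n)) {
    results[[i]] <- tryCatch(
      process_subject(cohort$recordings[[i]], config),
      error = function(e) stop("subject ", i, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  group <- cohort$behavior$group
  tli <- vapply(results, function(r) r$tli$tli, numeric(1))
  itc_tone <- vapply(results, function(r) r$tli$itc_tone, numeric(1))
  itc_triplet <- vapply(results, function(r) r$tli$itc_triplet, numeric(1))
  subjects <- tibble::tibble(
    subject = seq_len(n), group = group, tli = tli, itc_tone = itc_tone,
    itc_triplet = itc_triplet,
    n_epochs = vapply(results, function(r) r$n_epochs, numeric(1)),
    n_rejected = vapply(results, function(r) r$n_rejected, numeric(1)))

  ctrl <- group == "control"
  spectra <- lapply(results, function(r) r$spectrum)
  stats_out <- list(
    peak_tone = list(
      control = peak_vs_neighbors(spectra[ctrl], TONE_RATE_HZ),
      dyslexia = peak_vs_neighbors(spectra[!ctrl], TONE_RATE_HZ)),
    peak_triplet = list(
      control = peak_vs_neighbors(spectra[ctrl], TRIPLET_RATE_HZ),
      dyslexia = peak_vs_neighbors(spectra[!ctrl], TRIPLET_RATE_HZ)),
    itc_tone_group = group_ttest(itc_tone[ctrl], itc_tone[!ctrl],
                                 "two.sided"),
    itc_triplet_group = group_ttest(itc_triplet[ctrl], itc_triplet[!ctrl],
                                    "two.sided"),
    tli_group = group_ttest(tli[ctrl], tli[!ctrl], "greater"))

  curves <- lapply(results, function(r) r$curve)
  if (all(!vapply(curves, is.null, logical(1)))) {
    n_win <- min(vapply(curves, nrow, integer(1)))
    if (n_win >= config$min_len) {
      tc <- t(vapply(curves, function(cu) cu$tli[seq_len(n_win)],
                     numeric(n_win)))
      stats_out$cluster_tli <- cluster_permutation(
        tc, group, n_perm = config$n_perm, alpha = config$alpha,
        min_len = config$min_len, seed = config$seed + 1L)
    } else {
      stats_out$cluster_tli <- NULL
      stats_out$cluster_note <- "too few aligned windows for a cluster test"
    }
  } else {
    stats_out$cluster_tli <- NULL
    stats_out$cluster_note <-
      "some subjects lack enough first-block epochs for the sliding window"
  }

  beh <- cohort$behavior
  stats_out$correlations <- list(
    spelling = brain_behavior_correlation(tli, zstandardize(beh$spelling_raw)),
    reading_speed = brain_behavior_correlation(
      tli, zstandardize(beh$reading_speed_raw)),
    reading_comprehension = brain_behavior_correlation(
      tli, zstandardize(beh$reading_comprehension_raw)))
  stats_out$note <-
    "behavior correlations are reported uncorrected for multiple comparisons"

  structure(list(subjects = subjects, behavior = beh, stats = stats_out,
                 curves = curves, config = config,
                 version = as.character(utils::packageVersion("triplettag"))),
            class = "pipeline_report")
}

#' Serialize a pipeline report to JSON
#'
#' Writes the statistics, per-subject table, and resolved configuration
#' (timestamps excluded so identical runs produce identical files).
#'
#' @param report A `pipeline_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "tbl_df")) return(as.data.frame(x))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  out <- list(subjects = as.data.frame(report$subjects),
              stats = strip(report$stats),
              config = strip(unclass(report$config)),
              version = report$version)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
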