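# Forward simulation of multichannel EEG for a triplet tone stream.
#
# Each tone elicits a damped-oscillation evoked kernel projected onto the
# scalp with a fronto-central gain profile. Phase consistency at the tone
# rate is controlled by per-tone latency jitter (tone_lock, radians at
# 3.33 Hz); sensitivity to the hidden triplet structure is injected as a
# period-3 amplitude/latency modulation of triplet-initial tones whose
# depth follows the subject's latent learning curve a*log(x) + b, so that
# spectral peaks at 1.11 Hz and its harmonics arise naturally rather than
# from an added sinusoid.

FC_CLUSTER <- c("F1", "F2", "Fz", "FC1", "FC2", "FCz", "C1", "C2", "Cz")
MASTOIDS <- c("M1", "M2")

#' Default EEG montage
#'
#' A reduced 10-20 montage containing the nine fronto-central cluster
#' electrodes (F1, F2, Fz, FC1, FC2, FCz, C1, C2, Cz), both mastoids, and
#' a few distant electrodes, with 2-D positions (unit head radius) and a
#' per-channel topographic gain for the simulated auditory evoked source
#' (Gaussian falloff from FCz; near-zero on the mastoids so mastoid
#' re-referencing behaves as in real data).
#'
#' @return A tibble with columns `channel`, `x`, `y`, `gain`.
#' @export
default_montage <- function() {
  m <- tibble::tribble(
    ~channel, ~x, ~y,
    "F1", -0.15, 0.35, "F2", 0.15, 0.35, "Fz", 0, 0.35,
    "FC1", -0.15, 0.18, "FC2", 0.15, 0.18, "FCz", 0, 0.18,
    "C1", -0.15, 0.00, "C2", 0.15, 0.00, "Cz", 0, 0.00,
    "Pz", 0, -0.35, "Oz", 0, -0.70, "T7", -0.70, 0.00, "T8", 0.70, 0.00,
    "M1", -0.85, -0.25, "M2", 0.85, -0.25
  )
  d2 <- (m$x - 0)^2 + (m$y - 0.18)^2   # source maximum under FCz
  m$gain <- exp(-d2 / (2 * 0.45^2))
  m$gain[m$channel %in% MASTOIDS] <- 0.02
  m
}

validate_montage <- function(montage) {
  need <- c(FC_CLUSTER, MASTOIDS)
  missing <- setdiff(need, montage$channel)
  if (length(missing)) {
    stop("montage is missing required channels: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(montage$channel)) stop("duplicate channel names", call. = FALSE)
  invisible(montage)
}

#' Subject simulation profile
#'
#' Parameters controlling one subject's simulated neural and behavioral
#' data.
#'
#' @param group `"control"` or `"dyslexia"`.
#' @param tone_lock Phase-jitter scale in radians at the 3.33 Hz tone
#'   rate; lower values give higher tone-rate inter-trial coherence.
#' @param triplet_lock Depth of the period-3 modulation distinguishing
#'   triplet-initial tones; higher values give higher triplet-rate ITC.
#' @param learn_a,learn_b Latent learning curve `a*log(x) + b` over
#'   triplets presented `x`, mapped (clipped at 0) to the modulation depth.
#' @param noise_amplitude RMS of the 1/f background noise, in microvolts.
#' @param noise_exponent Spectral exponent of the background noise.
#' @param artifact_rate High-amplitude transient artifacts per minute.
#' @param artifact_amplitude Artifact peak amplitude in microvolts.
#' @param spelling_z,reading_speed_z,reading_comprehension_z Standardized
#'   behavioral scores.
#' @param seed Integer seed for this subject's randomness.
#' @return A `subject_profile` object (list).
#' @export
subject_profile <- function(group = "control", tone_lock = 0.8,
                            triplet_lock = 0.5, learn_a = 0.25, learn_b = 0,
                            noise_amplitude = 10, noise_exponent = 1,
                            artifact_rate = 0.2, artifact_amplitude = 400,
                            spelling_z = 0, reading_speed_z = 0,
                            reading_comprehension_z = 0, seed = 1L) {
  stopifnot(tone_lock >= 0, triplet_lock >= 0, noise_amplitude > 0,
            artifact_rate >= 0)
  p <- list(group = group, tone_lock = tone_lock, triplet_lock = triplet_lock,
            learn_a = learn_a, learn_b = learn_b,
            noise_amplitude = noise_amplitude, noise_exponent = noise_exponent,
            artifact_rate = artifact_rate,
            artifact_amplitude = artifact_amplitude,
            spelling_z = spelling_z, reading_speed_z = reading_speed_z,
            reading_comprehension_z = reading_comprehension_z,
            seed = as.integer(seed))
  class(p) <- "subject_profile"
  p
}

# damped-oscillation evoked kernel: ~10 Hz carrier, ~100 ms decay,
# truncated at one SOA so consecutive tone responses do not overlap;
# peak amplitude ~5 uV at unit topographic gain
evoked_kernel <- function(srate, f0 = 10, tau = 0.1, amplitude = 5) {
  t <- seq(0, SOA_S - 1 / srate, by = 1 / srate)
  k <- exp(-t / tau) * sin(2 * pi * f0 * t)
  amplitude * k / max(abs(k))
}

# slow chunk-onset response evoked by triplet-initial tones: a damped
# ~2.5 Hz oscillation spanning the whole 0.9-s triplet, so the injected
# period-3 structure carries genuine energy at 1.11 Hz and its
# harmonics that survives the per-tone de-meaning downstream. Its
# 3.33 Hz Fourier component over the triplet period is projected out so
# the injection leaves the tone-rate bin untouched.
chunk_kernel <- function(srate, f0 = 2.5, tau = 0.25, amplitude = 5) {
  t <- seq(0, TRIPLET_S - 1 / srate, by = 1 / srate)
  k <- exp(-t / tau) * sin(2 * pi * f0 * t)
  for (basis in list(cos(2 * pi * TONE_RATE_HZ * t),
                     sin(2 * pi * TONE_RATE_HZ * t))) {
    k <- k - sum(k * basis) / sum(basis^2) * basis
  }
  amplitude * k / max(abs(k))
}

# 1/f^exponent noise with unit RMS, via spectral shaping of white noise
pink_noise <- function(n, exponent = 1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))                       # avoid DC blow-up
  f <- pmin(f, n - f + 1)                         # two-sided frequency index
  X <- X * f^(-exponent / 2)
  X[1] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

# latent learning curve value -> modulation depth (monotone, g(0) = 0)
learning_modulation <- function(profile, x) {
  pmax(profile$learn_a * log(pmax(x, 1)) + profile$learn_b, 0)
}

#' Forward-simulate a continuous EEG recording
#'
#' @param events An `event_table` from [generate_sequence()].
#' @param profile A [subject_profile()].
#' @param montage A montage tibble, see [default_montage()].
#' @param srate Sampling rate in Hz (>= 100; the evoked kernel needs the
#'   bandwidth).
#' @return An `eeg_recording`: list with `signal` (channels x samples
#'   matrix, microvolts), `srate`, `montage`, `events`, and
#'   `block_bounds` (first/last sample of each block).
#' @export
simulate_recording <- function(events, profile, montage = default_montage(),
                               srate = 500) {
  if (!nrow(events)) stop("empty event table", call. = FALSE)
  if (srate < 100) {
    stop("srate must be >= 100 Hz to represent the evoked kernel", call. = FALSE)
  }
  validate_montage(montage)
  set.seed(profile$seed)
  kernel <- evoked_kernel(srate)
  n_ch <- nrow(montage)
  blocks <- sort(unique(events$block))
  tpb <- max(events$triplet_index)

  sig_blocks <- vector("list", length(blocks))
  bounds <- tibble::tibble(block = blocks, start_sample = NA_integer_,
                           end_sample = NA_integer_)
  offset <- 0L
  for (bi in seq_along(blocks)) {
    eb <- events[events$block == blocks[bi], ]
    dur <- max(eb$onset) + 2 * SOA_S
    L <- ceiling(dur * srate)

    # cumulative triplets presented before this tone (learning coordinate)
    x_tri <- (bi - 1L) * tpb + eb$triplet_index
    depth <- profile$triplet_lock * learning_modulation(profile, x_tri)
    initial <- eb$position == 1L
    lat <- -0.01 * pmin(depth, 2) * initial        # seconds, latency advance
    jitter <- stats::rnorm(nrow(eb), 0,
                           profile$tone_lock / (2 * pi * TONE_RATE_HZ))

    s_idx <- round((eb$onset + jitter + lat) * srate) + 1L
    s_idx <- pmin(pmax(s_idx, 1L), L)
    imp <- numeric(L)
    for (j in seq_along(s_idx)) imp[s_idx[j]] <- imp[s_idx[j]] + 1
    # chunk-onset component on triplet-initial tones, scaled by the
    # learning-curve modulation depth
    imp_chunk <- numeric(L)
    ini <- which(initial)
    for (j in ini) imp_chunk[s_idx[j]] <- imp_chunk[s_idx[j]] + depth[j]
    ck <- chunk_kernel(srate)
    nfft <- stats::nextn(L + length(ck))
    conv_fft <- function(x, k) {
      Re(stats::fft(stats::fft(c(x, numeric(nfft - L))) *
                      stats::fft(c(k, numeric(nfft - length(k)))),
                    inverse = TRUE))[seq_len(L)] / nfft
    }
    base <- conv_fft(imp, kernel) + conv_fft(imp_chunk, ck)

    sig <- outer(montage$gain, base)
    for (ch in seq_len(n_ch)) {
      sig[ch, ] <- sig[ch, ] +
        profile$noise_amplitude * pink_noise(L, profile$noise_exponent)
    }

    # generic high-amplitude transients at Poisson times, on all channels
    n_art <- stats::rpois(1, profile$artifact_rate * dur / 60)
    if (n_art > 0) {
      art_len <- round(0.5 * srate)
      bump <- profile$artifact_amplitude *
        (0.5 - 0.5 * cos(2 * pi * seq_len(art_len) / (art_len + 1)))
      for (a in seq_len(n_art)) {
        at <- sample.int(max(L - art_len, 1), 1)
        span <- at:min(at + art_len - 1, L)
        # scalp-weighted topography (near-zero on the mastoids) with
        # per-channel variability, so the transient survives
        # re-referencing and reaches the analysis cluster
        topo <- montage$gain * stats::runif(n_ch, 0.7, 1.3)
        sig[, span] <- sig[, span] +
          topo %o% bump[seq_along(span)]
      }
    }
    sig_blocks[[bi]] <- sig
    bounds$start_sample[bi] <- offset + 1L
    bounds$end_sample[bi] <- offset + L
    offset <- offset + L
  }

  rec <- list(signal = do.call(cbind, sig_blocks), srate = srate,
              montage = montage, events = events, block_bounds = bounds)
  rownames(rec$signal) <- montage$channel
  class(rec) <- "eeg_recording"
  rec
}

#' Cohort effect specification
#'
#' Encodes the standardized group effects the simulated cohort should
#' carry: a latent triplet-sensitivity (TLI) difference `d` between
#' control and dyslexia groups, a correlation `rho` between the
#' standardized latent sensitivity and spelling scores, correlations for
#' the reading scores (default 0), and an additive tone-lock offset for
#' the control group (controls jitter more at the tone rate, so their
#' tone-rate ITC is lower, as the group difference requires).
#'
#' @param d Standardized latent TLI group difference (control minus
#'   dyslexia).
#' @param rho Correlation of spelling scores with standardized latent TLI.
#' @param rho_reading Correlation of both reading scores with latent TLI.
#' @param tone_lock_diff Added tone-rate phase jitter (radians) in the
#'   control group.
#' @return An `effect_spec` list.
#' @export
cohort_effects <- function(d = 0.64, rho = 0.35, rho_reading = 0,
                           tone_lock_diff = 0.15) {
  structure(list(d = d, rho = rho, rho_reading = rho_reading,
                 tone_lock_diff = tone_lock_diff), class = "effect_spec")
}

#' Simulate a cohort of subjects
#'
#' Draws per-subject profiles so that the latent triplet sensitivity
#' differs between groups by `effect_spec$d` standard units and spelling
#' scores correlate with the standardized latent sensitivity at
#' `effect_spec$rho`; optionally forward-simulates full recordings.
#'
#' @param n_control,n_dyslexia Group sizes (each >= 2).
#' @param effect_spec See [cohort_effects()].
#' @param seed Integer seed.
#' @param spec Sequence design used for every subject's stimulus stream
#'   (each subject gets an independently drawn sequence).
#' @param montage,srate Passed to [simulate_recording()].
#' @param simulate_signal If `FALSE`, only profiles and the behavioral
#'   table are generated (fast; used for large statistical calibration
#'   runs).
#' @return A list with `profiles`, `behavior` (tibble: subject, group, raw
#'   and z-standardized scores, latent sensitivity), and, when requested,
#'   `recordings` and `events` lists.
#' @export
simulate_cohort <- function(n_control, n_dyslexia,
                            effect_spec = cohort_effects(), seed = 1L,
                            spec = sequence_spec(), montage = default_montage(),
                            srate = 500, simulate_signal = TRUE) {
  if (n_control < 2 || n_dyslexia < 2) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  set.seed(seed)
  n <- n_control + n_dyslexia
  group <- rep(c("control", "dyslexia"), c(n_control, n_dyslexia))
  latent <- stats::rnorm(n) + ifelse(group == "control",
                                     effect_spec$d / 2, -effect_spec$d / 2)
  latent_std <- as.vector(scale(latent))
  spelling_z <- effect_spec$rho * latent_std +
    sqrt(1 - effect_spec$rho^2) * stats::rnorm(n)
  rr <- effect_spec$rho_reading
  reading_speed_z <- rr * latent_std + sqrt(1 - rr^2) * stats::rnorm(n)
  reading_comprehension_z <- rr * latent_std + sqrt(1 - rr^2) * stats::rnorm(n)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)

  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    profiles[[i]] <- subject_profile(
      group = group[i],
      tone_lock = 0.8 + effect_spec$tone_lock_diff * (group[i] == "control"),
      triplet_lock = max(0.5 + 0.15 * latent[i], 0),
      learn_a = max(0.25 + 0.05 * latent[i], 0), learn_b = 0,
      spelling_z = spelling_z[i], reading_speed_z = reading_speed_z[i],
      reading_comprehension_z = reading_comprehension_z[i],
      seed = subject_seeds[i])
  }
  behavior <- tibble::tibble(
    subject = seq_len(n), group = group, latent_tli = latent,
    spelling_raw = 100 + 15 * spelling_z,
    reading_speed_raw = 50 + 10 * reading_speed_z,
    reading_comprehension_raw = 30 + 5 * reading_comprehension_z,
    spelling_z = spelling_z, reading_speed_z = reading_speed_z,
    reading_comprehension_z = reading_comprehension_z)

  out <- list(profiles = profiles, behavior = behavior, seed = seed)
  if (simulate_signal) {
    seq_seeds <- sample.int(.Machine$integer.max - 1L, n)
    out$events <- lapply(seq_len(n), function(i) {
      s <- spec; s$seed <- seq_seeds[i]
      s$counterbalance_id <- ((i - 1L) %% 6L) + 1L
      generate_sequence(s)
    })
    out$recordings <- lapply(seq_len(n), function(i) {
      simulate_recording(out$events[[i]], profiles[[i]], montage, srate)
    })
  }
  out
}
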