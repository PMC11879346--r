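test_that("ITC matches analytic values on constructed phase fixtures", {
  # identical phases: perfect coherence
  ep1 <- make_phase_epochs(20, bin = 6, phase_rule = "identical")
  sp1 <- compute_itc(ep1)
  expect_equal(extract_rate_bins(sp1)$itc_triplet, 1, tolerance = 1e-6)

  # antiphase pairs cancel
  ep2 <- make_phase_epochs(10, bin = 6, phase_rule = "alternating")
  sp2 <- compute_itc(ep2)
  expect_lt(extract_rate_bins(sp2)$itc_triplet, 1e-6)

  # two epochs with opposite phase: ITC 0 at that bin
  ep3 <- make_phase_epochs(2, bin = 18, phase_rule = "alternating")
  sp3 <- compute_itc(ep3)
  expect_lt(extract_rate_bins(sp3)$itc_tone, 1e-6)
})

test_that("uniform-phase ITC follows the Rayleigh null expectation", {
  n_epochs <- 100
  # independent Monte-Carlo oracle on raw phasors
  set.seed(11)
  oracle <- mean(replicate(10000, abs(mean(exp(1i * runif(n_epochs, 0, 2 * pi))))))
  expect_equal(oracle, sqrt(pi) / (2 * sqrt(n_epochs)), tolerance = 0.02)

  # implementation path: ITC of uniform-phase epochs through the FFT
  vals <- vapply(1:200, function(s) {
    ep <- make_phase_epochs(n_epochs, bin = 6, phase_rule = "uniform", seed = s)
    extract_rate_bins(compute_itc(ep))$itc_triplet
  }, numeric(1))
  mc_se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - oracle), 4 * mc_se + 0.002)
})

test_that("ITC is invariant to amplitude scaling and common phase rotations", {
  set.seed(12)
  ep <- make_phase_epochs(12, bin = 6, phase_rule = "uniform", seed = 3)
  ep$data <- ep$data + array(0.3 * rnorm(length(ep$data)), dim = dim(ep$data))
  base <- compute_itc(ep)$itc

  ep_scaled <- ep; ep_scaled$data <- ep$data * 7.5
  expect_equal(compute_itc(ep_scaled)$itc, base, tolerance = 1e-10)

  # delaying every epoch by the same offset rotates all phasors at the
  # target bin by a common angle, leaving their coherence unchanged
  ep_a <- make_phase_epochs(12, bin = 6, phase_rule = "uniform", seed = 3)
  ep_b <- ep_a
  t <- (seq_len(dim(ep_a$data)[3]) - 1) / ep_a$srate
  for (e in 1:12) {
    ep_b$data[e, 1, ] <- cos(2 * pi * (6 / 5.4) * t + ep_a$phases[e] + 1.3)
  }
  itc_a <- extract_rate_bins(compute_itc(ep_a))$itc_triplet
  itc_b <- extract_rate_bins(compute_itc(ep_b))$itc_triplet
  # equal up to the symmetric Hanning window's sidelobe leakage
  expect_equal(itc_a, itc_b, tolerance = 1e-4)
})

test_that("rate bins sit at 1.11 and 3.33 Hz only for 5.4-s epochs", {
  ep <- make_phase_epochs(4, bin = 6)
  sp <- compute_itc(ep)
  b <- extract_rate_bins(sp)
  expect_equal(unname(b$bins["triplet"]), 6L)
  expect_equal(unname(b$bins["tone"]), 18L)
  expect_equal(round(sp$freqs[b$bins["triplet"] + 1], 2), 1.11)
  expect_equal(round(sp$freqs[b$bins["tone"] + 1], 2), 3.33)

  # a 5.0-s epoch grid cannot host the rates exactly
  ep5 <- ep
  ep5$data <- ep5$data[, , 1:round(5.0 * ep$srate), drop = FALSE]
  ep5$epoch_length <- 5.0
  expect_error(extract_rate_bins(compute_itc(ep5)), "exact FFT bin")
})

test_that("peak-vs-neighbor contrasts use the 2.96 and 3.70 Hz control bins", {
  freqs <- (0:405) / 5.4
  make_sp <- function(peak) {
    itc <- rep(0.1, length(freqs))
    itc[19] <- peak                       # bin 18 = 3.33 Hz
    structure(list(freqs = freqs, itc = itc), class = "itc_spectrum")
  }
  spectra <- lapply(c(0.5, 0.45, 0.55, 0.48, 0.52), make_sp)
  res <- peak_vs_neighbors(spectra, peak_hz = 10 / 3)
  expect_equal(round(res$control_freqs, 2), c(2.96, 3.70))
  expect_equal(res$contrasts, c(0.5, 0.45, 0.55, 0.48, 0.52) - 0.1)
  # matches the one-sample t oracle
  oracle <- t.test(res$contrasts, alternative = "greater")
  expect_equal(res$t, unname(oracle$statistic))
  expect_equal(res$p, oracle$p.value)

  # degenerate all-zero contrasts: t = 0, p = 0.5
  flat <- lapply(rep(0.1, 4), make_sp)
  res0 <- peak_vs_neighbors(flat, peak_hz = 10 / 3)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 0.5)

  expect_error(peak_vs_neighbors(spectra[1:2]), "3 subjects")
  expect_error(peak_vs_neighbors(spectra, peak_hz = 1 / 5.4, offset = 10),
               "outside")
})

test_that("TLI is the triplet-to-tone ITC ratio with a guarded denominator", {
  expect_equal(compute_tli(0.3, 0.3)$tli, 1)
  expect_equal(compute_tli(0.2, 0.5)$tli, 0.4)
  expect_error(compute_tli(0.2, 0), "undefined")

  # block-averaged ITC equals the per-block ITC when blocks are identical
  ep <- make_phase_epochs(8, bin = 6, phase_rule = "uniform", seed = 9)
  ep2 <- ep
  ep2$data <- abind_epochs(ep$data, ep$data)
  ep2$info <- dplyr::bind_rows(ep$info,
                               transform(ep$info, block = 2L,
                                         epoch = epoch + 8L))
  sp <- compute_itc(ep2)
  expect_equal(sp$itc_by_block[, 1], sp$itc_by_block[, 2])
  expect_equal(sp$itc, sp$itc_by_block[, 1])
})

test_that("topographic ITC reflects the injected fronto-central gain", {
  spec <- sequence_spec(n_blocks = 1, triplets_per_block = 90,
                        targets_per_block = 2, seed = 21)
  ev <- generate_sequence(spec)
  prof <- subject_profile(seed = 22, tone_lock = 0.3, triplet_lock = 0.5,
                          learn_b = 1, artifact_rate = 0)
  rec <- simulate_recording(ev, prof, srate = 150)
  rec <- bandpass(rec, preproc_config())
  st <- demean_per_tone(rereference(
    excise_and_concatenate(rec, select_standard_triplets(ev))))
  ep <- cut_epochs(st)
  topo <- itc_topography(ep)
  expect_setequal(topo$channel, rec$montage$channel)
  # cluster channels carry more tone-rate phase locking than the rest
  expect_gt(mean(topo$itc_tone[topo$in_cluster]),
            mean(topo$itc_tone[!topo$in_cluster]))

  # identical channels give identical ITC values
  ep_id <- ep
  for (ch in seq_along(ep_id$channels)) ep_id$data[, ch, ] <- ep$data[, 1, ]
  topo_id <- itc_topography(ep_id)
  expect_equal(var(topo_id$itc_tone), 0)
})
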