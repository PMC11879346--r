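test_that("triplet selection applies the deviant / post-deviant / target rules", {
  ev <- make_toy_block(8, deviant_positions = c(3, 4), target_positions = 7)
  sel <- select_standard_triplets(ev)
  expect_equal(sel$triplet_index[sel$keep], c(1, 2, 6, 8))
  expect_equal(sel$reason[sel$triplet_index == 3], "deviant")
  expect_equal(sel$reason[sel$triplet_index == 4], "deviant")
  expect_equal(sel$reason[sel$triplet_index == 5], "post_deviant")
  expect_equal(sel$reason[sel$triplet_index == 7], "target")

  sel_clean <- select_standard_triplets(make_toy_block(5))
  expect_true(all(sel_clean$keep))

  sel_none <- select_standard_triplets(
    make_toy_block(3, deviant_positions = 1:3))
  expect_true(all(!sel_none$keep))

  # a block's first triplet is never post-deviant relative to the
  # previous block
  ev2 <- make_toy_block(4, deviant_positions = 4)
  ev2b <- ev2; ev2b$block <- 2L
  both <- dplyr::bind_rows(ev2, ev2b)
  class(both) <- class(ev2)
  sel2 <- select_standard_triplets(both)
  expect_true(sel2$keep[sel2$block == 2 & sel2$triplet_index == 1])
})

test_that("excision concatenates retained spans bit-identically with a correct registry", {
  srate <- 150
  ev <- make_toy_block(3, deviant_positions = 2)
  rec <- toy_recording(ev, srate = srate)
  sel <- select_standard_triplets(ev)          # keeps {1}; 2 deviant, 3 post
  sel$keep <- sel$triplet_index %in% c(1, 3)   # hand-set keep {1, 3}
  sel$reason[sel$triplet_index == 3] <- NA

  stream <- excise_and_concatenate(rec, sel)
  span <- round(0.9 * srate)
  expect_equal(ncol(stream$signal), 2 * span)
  # retained samples identical to the source spans
  expect_identical(stream$signal[, 1:span], rec$signal[, 1:span])
  expect_identical(stream$signal[, span + 1:span],
                   rec$signal[, 2 * span + 1:span])
  # registry maps tone onsets into the new stream
  reg <- stream$registry
  expect_equal(reg$sample[reg$triplet_index == 1],
               1 + (0:2) * round(0.3 * srate))
  expect_equal(reg$sample[reg$triplet_index == 3],
               span + 1 + (0:2) * round(0.3 * srate))

  # all kept: identity
  sel_all <- select_standard_triplets(make_toy_block(3))
  rec3 <- toy_recording(make_toy_block(3), srate = srate)
  st_all <- excise_and_concatenate(rec3, sel_all)
  expect_identical(st_all$signal, rec3$signal[, 1:(3 * span)])

  # none kept: error
  sel_none <- sel; sel_none$keep <- FALSE
  expect_error(excise_and_concatenate(rec, sel_none), "no standard")
})

test_that("per-tone de-meaning zeroes each 300 ms window mean", {
  srate <- 150
  ev <- make_toy_block(4)
  rec <- toy_recording(ev, srate = srate, fill = function(i) rep(7, length(i)))
  stream <- excise_and_concatenate(rec, select_standard_triplets(ev))
  dm <- demean_per_tone(stream)
  expect_true(all(abs(dm$signal) < 1e-12))

  # piecewise-constant per tone window: all zeros
  ntone <- round(0.3 * srate)
  rec2 <- toy_recording(ev, srate = srate,
                        fill = function(i) ((i - 1) %/% ntone))
  st2 <- demean_per_tone(excise_and_concatenate(rec2, select_standard_triplets(ev)))
  expect_true(all(abs(st2$signal) < 1e-12))

  # ramp: each window keeps its shape minus its own mean
  rec3 <- toy_recording(ev, srate = srate, fill = function(i) as.numeric(i))
  st3 <- demean_per_tone(excise_and_concatenate(rec3, select_standard_triplets(ev)))
  w1 <- 1:ntone
  expect_equal(st3$signal[1, w1], w1 - mean(w1))

  # a broken registry is rejected
  st_bad <- excise_and_concatenate(rec3, select_standard_triplets(ev))
  st_bad$registry$sample[2] <- st_bad$registry$sample[2] + 1L
  expect_error(demean_per_tone(st_bad), "tile")
})

test_that("epoch cutting groups six retained triplets and discards block-tail leftovers", {
  srate <- 150
  for (n_tr in c(13, 6, 5)) {
    ev <- make_toy_block(n_tr)
    rec <- toy_recording(ev, srate = srate)
    st <- demean_per_tone(excise_and_concatenate(rec, select_standard_triplets(ev)))
    ep <- cut_epochs(st)
    expect_equal(dim(ep$data)[1], n_tr %/% 6)
  }
  ev6 <- make_toy_block(6)
  rec6 <- toy_recording(ev6, srate = srate)
  st6 <- demean_per_tone(excise_and_concatenate(rec6, select_standard_triplets(ev6)))
  ep6 <- cut_epochs(st6)
  expect_equal(dim(ep6$data)[3], round(5.4 * srate))
  expect_equal(ep6$info$retained_triplets, 6L)

  # epoching never alters retained samples (only de-meaning does)
  ev12 <- make_toy_block(12)
  rec12 <- toy_recording(ev12, srate = srate, fill = function(i) sin(i / 9))
  st12 <- excise_and_concatenate(rec12, select_standard_triplets(ev12))
  ep12 <- cut_epochs(st12)
  expect_equal(ep12$data[1, 1, ], st12$signal[1, 1:round(5.4 * srate)])
  expect_equal(ep12$data[2, 1, ],
               st12$signal[1, round(5.4 * srate) + 1:round(5.4 * srate)])
})

test_that("peak-to-peak rejection drops exactly the contaminated epochs", {
  srate <- 150
  ev <- make_toy_block(18)
  rec <- toy_recording(ev, srate = srate, fill = function(i) rep(0, length(i)))
  st <- demean_per_tone(excise_and_concatenate(rec, select_standard_triplets(ev)))
  ep <- cut_epochs(st)
  expect_equal(dim(ep$data)[1], 3)

  # all-zero epochs survive
  expect_equal(dim(reject_epochs(ep)$data)[1], 3)

  # a 400 uV spike in epoch 2 removes exactly epoch 2
  ep_sp <- ep
  ep_sp$data[2, 3, 100] <- 400
  kept <- reject_epochs(ep_sp)
  expect_equal(dim(kept$data)[1], 2)
  expect_equal(kept$n_rejected, 1)
  expect_equal(kept$info$epoch_in_block, c(1L, 3L))

  # infinite threshold keeps everything
  expect_equal(dim(reject_epochs(ep_sp, threshold = Inf)$data)[1], 3)

  ep_all <- ep
  ep_all$data[, 1, 1] <- 1000
  expect_error(reject_epochs(ep_all), "all .* epochs")
})

test_that("cluster averaging is the unweighted fronto-central mean", {
  srate <- 150
  ev <- make_toy_block(12)
  rec <- toy_recording(ev, srate = srate, fill = function(i) cos(i / 7))
  st <- excise_and_concatenate(rec, select_standard_triplets(ev))
  ep <- cut_epochs(st)

  # identical channels: average equals any one of them
  avg <- cluster_average(ep)
  expect_equal(avg$channels, "cluster")
  expect_equal(avg$data[1, 1, ], ep$data[1, 1, ])

  # +v / -v pair among zeros cancels
  ep0 <- ep; ep0$data[] <- 0
  i_f1 <- match("F1", ep$channels); i_f2 <- match("F2", ep$channels)
  ep0$data[1, i_f1, ] <- 5; ep0$data[1, i_f2, ] <- -5
  expect_equal(max(abs(cluster_average(ep0)$data)), 0)

  # random epochs match the brute-force mean
  set.seed(5)
  ep_r <- ep; ep_r$data[] <- rnorm(length(ep_r$data))
  idx <- match(c("F1", "F2", "Fz", "FC1", "FC2", "FCz", "C1", "C2", "Cz"),
               ep_r$channels)
  oracle <- colMeans(matrix(ep_r$data[2, idx, ], nrow = length(idx)))
  expect_equal(cluster_average(ep_r)$data[2, 1, ], oracle)

  ep_m <- ep; ep_m$channels[match("Fz", ep_m$channels)] <- "QQ"
  expect_error(cluster_average(ep_m), "Fz")
})
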