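make_sine_rec <- function(freqs, fs = 250, seconds = 20, amp = 1) {
  t <- (seq_len(fs * seconds) - 1) / fs
  data <- do.call(rbind, lapply(freqs, function(f) amp * sin(2 * pi * f * t)))
  eeg_recording(data, fs)
}

test_that("band-pass filter has the designed pass/stop behaviour, zero phase", {
  rec <- make_sine_rec(c(10, 0.2))
  out <- bandpass_filter(rec, 1, 40)
  mid <- 1000:4000                    # trim edges
  amp10 <- sqrt(2 * mean(out$data[1, mid]^2))
  expect_lt(abs(amp10 - 1), 0.01)     # passband gain within 1%
  amp02 <- sqrt(2 * mean(out$data[2, mid]^2))
  expect_lt(amp02, 0.05)              # stopband residual < 5%
  # impulse-train peak latency unchanged (zero-phase contract)
  imp <- matrix(0, 2, 5000)
  imp[, c(1000, 2500, 4000)] <- 1
  fo <- bandpass_filter(eeg_recording(imp, 250), 1, 40)
  expect_equal(which.max(fo$data[1, 2000:3000]) + 1999, 2500)
  expect_error(bandpass_filter(rec, 0, 40))
  expect_error(bandpass_filter(rec, 10, 200))
})

test_that("planted channel defects are detected with the right criterion", {
  tk <- fixture_task(seconds = 8, seed = 31)
  rec <- tk$recording
  nm <- rec$channel_names
  # flat for ~5.5 s
  r1 <- rec; r1$data[5, 200:(200 + round(250 * 5.5))] <- 3.14
  b1 <- detect_bad_channels(r1)$bad_channels
  expect_true(any(b1$channel == nm[5] & b1$criterion == "flat"))
  # independent noise amid a smooth field
  r2 <- rec
  r2$data[10, ] <- withr::with_seed(1, stats::rnorm(ncol(rec$data),
                                                    sd = stats::sd(rec$data[10, ])))
  b2 <- detect_bad_channels(r2)$bad_channels
  expect_true(any(b2$channel == nm[10] &
                    b2$criterion == "low neighbor correlation"))
  # amplitude outlier
  r3 <- rec; r3$data[20, ] <- rec$data[20, ] * 8
  b3 <- detect_bad_channels(r3)$bad_channels
  expect_true(any(b3$channel == nm[20] & b3$criterion == "amplitude"))
  # missing positions: neighbour criterion disabled with a warning entry
  r4 <- rec; r4$positions <- NULL
  rep4 <- detect_bad_channels(r4)
  expect_match(rep4$warnings, "neighbour", all = FALSE)
})

test_that("clean recordings are essentially never flagged", {
  # flat/neighbour flags: none; amplitude z > 3 has a small intrinsic
  # false-alarm rate, so bound the overall channel false-flag rate instead
  n_flag <- 0; n_eval <- 0
  for (i in 1:8) {
    tk <- fixture_task(seconds = 8, seed = 100 + i)
    b <- detect_bad_channels(tk$recording)$bad_channels
    expect_false(any(b$criterion %in%
                       c("flat", "low neighbor correlation")))
    n_flag <- n_flag + nrow(b)
    n_eval <- n_eval + 64
  }
  expect_lte(n_flag / n_eval, 0.02)
})

test_that("epoch cleaning rejects amplitude artifacts and repairs local defects", {
  tk <- fixture_task(seconds = 30, seed = 51)
  rec <- tk$recording
  # clean input: zero rejections
  cl0 <- epoch_and_clean(rec)
  expect_equal(nrow(cl0$report$rejected_epochs), 0)
  # a 150 uV artifact at t = 3.5 s spanning many channels sits in epoch 2:
  # too broad for local repair, so the amplitude criterion rejects it
  r1 <- rec
  r1$data[1:20, 3.5 * 250] <- r1$data[1:20, 3.5 * 250] +
    150 * rep(c(1, -1), 10)
  cl1 <- epoch_and_clean(r1)
  expect_true(2 %in%
    cl1$report$rejected_epochs$epoch[cl1$report$rejected_epochs$criterion ==
                                       "amplitude"])
  expect_equal(ncol(cl1$recording$data),
               ncol(rec$data) %/% 500 * 500 - 500 *
                 length(unique(cl1$report$rejected_epochs$epoch)))
  # one channel corrupted in one epoch only: interpolated, epoch retained
  r2 <- rec
  true_seg <- r2$data[7, 2501:3000]
  r2$data[7, 2501:3000] <- withr::with_seed(2, stats::rnorm(500, sd = 40))
  cl2 <- epoch_and_clean(r2)
  expect_true(any(cl2$report$interpolated_local$epoch == 6 &
                    cl2$report$interpolated_local$channel ==
                      rec$channel_names[7]))
  expect_false(6 %in% cl2$report$rejected_epochs$epoch)
  kept <- setdiff(seq_len(15), cl2$report$rejected_epochs$epoch)
  seg <- cl2$recording$data[7, (which(kept == 6) - 1) * 500 + (1:500)]
  expect_gte(stats::cor(seg, true_seg), 0.9)
  expect_error(epoch_and_clean(fixture_task(seconds = 1)$recording,
                               epoch_seconds = 2))
})

test_that("spherical-spline interpolation reconstructs smooth fields", {
  mont <- montage_biosemi64()
  pos <- as.matrix(mont[, c("x", "y", "z")])
  # analytic low-order spherical field sampled at the sensors
  fld <- pos[, 3]^2 + 0.5 * pos[, 1] - 0.3 * pos[, 2]
  fld <- fld - mean(fld)
  rec <- eeg_recording(cbind(fld, fld * 2, fld * 0.5), fs = 10,
                       mont$name, pos)
  out <- interpolate_spherical(rec, bad = "C3")
  i <- match("C3", mont$name)
  expect_lt(max(abs(out$data[i, ] - rec$data[i, ])) /
              (max(fld) - min(fld)), 0.05)
  # good channels bit-identical
  expect_identical(out$data[-i, ], rec$data[-i, ])
  # interpolated value within neighbour min/max +/- 20% of the field range
  nb <- mspilot:::nearest_neighbors(pos, 4)[i, ]
  rng <- range(fld[nb])
  slack <- 0.2 * (max(fld) - min(fld))
  expect_true(all(out$data[i, 1] >= rng[1] - slack &
                    out$data[i, 1] <= rng[2] + slack))
  expect_error(interpolate_spherical(rec, bad = "nope"))
  rec$positions <- NULL
  expect_error(interpolate_spherical(rec, bad = "C3"), "positions")
})

test_that("finalize re-references, downsamples and is idempotent", {
  t <- (seq_len(2048 * 4) - 1) / 2048
  rec <- eeg_recording(rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t),
                             sin(2 * pi * 3 * t)), 2048)
  out <- finalize_recording(rec, 250)
  expect_equal(out$fs, 250)
  expect_lte(abs(ncol(out$data) - round(ncol(rec$data) * 250 / 2048)), 1)
  expect_lt(max(abs(colSums(out$data))), 1e-6)
  # 10 Hz component amplitude preserved within 2%: fit a quadrature basis
  # to channel 1 before (average-referenced, 2048 Hz) and after resampling
  amp10 <- function(x, fs) {
    tt <- (seq_along(x) - 1) / fs
    cf <- stats::coef(stats::lm(x ~ sin(2 * pi * 10 * tt) +
                                  cos(2 * pi * 10 * tt)))
    sqrt(sum(cf[2:3]^2))
  }
  ref <- average_reference(rec)
  expect_lt(abs(amp10(out$data[1, ], 250) /
                  amp10(ref$data[1, ], 2048) - 1), 0.02)
  # idempotence at the target rate
  again <- finalize_recording(out, 250)
  expect_lt(max(abs(again$data - out$data)), 1e-9)
  expect_error(finalize_recording(out, 500), "upsampling")
})
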