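test_that("template maps are unit-norm, zero-mean, dissimilar and deterministic", {
  tm <- generate_template_maps(7, 64, 0.7, seed = 1)
  expect_equal(dim(tm$maps), c(7, 64))
  expect_true(all(abs(sqrt(rowSums(tm$maps^2)) - 1) < 1e-9))
  expect_true(all(abs(rowSums(tm$maps)) < 1e-9))
  # exhaustive pairwise similarity check over all 21 pairs
  for (i in 1:6) for (j in (i + 1):7)
    expect_lte(abs(stats::cor(tm$maps[i, ], tm$maps[j, ])), 0.7)
  tm2 <- generate_template_maps(7, 64, 0.7, seed = 1)
  expect_identical(tm$maps, tm2$maps)
  expect_false(identical(
    tm$maps, generate_template_maps(7, 64, 0.7, seed = 2)$maps))
})

test_that("template map generation rejects infeasible similarity budgets", {
  expect_error(generate_template_maps(20, 32, 0.05, seed = 1,
                                      max_retries = 20),
               "max_similarity")
  expect_error(generate_template_maps(1, 64, 0.7, seed = 1))
  expect_error(generate_template_maps(7, 64, 1.2, seed = 1))
})

test_that("label sequences follow the dwell model", {
  # degenerate single-class chain: one run
  m1 <- sequence_model(1, mean_dwell = 5)
  s1 <- sample_label_sequence(m1, 500, seed = 3)
  expect_true(all(s1$labels == 1L))
  expect_equal(length(rle(s1$labels)$lengths), 1L)
  # geometric dwell with mean 20: empirical mean run length within 5%
  sq <- sample_label_sequence(fixture_model(20), 1e5, seed = 4)
  expect_lt(abs(mean(rle(sq$labels)$lengths) / 20 - 1), 0.05)
  # symmetric chain: stationary coverage 1/7 each, and coverages sum to 1
  sq2 <- sample_label_sequence(fixture_model(20), 2e5, seed = 5)
  cov <- tabulate(sq2$labels, 7) / length(sq2$labels)
  expect_true(all(abs(cov - 1 / 7) < 0.01))
  expect_equal(sum(cov), 1, tolerance = 1e-12)
  # fixed dwell
  sf <- sample_label_sequence(sequence_model(3, mean_dwell = 10,
                                             dwell = "fixed"), 1000, seed = 6)
  expect_true(all(rle(sf$labels)$lengths[-length(rle(sf$labels)$lengths)] == 10))
})

test_that("sequence model validates its transition matrix", {
  expect_error(sequence_model(3, transition = matrix(1 / 3, 3, 3)),
               "diagonal")
  bad <- matrix(c(0, 1, 1, 0.5, 0, 0.2, 0.5, 0, 0.8), 3, 3)
  expect_error(sequence_model(3, transition = bad), "sum to 1")
  expect_error(sample_label_sequence(fixture_model(), 0))
})

test_that("rendered EEG honours the forward model and the SNR contract", {
  tk <- fixture_task(seconds = 4, snr_db = Inf, seed = 11)
  # noiseless identity: backfitting returns the planted labels at every sample
  bf <- backfit(tk$recording, tk$maps)
  expect_identical(bf$labels, tk$labels$labels)
  # zero envelope: all-zero recording
  z <- render_eeg(tk$maps, tk$labels, envelope = rep(0, 1000), seed = 1)
  expect_true(all(z$data == 0))
  # average-reference invariant
  expect_lt(max(abs(colSums(tk$recording$data))), 1e-6)
  # measured signal/noise power ratio within 0.5 dB of the requested 10 dB
  clean <- render_eeg(tk$maps, tk$labels, snr_db = Inf, seed = 21)
  noisy <- render_eeg(tk$maps, tk$labels, snr_db = 10, seed = 21)
  snr_meas <- 10 * log10(mean(clean$data^2) /
                           mean((noisy$data - clean$data)^2))
  expect_lt(abs(snr_meas - 10), 0.5)
  # mismatched envelope length
  expect_error(render_eeg(tk$maps, tk$labels, envelope = rep(1, 10)),
               "length")
})

test_that("protocol simulation yields the printed task structure", {
  spec <- protocol_spec()
  expect_equal(unname(spec$stages), c(7, 8, 7))
  small <- protocol_spec(c(Solo = 1), 2, 3, sampling_rate = 100)
  items <- simulate_protocol(small, fixture_maps(), snr_db = Inf, seed = 1)
  expect_length(items, 2)
  expect_equal(vapply(items, `[[`, "", "task_type"), c("Baseline", "Trial"))
  expect_equal(ncol(items[[1]]$recording$data), 200)  # 2 s at 100 Hz
  expect_equal(ncol(items[[2]]$recording$data), 300)  # 3 s at 100 Hz
  # determinism of the whole protocol
  items2 <- simulate_protocol(small, fixture_maps(), snr_db = Inf, seed = 1)
  expect_identical(items[[2]]$recording$data, items2[[2]]$recording$data)
})

test_that("correlated +/-1 sequences are binary and hit their Hurst targets", {
  x <- sample_correlated_pm1(0.5, 5000, seed = 1)
  expect_setequal(unique(x), c(-1, 1))
  expect_identical(x, sample_correlated_pm1(0.5, 5000, seed = 1))
  expect_error(sample_correlated_pm1(1.2, 5000, seed = 1))
  expect_error(sample_correlated_pm1(0.5, 100, seed = 1))
  h5 <- as.numeric(dfa_hurst(sample_correlated_pm1(0.5, 1e5, seed = 2)))
  h8 <- as.numeric(dfa_hurst(sample_correlated_pm1(0.8, 1e5, seed = 3)))
  expect_lt(abs(h5 - 0.5), 0.05)
  expect_lt(abs(h8 - 0.8), 0.05)
})
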