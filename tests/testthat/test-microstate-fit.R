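test_that("GFP matches its closed forms", {
  rec <- eeg_recording(matrix(5, 4, 10), fs = 100)
  expect_equal(compute_gfp(rec)$values, rep(0, 10))
  # column (c, -c, 0, ..., 0): spatial SD = sqrt(2 c^2 / N)
  N <- 8; cval <- 3
  col <- c(cval, -cval, rep(0, N - 2))
  rec2 <- eeg_recording(cbind(col, 3 * col), fs = 100)
  g <- compute_gfp(rec2)$values
  expect_equal(unname(g[1]), sqrt(2 * cval^2 / N), tolerance = 1e-12)
  expect_equal(unname(g[2]), unname(3 * g[1]), tolerance = 1e-12)
})

test_that("GFP peak picking finds local maxima with spacing and plateaus", {
  fs <- 250
  t <- (seq_len(fs * 2) - 1) / fs
  g <- abs(sin(2 * pi * 10 * t))
  pk <- find_gfp_peaks(g, fs = fs)
  expect_lt(abs(length(pk) / 2 - 20), 2)            # ~20 peaks per second
  expect_error(find_gfp_peaks(seq_len(100), fs = fs), "peak")
  g2 <- rep(1, 100); g2[50] <- 3
  expect_equal(find_gfp_peaks(c(0, g2, 0), fs = fs), 51)
  # plateau counted once, at its centre
  g3 <- c(0, 1, 2, 2, 2, 1, 0)
  expect_equal(find_gfp_peaks(g3, fs = fs), 4)
})

test_that("modified k-means exactly represents noiseless two-map data", {
  set.seed(1)
  v1 <- c(1, -1, rep(0, 6)); v1 <- (v1 - mean(v1)) / sqrt(sum((v1 - mean(v1))^2))
  v2 <- c(0, 0, 1, -1, rep(0, 4)); v2 <- (v2 - mean(v2)) / sqrt(sum((v2 - mean(v2))^2))
  amp <- runif(60, 0.5, 2) * sample(c(-1, 1), 60, TRUE)
  X <- rbind(outer(amp[1:30], v1), outer(amp[31:60], v2))[sample(60), ]
  sol <- modified_kmeans(X, 2, n_init = 10, seed = 5)
  expect_lt(sol$cost_F, 1e-12)
  expect_lt(sol$cv, 1e-12)
  expect_gte(sol$gev, 1 - 1e-9)
})

test_that("fitting recovers planted maps from noisy renders", {
  tk <- fixture_task(seconds = 16, snr_db = 20, seed = 61)
  pk <- find_gfp_peaks(compute_gfp(tk$recording))
  sol <- modified_kmeans(t(tk$recording$data[, pk]), 7, n_init = 8, seed = 9)
  m <- match_maps(tk$maps$maps, sol$maps)
  expect_gte(mean(m$corr), 0.95)
})

test_that("cost, CV and GEV equal their brute-force transcriptions", {
  set.seed(2)
  X <- matrix(rnorm(120 * 16), 120, 16)
  sol <- modified_kmeans(X, 4, n_init = 3, seed = 3)
  expect_equal(sol$cost_F, oracle_cost_F(X, sol$maps, sol$assignments),
               tolerance = 1e-12)
  expect_equal(sol$cv, oracle_cv(X, sol$maps, sol$assignments),
               tolerance = 1e-12)
  expect_equal(cross_validation(sol, X),
               oracle_cv(X, sol$maps, sol$assignments), tolerance = 1e-12)
  expect_equal(sol$gev, oracle_gev(X, sol$maps, sol$assignments),
               tolerance = 1e-12)
  expect_equal(global_explained_variance(sol, X), sol$gev, tolerance = 1e-12)
  expect_gt(sol$gev, 0); expect_lt(sol$gev, 1)
  # quadratic homogeneity: doubling potentials multiplies cost and CV by 4
  sol2 <- modified_kmeans(2 * X, 4, n_init = 3, seed = 3)
  expect_equal(sol2$cost_F, 4 * sol$cost_F, tolerance = 1e-9)
  expect_equal(sol2$cv, 4 * sol$cv, tolerance = 1e-9)
  expect_error(modified_kmeans(X, 15, n_init = 1, seed = 1))
})

test_that("polarity flips and channel permutations leave the fit invariant", {
  set.seed(4)
  X <- matrix(rnorm(100 * 12), 100, 12)
  sol <- modified_kmeans(X, 3, n_init = 4, seed = 8)
  # flipping the sign of every sample
  solf <- modified_kmeans(-X, 3, n_init = 4, seed = 8)
  expect_equal(solf$cost_F, sol$cost_F, tolerance = 1e-12)
  expect_equal(solf$cv, sol$cv, tolerance = 1e-12)
  expect_equal(solf$gev, sol$gev, tolerance = 1e-12)
  # permuting channels permutes maps identically
  p <- sample(12)
  solp <- modified_kmeans(X[, p], 3, n_init = 4, seed = 8)
  expect_equal(solp$cost_F, sol$cost_F, tolerance = 1e-12)
  expect_equal(solp$cv, sol$cv, tolerance = 1e-12)
  expect_equal(abs(solp$maps), abs(sol$maps[, p]), tolerance = 1e-9)
})

test_that("best-of-restarts CV is non-increasing in the number of restarts", {
  tk <- fixture_task(seconds = 4, snr_db = 10, seed = 71)
  pk <- find_gfp_peaks(compute_gfp(tk$recording))
  X <- t(tk$recording$data[, pk])
  cvs <- vapply(c(1, 5, 20), function(ni)
    modified_kmeans(X, 7, n_init = ni, seed = 101)$cv, numeric(1))
  expect_true(all(diff(cvs) <= 1e-12))
})
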