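# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

fixture_maps <- function() {
  if (is.null(.fixture_env$maps))
    .fixture_env$maps <- generate_template_maps(7, 64, 0.7, seed = 42L)
  .fixture_env$maps
}

fixture_model <- function(mean_dwell = 20) sequence_model(7, mean_dwell = mean_dwell)

# one rendered task: labels + recording at the requested SNR
fixture_task <- function(seconds = 8, snr_db = 20, seed = 7L,
                         mean_dwell = 20) {
  maps <- fixture_maps()
  sq <- sample_label_sequence(fixture_model(mean_dwell), round(250 * seconds),
                              fs = 250, seed = seed)
  rec <- render_eeg(maps, sq, snr_db = snr_db, seed = seed + 1L)
  list(maps = maps, labels = sq, recording = rec)
}

# greedy match of recovered maps to reference maps by |spatial correlation|
match_maps <- function(reference, recovered) {
  C <- abs(spatial_correlation(reference, recovered))
  K <- nrow(C)
  perm <- integer(K)
  free <- seq_len(K)
  for (k in order(apply(C, 1, max), decreasing = TRUE)) {
    j <- free[which.max(C[k, free])]
    perm[k] <- j
    free <- setdiff(free, j)
  }
  list(perm = perm, corr = C[cbind(seq_len(K), perm)])
}

# brute-force transcriptions of the clustering cost and CV criteria,
# independent of the fitter's vectorized implementation
oracle_cost_F <- function(X, maps, assign) {
  total <- 0
  for (t in seq_len(nrow(X))) {
    v <- X[t, ]
    k <- assign[t]
    a <- sum(maps[k, ] * v)
    total <- total + sum((v - a * maps[k, ])^2)
  }
  total / (nrow(X) * (ncol(X) - 1))
}

oracle_cv <- function(X, maps, assign) {
  Ns <- ncol(X); Nk <- nrow(maps)
  s <- 0
  for (t in seq_len(nrow(X))) {
    v <- X[t, ]
    s <- s + sum(v * v) - sum(maps[assign[t], ] * v)^2
  }
  (s / (nrow(X) * (Ns - 1))) * ((Ns - 1) / (Ns - 1 - Nk))^2
}

oracle_gev <- function(X, maps, assign) {
  num <- 0; den <- 0
  for (t in seq_len(nrow(X))) {
    v <- X[t, ]
    g2 <- mean(v^2) - mean(v)^2
    num <- num + g2 * stats::cor(v, maps[assign[t], ])^2
    den <- den + g2
  }
  num / den
}

# run-length scan oracle for microstate parameters
oracle_parameters <- function(labels, fs, K) {
  n <- length(labels)
  runs <- list()
  start <- 1
  for (t in seq_len(n)) {
    if (t == n || labels[t + 1] != labels[t]) {
      runs[[length(runs) + 1]] <- c(labels[start], t - start + 1)
      start <- t + 1
    }
  }
  rl <- do.call(rbind, runs)
  t(vapply(seq_len(K), function(k) {
    len <- rl[rl[, 1] == k, 2]
    c(coverage = sum(len) / n,
      occurrence = length(len) / (n / fs),
      duration = if (length(len)) mean(len) * 1000 / fs else NA_real_)
  }, numeric(3)))
}
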