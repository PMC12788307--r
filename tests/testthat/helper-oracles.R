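# Independent brute-force oracles and fixture builders shared by the suite.
# These deliberately use different algorithms from the package internals
# (Floyd-Warshall instead of BFS, triple loops instead of A^3, explicit
# normal equations instead of lm).

# all-pairs shortest paths, Floyd-Warshall
fw_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

bf_global_efficiency <- function(adj) {
  n <- nrow(adj)
  D <- fw_distances(adj)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

bf_local_efficiency <- function(adj) {
  n <- nrow(adj)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    bf_global_efficiency(adj[nb, nb, drop = FALSE])
  }, 0))
}

# average clustering by exhaustive enumeration of node triples
bf_clustering <- function(adj) {
  n <- nrow(adj)
  tri <- numeric(n)
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      if (adj[i, j] && adj[j, k] && adj[i, k]) {
        tri[i] <- tri[i] + 1; tri[j] <- tri[j] + 1; tri[k] <- tri[k] + 1
      }
    }
  }
  deg <- rowSums(adj)
  mean(ifelse(deg < 2, 0, tri / (deg * (deg - 1) / 2)))
}

random_adjacency <- function(n, p = 0.3) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1L, p)
  a + t(a)
}

random_symmetric <- function(n) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- stats::runif(n * (n - 1) / 2)
  w + t(w)
}

# ANCOVA F and p from explicit normal equations / projections
ne_ancova <- function(values, group, age) {
  g <- as.numeric(factor(group, levels = c("control", "patient"))) - 1
  X_full <- cbind(1, g, age)
  X_red <- cbind(1, age)
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% values)
    r <- values - X %*% beta
    sum(r^2)
  }
  rss_f <- rss(X_full); rss_r <- rss(X_red)
  df2 <- length(values) - ncol(X_full)
  f <- (rss_r - rss_f) / (rss_f / df2)
  list(f = f, p = stats::pf(f, 1, df2, lower.tail = FALSE))
}

# step-up BH directly from its definition
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  ps <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ps)))
  pmin(1, adj)[order(o)]
}

# single- or multi-channel recording from explicit signals
sine_recording <- function(freqs, fs = 250, dur = 10, amps = 1, phases = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  amps <- rep_len(amps, length(freqs))
  phases <- rep_len(phases, length(freqs))
  data <- t(vapply(seq_along(freqs), function(i)
    amps[i] * sin(2 * pi * freqs[i] * t + phases[i]), t))
  eeg_recording(data, fs, paste0("ch", seq_along(freqs)))
}

# band-limited Gaussian noise via frequency-domain masking
bandlimited_noise <- function(n, fs, lo, hi) {
  spec <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  spec[f < lo | f > hi] <- 0
  Re(stats::fft(spec, inverse = TRUE)) / n
}

quiet_cohort <- function(n_per_group = 2, duration = 10, seed = 1, ...) {
  generate_cohort(simulation_config(
    n_patients = n_per_group, n_controls = n_per_group, seed = seed,
    task_schedule = data.frame(task = "resting", duration = duration), ...))
}
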