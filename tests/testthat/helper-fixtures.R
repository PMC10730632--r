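# Shared fixtures and independent oracles used across test files.

# step curve: baseline value then a jump at a given sample index
step_tic <- function(base = 100, jump_to = 130, n = 10, jump_at = 6,
                     dt = 1, baseline_window = NULL) {
  si <- c(rep(base, jump_at - 1), rep(jump_to, n - jump_at + 1))
  new_tic(seq(0, by = dt, length.out = n), si, baseline_window)
}

# linear-rise curve with explicit pre-onset baseline window
rise_tic <- function(base = 100, onset = 10, slope = 10, peak = 200,
                     t_end = 30, dt = 1) {
  t <- seq(0, t_end, by = dt)
  p <- enhancement_params(base, onset, slope, peak, washout_rate = 0)
  new_tic(t, osteodce:::enhancement_model(p, t),
          baseline_window = which(t < onset))
}

# brute-force onset oracle: for every candidate index, recompute the
# baseline mean from scratch and test the 20% rule; first qualifying wins
brute_force_t0 <- function(tic, threshold_frac = 0.20, min_baseline = 2L) {
  n <- length(tic$si)
  for (i in seq.int(min_baseline + 1L, n)) {
    base_mean <- sum(tic$si[seq_len(i - 1L)]) / (i - 1L)
    if (base_mean > 0 && tic$si[i] > (1 + threshold_frac) * base_mean) {
      return(list(t0 = tic$times[i], index = i, enhancing = TRUE))
    }
  }
  list(t0 = NA_real_, index = NA_integer_, enhancing = FALSE)
}

# random curves for oracle-equivalence checks: mix of flat, noisy-flat,
# enhancing and decaying shapes on irregular grids
random_tic <- function() {
  n <- sample(5:40, 1)
  t <- cumsum(runif(n, 0.5, 4))
  shape <- sample(1:4, 1)
  si <- switch(shape,
    rep(runif(1, 50, 200), n),
    runif(1, 50, 200) + rnorm(n, sd = 5),
    {
      onset <- runif(1, t[2], t[n - 1])
      base <- runif(1, 50, 200)
      base + pmax(0, t - onset) * runif(1, 1, 30) + rnorm(n, sd = 2)
    },
    sort(runif(n, 50, 200), decreasing = TRUE)
  )
  new_tic(t, pmax(si, 0))
}

# exhaustive Youden oracle: evaluate J at every cut, including the two
# degenerate cuts below and above all probabilities
brute_force_youden <- function(probs, y) {
  u <- sort(unique(probs))
  mids <- if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2 else numeric(0)
  cands <- c(min(u) - 1, mids, max(u) + 1)
  best_j <- -Inf
  best_t <- NA_real_
  for (th in cands) {
    pred <- as.integer(probs >= th)
    j <- sum(pred == 1 & y == 1) / sum(y == 1) +
      sum(pred == 0 & y == 0) / sum(y == 0) - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_t <- th
    }
  }
  list(threshold = best_t, J = best_j)
}

# small two-subregion phantom used by extraction tests
phantom_series <- function(noise_sd = 0, seed = 3,
                           sub_params = enhancement_params(100, 12, 15, 350,
                                                           0.005)) {
  grid <- make_sampling_grid(120, 1, 3, 6)
  geom <- list(
    dim = c(48, 48),
    tumor = list(center = c(24, 24), n_pix = 300),
    subregions = list(list(center = c(21, 22), n_pix = 60,
                           params = sub_params)),
    artery = list(center = c(42, 8), n_pix = 12)
  )
  generate_dce_series(
    tumor_params = enhancement_params(100, 16, 8, 300, 0.005),
    artery_params = enhancement_params(200, 9, 120, 600, 0.01),
    geometry = geom, grid = grid, seed = seed, noise_sd = noise_sd
  )
}
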