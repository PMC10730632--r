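#' Parametric enhancement model for a single tissue region
#'
#' The synthetic signal model is piecewise: flat at `baseline_si` before
#' `onset_time`, a linear rise at `wash_in_slope` until `peak_si` is reached,
#' then exponential washout back towards baseline at rate `washout_rate`.
#' This is the simplest curve shape that exposes all four semi-quantitative
#' perfusion features (onset, wash-in rate, peak enhancement, curve AUC).
#'
#' @param baseline_si pre-contrast signal intensity, arbitrary units > 0.
#' @param onset_time bolus-arrival time in seconds (>= 0).
#' @param wash_in_slope linear rise in signal units per second (>= 0).
#' @param peak_si peak signal intensity (>= `baseline_si`).
#' @param washout_rate exponential decay rate after the peak, 1/s (>= 0).
#' @param noise_sd standard deviation of additive i.i.d. Gaussian noise in
#'   signal units (>= 0).
#' @return An object of class `enhancement_params`.
#' @export
enhancement_params <- function(baseline_si, onset_time, wash_in_slope,
                               peak_si, washout_rate = 0, noise_sd = 0) {
  if (baseline_si <= 0) stop("`baseline_si` must be > 0")
  if (onset_time < 0) stop("`onset_time` must be >= 0")
  if (wash_in_slope < 0) stop("`wash_in_slope` must be >= 0")
  if (peak_si < baseline_si) stop("`peak_si` must be >= `baseline_si`")
  if (washout_rate < 0) stop("`washout_rate` must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(
    list(baseline_si = baseline_si, onset_time = onset_time,
         wash_in_slope = wash_in_slope, peak_si = peak_si,
         washout_rate = washout_rate, noise_sd = noise_sd),
    class = "enhancement_params"
  )
}

# Noiseless model curve evaluated at times t (vectorized).
enhancement_model <- function(params, t) {
  p <- params
  si <- rep(p$baseline_si, length(t))
  if (p$wash_in_slope > 0 && p$peak_si > p$baseline_si) {
    t_peak <- p$onset_time + (p$peak_si - p$baseline_si) / p$wash_in_slope
    rising <- t >= p$onset_time & t < t_peak
    si[rising] <- p$baseline_si + p$wash_in_slope * (t[rising] - p$onset_time)
    post <- t >= t_peak
    si[post] <- p$baseline_si +
      (p$peak_si - p$baseline_si) * exp(-p$washout_rate * (t[post] - t_peak))
  }
  si
}

#' Simulate a time-intensity curve
#'
#' Evaluates the piecewise enhancement model on a sampling grid and adds
#' i.i.d. Gaussian noise. The returned curve's baseline window is the set of
#' pre-injection frames of the grid. Reproducible for a fixed `seed`.
#'
#' @param params an [enhancement_params()] object.
#' @param grid a [make_sampling_grid()] object.
#' @param seed integer seed for the noise draw (ignored when `noise_sd` is 0).
#' @return A [new_tic()] object.
#' @export
generate_tic <- function(params, grid, seed = 1) {
  stopifnot(inherits(params, "enhancement_params"),
            inherits(grid, "sampling_grid"))
  si <- enhancement_model(params, grid$times)
  if (params$noise_sd > 0) {
    noise <- withr::with_seed(seed,
      stats::rnorm(length(si), sd = params$noise_sd))
    si <- pmax(si + noise, 0)
  }
  nb <- n_preinjection(grid)
  new_tic(grid$times, si,
          baseline_window = if (nb >= 1) seq_len(nb) else NULL)
}
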