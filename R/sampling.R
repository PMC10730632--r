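#' Dynamic-series sampling grid
#'
#' Build the acquisition time grid of a dynamic contrast-enhanced series:
#' dense sampling (typically 1 s) for the first minute, when the bolus
#' arrives, and coarser sampling (3-4 s) afterwards. Acquisition starts
#' `injection_offset` seconds before contrast injection, so the first
#' `injection_offset / fine_dt` frames are pre-injection baseline frames.
#'
#' @param duration_s total acquisition duration in seconds (> 60).
#' @param fine_dt sampling interval during the first minute, seconds.
#' @param coarse_dt sampling interval after the first minute, seconds
#'   (must be >= `fine_dt`).
#' @param injection_offset seconds between acquisition start and contrast
#'   injection; default 6 s.
#' @return An object of class `sampling_grid`: a list with `times` (seconds
#'   from acquisition start, strictly increasing, starting at 0) and
#'   `injection_offset`.
#' @examples
#' g <- make_sampling_grid(300, 1, 3)
#' head(g$times)
#' @export
make_sampling_grid <- function(duration_s, fine_dt = 1, coarse_dt = 3,
                               injection_offset = 6) {
  if (!is.numeric(duration_s) || duration_s <= 60) {
    stop("`duration_s` must exceed 60 s (dense first-minute window)")
  }
  if (fine_dt <= 0 || coarse_dt <= 0) {
    stop("sampling intervals must be positive")
  }
  if (fine_dt > coarse_dt) {
    stop("`fine_dt` must not exceed `coarse_dt`")
  }
  if (injection_offset < 0) stop("`injection_offset` must be >= 0")
  fine <- seq(0, 60 - fine_dt, by = fine_dt)
  coarse <- seq(max(fine) + coarse_dt, duration_s, by = coarse_dt)
  grid <- list(times = c(fine, coarse), injection_offset = injection_offset)
  class(grid) <- "sampling_grid"
  grid
}

#' @export
print.sampling_grid <- function(x, ...) {
  cat(sprintf(
    "<sampling_grid> %d frames over %.0f s (injection at %.0f s)\n",
    length(x$times), max(x$times), x$injection_offset
  ))
  invisible(x)
}

n_preinjection <- function(grid) {
  sum(grid$times < grid$injection_offset)
}
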