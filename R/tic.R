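#' Time-intensity curve
#'
#' A time-intensity curve (TIC) is the mean ROI signal intensity per dynamic
#' frame. `baseline_window` indexes the frames considered non-enhanced
#' (normally the pre-injection frames); it is used to normalize the wash-in
#' rate, maximum relative enhancement and curve AUC. Onset detection
#' ([detect_t0()]) never uses it — the 20% rule defines its own baseline.
#'
#' @param times acquisition times in seconds, strictly increasing.
#' @param si mean ROI signal intensities, same length as `times`, >= 0.
#' @param baseline_window integer indices of baseline (pre-injection) frames,
#'   or `NULL` when unknown.
#' @return An object of class `tic`.
#' @export
new_tic <- function(times, si, baseline_window = NULL) {
  if (length(times) != length(si)) {
    stop("`times` and `si` must have equal length")
  }
  if (length(times) >= 2 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing")
  }
  if (any(si < 0)) stop("signal intensities must be >= 0")
  if (!is.null(baseline_window)) {
    baseline_window <- as.integer(baseline_window)
    if (any(baseline_window < 1L) || any(baseline_window > length(si))) {
      stop("`baseline_window` indices out of range")
    }
  }
  structure(
    list(times = as.numeric(times), si = as.numeric(si),
         baseline_window = baseline_window),
    class = "tic"
  )
}

#' @export
print.tic <- function(x, ...) {
  cat(sprintf(
    "<tic> %d samples, t = [%.1f, %.1f] s, SI range [%.1f, %.1f]%s\n",
    length(x$times), min(x$times), max(x$times), min(x$si), max(x$si),
    if (is.null(x$baseline_window)) "" else
      sprintf(", %d baseline frames", length(x$baseline_window))
  ))
  invisible(x)
}

#' @export
as.data.frame.tic <- function(x, ...) {
  data.frame(time_s = x$times, si = x$si)
}

# Mean baseline signal used to normalize WIR/MRE/AUC. Prefers the explicit
# pre-injection window; falls back to the self-consistent pre-onset window
# found by the 20% rule.
tic_baseline_mean <- function(tic, t0_index = NULL) {
  if (!is.null(tic$baseline_window)) {
    return(mean(tic$si[tic$baseline_window]))
  }
  if (is.null(t0_index)) {
    det <- detect_t0(tic)
    t0_index <- det$index
  }
  if (is.na(t0_index)) return(mean(tic$si))
  mean(tic$si[seq_len(t0_index - 1L)])
}
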