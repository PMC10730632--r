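#' Onset of enhancement (T0)
#'
#' T0 is the first time point at which the signal intensity rises more than
#' `threshold_frac` (20\% by default) above the mean signal of all earlier
#' time points. The definition is self-referential (the baseline is
#' everything before T0), which is resolved by a left-to-right scan: the
#' candidate baseline grows sample by sample until the rule fires. At least
#' `min_baseline` samples must precede a candidate, so a spike in the very
#' first frames cannot trigger.
#'
#' @param tic a [new_tic()] with at least 3 samples.
#' @param threshold_frac relative rise over baseline that defines onset.
#' @param min_baseline minimum number of baseline samples before onset.
#' @return list with `t0` (seconds, `NA` when non-enhancing), `index`
#'   (sample index of onset), and `enhancing` (logical).
#' @export
detect_t0 <- function(tic, threshold_frac = 0.20, min_baseline = 2L) {
  stopifnot(inherits(tic, "tic"))
  n <- length(tic$si)
  if (n < 3) stop("onset detection needs at least 3 samples")
  csum <- cumsum(tic$si)
  for (i in seq.int(min_baseline + 1L, n)) {
    base_mean <- csum[i - 1L] / (i - 1L)
    if (base_mean > 0 && tic$si[i] > (1 + threshold_frac) * base_mean) {
      return(list(t0 = tic$times[i], index = i, enhancing = TRUE))
    }
  }
  list(t0 = NA_real_, index = NA_integer_, enhancing = FALSE)
}

#' Time to enhancement (TTE)
#'
#' Difference between the tumor's and the regional artery's onset of
#' enhancement. The bolus reaches the artery first, so TTE is normally
#' positive; a negative value (tumor apparently enhancing before the
#' artery) is returned with a warning.
#'
#' @param tumor_tic,artery_tic [new_tic()] objects.
#' @return TTE in seconds, or `NA` when either curve does not enhance.
#' @export
compute_tte <- function(tumor_tic, artery_tic) {
  dt_t <- detect_t0(tumor_tic)
  dt_a <- detect_t0(artery_tic)
  if (!dt_t$enhancing || !dt_a$enhancing) {
    warning("non-enhancing curve: TTE undefined")
    return(NA_real_)
  }
  tte <- dt_t$t0 - dt_a$t0
  if (tte < 0) warning("tumor onset precedes artery onset (negative TTE)")
  tte
}

#' Wash-in rate (WIR)
#'
#' Maximum rise in signal per second between onset and the time of peak
#' enhancement, expressed as a fraction of the baseline signal. The default
#' `"max_pair"` estimator takes slopes over consecutive sample pairs only
#' (an all-pairs slope would be diluted by plateaus); the pair ending at
#' the onset sample is included so that a single-frame jump to plateau
#' yields `jump / (dt * baseline)`. On noisy curves the maximum of many
#' single-pair slopes is biased upward (an order-statistic effect);
#' `"rise_chord"` instead takes the chord slope from the onset sample to
#' the first sample within 3 baseline-noise standard deviations of the
#' peak, which is exact on a linear rise and far less noise-sensitive.
#' Both estimators coincide on noiseless piecewise-linear curves.
#'
#' @param tic a [new_tic()].
#' @param method `"max_pair"` (default) or `"rise_chord"`.
#' @return WIR in 1/s (fraction of baseline per second), floored at 0;
#'   `NA` for a non-enhancing curve.
#' @export
compute_wir <- function(tic, method = c("max_pair", "rise_chord")) {
  method <- match.arg(method)
  det <- detect_t0(tic)
  if (!det$enhancing) return(NA_real_)
  base <- tic_baseline_mean(tic, det$index)
  if (base <= 0) stop("degenerate (non-positive) baseline signal")
  max_pair <- function(upper_idx) {
    ks <- seq.int(det$index, max(det$index, upper_idx))
    ks <- ks[ks >= 2]
    slopes <- (tic$si[ks] - tic$si[ks - 1L]) /
      (tic$times[ks] - tic$times[ks - 1L])
    max(0, max(slopes) / base)
  }
  if (method == "max_pair") {
    return(max_pair(which.max(tic$si)))
  }
  noise_sd <- if (!is.null(tic$baseline_window) &&
                  length(tic$baseline_window) >= 3) {
    stats::sd(tic$si[tic$baseline_window])
  } else 0
  near_peak <- max(tic$si) - 3 * noise_sd
  p <- which(tic$si >= near_peak & seq_along(tic$si) >= det$index)[1]
  if (is.na(p) || p <= det$index) return(max_pair(det$index))
  max(0, (tic$si[p] - tic$si[det$index]) /
        (tic$times[p] - tic$times[det$index]) / base)
}

#' Maximum relative enhancement (MRE)
#'
#' Peak signal relative to the non-enhanced baseline signal. The default
#' convention is the enhancement fraction `(max - baseline) / baseline`; the
#' raw ratio `max / baseline` differs by the additive 1 and is available via
#' `convention = "ratio"`.
#'
#' @param tic a [new_tic()].
#' @param convention `"net"` (default) or `"ratio"`.
#' @return dimensionless MRE (>= 0 under `"net"` for an enhancing curve).
#' @export
compute_mre <- function(tic, convention = c("net", "ratio")) {
  convention <- match.arg(convention)
  det <- detect_t0(tic)
  base <- tic_baseline_mean(tic, det$index)
  if (base <= 0) stop("degenerate (non-positive) baseline signal")
  if (!det$enhancing) return(if (convention == "net") 0 else 1)
  m <- max(tic$si) / base
  if (convention == "net") m - 1 else m
}

#' Curve AUC (integrated relative enhancement)
#'
#' Trapezoidal integral of the baseline-relative signal over time, from
#' onset to the last acquired sample, honoring the non-uniform sampling
#' grid. The default integrand is the net enhancement
#' `(si - baseline) / baseline`; `integrand = "ratio"` integrates
#' `si / baseline` instead.
#'
#' @param tic a [new_tic()].
#' @param integrand `"net"` (default) or `"ratio"`.
#' @return AUC in seconds (the integrand is dimensionless); 0 for a
#'   non-enhancing curve.
#' @export
compute_auc <- function(tic, integrand = c("net", "ratio")) {
  integrand <- match.arg(integrand)
  det <- detect_t0(tic)
  base <- tic_baseline_mean(tic, det$index)
  if (base <= 0) stop("degenerate (non-positive) baseline signal")
  if (!det$enhancing) return(0)
  ks <- seq.int(det$index, length(tic$si))
  if (length(ks) < 2) return(0)
  y <- if (integrand == "net") (tic$si[ks] - base) / base else tic$si[ks] / base
  sum(diff(tic$times[ks]) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' All perfusion features of one scan
#'
#' Convenience wrapper computing T0, TTE (against an artery curve, when
#' given), WIR, MRE and AUC for one tumor TIC.
#'
#' @param tic tumor [new_tic()].
#' @param artery_tic optional regional-artery [new_tic()] for TTE.
#' @param mre_convention,auc_integrand passed to [compute_mre()] /
#'   [compute_auc()].
#' @param wir_method passed to [compute_wir()].
#' @return list of class `perfusion_features`: `t0`, `tte`, `wir`, `mre`,
#'   `auc`, `enhancing`, plus `t_end` and `artery_t0` used for censoring
#'   non-enhancing post-treatment scans.
#' @export
perfusion_features <- function(tic, artery_tic = NULL,
                               mre_convention = "net",
                               auc_integrand = "net",
                               wir_method = "max_pair") {
  det <- detect_t0(tic)
  artery_t0 <- NA_real_
  tte <- NA_real_
  if (!is.null(artery_tic)) {
    det_a <- detect_t0(artery_tic)
    if (det_a$enhancing) artery_t0 <- det_a$t0
    if (det$enhancing && det_a$enhancing) tte <- det$t0 - artery_t0
  }
  out <- list(
    t0 = det$t0,
    tte = tte,
    wir = if (det$enhancing) compute_wir(tic, wir_method) else NA_real_,
    mre = if (det$enhancing) compute_mre(tic, mre_convention) else NA_real_,
    auc = if (det$enhancing) compute_auc(tic, auc_integrand) else 0,
    enhancing = det$enhancing,
    t_end = max(tic$times),
    artery_t0 = artery_t0
  )
  class(out) <- "perfusion_features"
  out
}

# Censoring conventions for a non-enhancing (total-response) scan: rate and
# enhancement features at the eps floor so pre/post ratios stay finite and
# large; onset censored at the end of acquisition, so TTE becomes
# (t_end - artery T0).
censored_values <- function(fs, eps) {
  if (fs$enhancing) return(fs)
  fs$wir <- eps
  fs$mre <- eps
  fs$auc <- eps
  if (!is.na(fs$artery_t0)) fs$tte <- fs$t_end - fs$artery_t0
  fs
}

#' Relative-change features across the pre/post-chemotherapy pair
#'
#' Ratio features divide the pre-treatment value by the post-treatment value
#' (a strong responder loses perfusion, so ratios are large); the TTE change
#' is post minus pre; rVolume is the pre/post ellipsoid volume ratio. A
#' non-enhancing post scan (total response) is censored: its rate and
#' enhancement features are floored at `eps` and its onset at the end of
#' acquisition, keeping ratios finite and on the good-response side.
#'
#' @param pre,post [perfusion_features()] of the pre/post scans.
#' @param vol_pre_mm3,vol_post_mm3 ellipsoid tumor volumes (> 0).
#' @param eps positive floor for denominators, in baseline-relative units.
#' @return list of class `relative_features`: `r_wir`, `r_mre`, `r_auc`,
#'   `delta_tte`, `r_volume`.
#' @export
relative_features <- function(pre, post, vol_pre_mm3, vol_post_mm3,
                              eps = 1e-6) {
  if (eps <= 0) stop("`eps` must be > 0")
  if (vol_pre_mm3 <= 0 || vol_post_mm3 <= 0) {
    stop("volumes must be > 0")
  }
  if (!pre$enhancing) {
    warning("pre-treatment scan non-enhancing; ratio features censored")
    pre <- censored_values(pre, eps)
  }
  post <- censored_values(post, eps)
  out <- list(
    r_wir = pre$wir / max(post$wir, eps),
    r_mre = pre$mre / max(post$mre, eps),
    r_auc = pre$auc / max(post$auc, eps),
    delta_tte = post$tte - pre$tte,
    r_volume = vol_pre_mm3 / vol_post_mm3
  )
  class(out) <- "relative_features"
  out
}

#' Average the feature sets of the two focal ROIs
#'
#' Field-wise arithmetic mean of two [perfusion_features()] sets from the
#' same scan. If exactly one ROI is non-enhancing its values enter the
#' average under the censoring conventions (eps-floored rates, onset at end
#' of acquisition) rather than being dropped.
#'
#' @param fs1,fs2 [perfusion_features()] objects.
#' @param eps censoring floor.
#' @return a `perfusion_features` list.
#' @export
focal_average <- function(fs1, fs2, eps = 1e-6) {
  a <- censored_values(fs1, eps)
  b <- censored_values(fs2, eps)
  out <- list(
    t0 = mean(c(a$t0, b$t0), na.rm = TRUE),
    tte = mean(c(a$tte, b$tte)),
    wir = mean(c(a$wir, b$wir)),
    mre = mean(c(a$mre, b$mre)),
    auc = mean(c(a$auc, b$auc)),
    enhancing = a$enhancing || b$enhancing,
    t_end = max(a$t_end, b$t_end),
    artery_t0 = a$artery_t0
  )
  class(out) <- "perfusion_features"
  out
}
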