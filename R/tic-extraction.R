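#' Subtraction imaging
#'
#' Subtracts the first (baseline) frame from every frame of the series, the
#' standard preprocessing used to visualize early and fast enhancing
#' regions. Negative differences are signal drops below baseline — noise in
#' this context — and are clipped at zero with a warning.
#'
#' @param series a [dce_series()] with at least two frames.
#' @return a [dce_series()] of the same shape; frame 1 is all zero.
#' @export
compute_subtraction <- function(series) {
  stopifnot(inherits(series, "dce_series"))
  nt <- dim(series$pixels)[3]
  if (nt < 2) stop("subtraction requires at least two frames")
  base <- series$pixels[, , 1]
  out <- sweep(series$pixels, c(1, 2), base, "-")
  if (any(out < 0)) {
    warning("negative subtraction values clipped to 0")
    out[out < 0] <- 0
  }
  dce_series(out, series$times, series$injection_offset,
             series$pixel_spacing)
}

#' Extract a time-intensity curve from a masked region
#'
#' The curve value at each frame is the arithmetic mean signal over the
#' masked pixels. The baseline window is initialized to the pre-injection
#' frames of the series.
#'
#' @param series a [dce_series()].
#' @param mask logical matrix aligned with the series' spatial grid.
#' @return a [new_tic()].
#' @export
extract_tic <- function(series, mask) {
  stopifnot(inherits(series, "dce_series"))
  mask <- as.logical(mask)
  dim(mask) <- dim(series$pixels)[1:2]
  if (!any(mask)) stop("empty ROI mask")
  if (!identical(dim(mask), dim(series$pixels)[1:2])) {
    stop("mask not aligned with series spatial grid")
  }
  nt <- dim(series$pixels)[3]
  flat <- matrix(series$pixels, ncol = nt)
  si <- colMeans(flat[as.vector(mask), , drop = FALSE])
  nb <- sum(series$times < series$injection_offset)
  new_tic(series$times, si,
          baseline_window = if (nb >= 1) seq_len(nb) else NULL)
}

# 3x3 box smoothing of one frame (edge pixels average available neighbors).
smooth3x3 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  acc <- matrix(0, nx, ny)
  cnt <- matrix(0, nx, ny)
  for (dx in -1:1) {
    for (dy in -1:1) {
      xs <- max(1, 1 + dx):min(nx, nx + dx)
      ys <- max(1, 1 + dy):min(ny, ny + dy)
      acc[xs - dx, ys - dy] <- acc[xs - dx, ys - dy] + m[xs, ys]
      cnt[xs - dx, ys - dy] <- cnt[xs - dx, ys - dy] + 1
    }
  }
  acc / cnt
}

# Per-pixel onset index by the 20% rule (vectorized left-to-right scan over
# a pixels x frames matrix); returns NA where no frame qualifies. `min_base`
# baseline samples are required before any index may fire.
pixel_onset_scan <- function(flat, min_base = 2L) {
  np <- nrow(flat); nt <- ncol(flat)
  onset <- rep(NA_integer_, np)
  csum <- t(apply(flat, 1, cumsum))
  if (np == 1) csum <- matrix(csum, nrow = 1)
  for (i in seq.int(min_base + 1L, nt)) {
    base_mean <- csum[, i - 1L] / (i - 1L)
    fire <- is.na(onset) & flat[, i] > 1.2 * base_mean & base_mean > 0
    onset[fire] <- i
    if (!anyNA(onset)) break
  }
  onset
}

#' Place the two focal circular ROIs
#'
#' Deterministic stand-in for the visual placement of two small circular
#' ROIs (about 10-20 mm^2) in the earliest and fastest enhancing regions of
#' the tumor, as seen on the subtraction images. Each pixel of the smoothed
#' subtraction stack is ranked by earliest onset (20\% rule), then by the
#' largest baseline-relative wash-in slope; the two discs are centered on
#' the best-ranked pixels whose discs fit inside the whole-slab mask and do
#' not overlap each other. When onsets do not differ across the tumor the
#' ranking falls back to the most intense enhancement (peak subtraction
#' signal).
#'
#' @param series the dynamic series (raw; subtraction is computed
#'   internally).
#' @param whole_slab_mask logical tumor mask.
#' @param roi_area_mm2 requested focal ROI area; default 15 mm^2.
#' @param pixel_spacing mm per pixel (length 2); defaults to the series'.
#' @return list of two logical masks (`focal_1`, `focal_2`).
#' @export
place_focal_rois <- function(series, whole_slab_mask, roi_area_mm2 = 15,
                             pixel_spacing = NULL) {
  stopifnot(inherits(series, "dce_series"))
  if (is.null(pixel_spacing)) pixel_spacing <- series$pixel_spacing
  if (roi_area_mm2 < 10 || roi_area_mm2 > 20) {
    stop("`roi_area_mm2` must lie in [10, 20] mm^2")
  }
  mask <- whole_slab_mask
  n_pix <- max(1L, round(roi_area_mm2 / prod(pixel_spacing)))
  sub <- suppressWarnings(compute_subtraction(series))
  sm <- sub$pixels
  nt <- dim(sm)[3]
  for (k in seq_len(nt)) sm[, , k] <- smooth3x3(sm[, , k])

  idx <- which(mask)
  if (length(idx) < 2 * n_pix) stop("tumor too small for two focal ROIs")
  flat <- matrix(sm, ncol = nt)[idx, , drop = FALSE]
  # shift to a positive pseudo-baseline so the relative 20% rule is
  # well-defined on subtraction values that start at 0
  flat_b <- flat + 1
  onset <- pixel_onset_scan(flat_b)
  dt <- diff(series$times)
  slopes <- t(apply(flat, 1, function(v) diff(v) / dt))
  max_slope <- apply(slopes, 1, max)
  peak <- apply(flat, 1, max)

  enhancing <- !is.na(onset)
  if (sum(enhancing) >= 2 && length(unique(onset[enhancing])) > 1) {
    ord <- order(onset, -max_slope, idx)    # idx = row-major tie-break
  } else {
    ord <- order(-peak, idx)                # intensity fallback
  }

  dim_xy <- dim(mask)
  centers_xy <- arrayInd(idx, dim_xy)
  placed <- list()
  taken <- matrix(FALSE, dim_xy[1], dim_xy[2])
  for (r in ord) {
    cand <- disc_mask(dim_xy, centers_xy[r, ], n_pix)
    if (sum(cand) < n_pix) next          # clipped by image edge
    if (!all(mask[cand])) next           # must sit inside the tumor
    if (any(taken & cand)) next          # disjoint from the first ROI
    placed[[length(placed) + 1]] <- cand
    taken <- taken | cand
    if (length(placed) == 2) break
  }
  if (length(placed) < 2) stop("tumor too small for two focal ROIs")
  names(placed) <- c("focal_1", "focal_2")
  placed
}

#' Select the single slice of largest tumor area from a volumetric series
#'
#' The whole-slab method operates on the one slice containing the largest
#' tumor cross-section. Given a 3D+t series (x, y, z, t) and a 3D tumor
#' mask, this picks the slice maximizing in-plane mask area and returns the
#' corresponding 2D+t series and 2D mask.
#'
#' @param pixels_4d numeric array with dims (x, y, z, t).
#' @param mask_3d logical array with dims (x, y, z).
#' @param times,injection_offset,pixel_spacing series metadata, as in
#'   [dce_series()].
#' @return list with `series` (a [dce_series()]), `mask` (2D logical) and
#'   `slice` (the selected z index; earliest wins ties).
#' @export
select_largest_slice <- function(pixels_4d, mask_3d, times,
                                 injection_offset = 6,
                                 pixel_spacing = c(1, 1)) {
  if (length(dim(pixels_4d)) != 4) stop("`pixels_4d` must have dims (x, y, z, t)")
  if (!identical(dim(mask_3d), dim(pixels_4d)[1:3])) {
    stop("mask not aligned with series spatial grid")
  }
  areas <- apply(mask_3d, 3, sum)
  if (max(areas) == 0) stop("empty ROI mask")
  z <- which.max(areas)
  list(
    series = dce_series(pixels_4d[, , z, , drop = TRUE], times,
                        injection_offset, pixel_spacing),
    mask = mask_3d[, , z],
    slice = z
  )
}

#' Ellipsoid tumor volume from three diameters
#'
#' @param d1_mm,d2_mm,d3_mm orthogonal tumor diameters in mm (> 0).
#' @return volume in mm^3, `(pi/6) d1 d2 d3`.
#' @examples
#' estimate_volume(10, 10, 10)  # 523.6 mm^3
#' @export
estimate_volume <- function(d1_mm, d2_mm, d3_mm) {
  if (any(c(d1_mm, d2_mm, d3_mm) <= 0)) stop("diameters must be > 0")
  (pi / 6) * d1_mm * d2_mm * d3_mm
}
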