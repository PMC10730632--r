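#' Dynamic contrast-enhanced image series
#'
#' Container for a 2D+t dynamic series: a `nx x ny x nt` array of signal
#' intensities with one acquisition timestamp per frame.
#'
#' @param pixels numeric array, dims `c(nx, ny, nt)`.
#' @param times acquisition times in seconds, length `nt`, strictly
#'   increasing.
#' @param injection_offset seconds between acquisition start and injection.
#' @param pixel_spacing in-plane pixel size in mm, length 2; defaults to
#'   1 x 1 mm when the series carries no geometry.
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(pixels, times, injection_offset = 6,
                       pixel_spacing = c(1, 1)) {
  pixels <- as.array(pixels)
  if (length(dim(pixels)) != 3) stop("`pixels` must be a 3D (x, y, t) array")
  if (dim(pixels)[3] != length(times)) {
    stop("frame count must equal timestamp count")
  }
  if (length(times) >= 2 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing")
  }
  structure(
    list(pixels = pixels, times = as.numeric(times),
         injection_offset = injection_offset,
         pixel_spacing = as.numeric(pixel_spacing)),
    class = "dce_series"
  )
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<dce_series> %d x %d pixels, %d frames over %.0f s\n",
              d[1], d[2], d[3], max(x$times)))
  invisible(x)
}

disc_offsets <- function(n_pix) {
  # n_pix nearest integer offsets to the origin: a filled discrete circle
  # with exactly the requested pixel count. Ties broken by row-major order
  # so placement is fully deterministic.
  r <- ceiling(sqrt(n_pix / pi)) + 2L
  g <- expand.grid(dx = -r:r, dy = -r:r)
  d2 <- g$dx^2 + g$dy^2
  ord <- order(d2, g$dx, g$dy)
  g[ord[seq_len(n_pix)], , drop = FALSE]
}

disc_mask <- function(dim_xy, center, n_pix) {
  off <- disc_offsets(n_pix)
  m <- matrix(FALSE, dim_xy[1], dim_xy[2])
  xs <- center[1] + off$dx
  ys <- center[2] + off$dy
  keep <- xs >= 1 & xs <= dim_xy[1] & ys >= 1 & ys <= dim_xy[2]
  m[cbind(xs[keep], ys[keep])] <- TRUE
  m
}

#' Simulate a dynamic series with tumor, focal subregions and artery
#'
#' Builds a 2D+t raster in which every pixel follows its region's enhancement
#' model plus i.i.d. Gaussian noise. The tumor disc may contain two or more
#' focal subregions with distinct onset/wash-in parameters, which is what the
#' focal-ROI placement algorithm is meant to find. Background pixels stay at
#' a constant low signal.
#'
#' @param tumor_params [enhancement_params()] for the bulk tumor.
#' @param artery_params [enhancement_params()] for the artery; its onset must
#'   precede the tumor onset (bolus reaches the artery first).
#' @param geometry list with `dim` (c(nx, ny)), `tumor` (list(center,
#'   n_pix)), optional `subregions` (list of list(center, n_pix, params)),
#'   and `artery` (list(center, n_pix)). Centers in pixel coordinates.
#' @param grid a [make_sampling_grid()].
#' @param seed integer seed for the noise field.
#' @param noise_sd Gaussian noise sd in signal units, applied to every pixel.
#' @param background_si constant background signal.
#' @return list with `series` (a [dce_series()]) and `masks` (logical
#'   matrices: `whole_slab`, `artery`, and one `subregion_<i>` per focal
#'   subregion).
#' @export
generate_dce_series <- function(tumor_params, artery_params, geometry, grid,
                                seed = 1, noise_sd = 0, background_si = 50) {
  stopifnot(inherits(grid, "sampling_grid"))
  if (artery_params$onset_time >= tumor_params$onset_time) {
    stop("artery onset must precede tumor onset")
  }
  dim_xy <- geometry$dim
  whole <- disc_mask(dim_xy, geometry$tumor$center, geometry$tumor$n_pix)
  artery <- disc_mask(dim_xy, geometry$artery$center, geometry$artery$n_pix)
  if (any(whole & artery)) stop("tumor and artery regions overlap")

  # region id per pixel: 0 background, 1 tumor bulk, 2 artery, 3.. subregions
  region <- matrix(0L, dim_xy[1], dim_xy[2])
  region[whole] <- 1L
  region[artery] <- 2L
  sub_masks <- list()
  params_by_region <- list(`1` = tumor_params, `2` = artery_params)
  subs <- geometry$subregions
  if (!is.null(subs)) {
    for (i in seq_along(subs)) {
      sm <- disc_mask(dim_xy, subs[[i]]$center, subs[[i]]$n_pix)
      if (!all(whole[sm])) stop("subregion extends outside the tumor")
      region[sm] <- 2L + i
      params_by_region[[as.character(2L + i)]] <- subs[[i]]$params
      sub_masks[[paste0("subregion_", i)]] <- sm
    }
  }

  nt <- length(grid$times)
  pixels <- array(background_si, dim = c(dim_xy[1], dim_xy[2], nt))
  for (rid in names(params_by_region)) {
    curve <- enhancement_model(params_by_region[[rid]], grid$times)
    idx <- which(region == as.integer(rid))
    for (k in seq_len(nt)) {
      frame <- pixels[, , k]
      frame[idx] <- curve[k]
      pixels[, , k] <- frame
    }
  }
  if (noise_sd > 0) {
    pixels <- withr::with_seed(seed, {
      pmax(pixels + stats::rnorm(length(pixels), sd = noise_sd), 0)
    })
  }
  list(
    series = dce_series(pixels, grid$times, grid$injection_offset),
    masks = c(list(whole_slab = whole, artery = artery), sub_masks)
  )
}
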