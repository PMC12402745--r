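as_values <- function(x) {
  if (inherits(x, "dose_volume")) return(x$dose)
  if (inherits(x, "recon_volume")) return(x$amplitude)
  if (inherits(x, "sensitivity_map")) return(x$values)
  x
}

as_grid <- function(x) {
  if (is.list(x) && !is.null(x$grid)) x$grid else NULL
}

#' Cumulative dose-volume histogram
#'
#' Each point gives the percentage of voxels receiving a value greater than
#' or equal to the corresponding level. Levels are equally spaced from 0 to
#' `max_value` (the volume maximum by default), so normalized (a.u.) volumes
#' yield relative-dose DVHs.
#'
#' @param volume a `dose_volume`, `recon_volume`, `sensitivity_map` or
#'   numeric array.
#' @param n_bins number of dose levels (at least 2; default 101).
#' @param max_value upper end of the level axis.
#' @return A `dvh_curve` data.frame with columns `dose` and
#'   `volume_fraction` (percent), non-increasing in dose.
#' @export
dvh <- function(volume, n_bins = 101, max_value = NULL) {
  v <- as.numeric(as_values(volume))
  if (length(v) == 0) stop("empty volume")
  if (n_bins < 2) stop("need at least 2 bins")
  if (is.null(max_value)) max_value <- max(v)
  if (max_value <= 0) stop("volume maximum must be positive")
  lev <- seq(0, max_value, length.out = n_bins)
  frac <- vapply(lev, function(d) 100 * mean(v >= d), 0)
  structure(data.frame(dose = lev, volume_fraction = frac),
            class = c("dvh_curve", "data.frame"))
}

#' @export
plot.dvh_curve <- function(x, ..., xlab = "Dose", ylab = "Volume (%)",
                           type = "l") {
  plot(x$dose, x$volume_fraction, type = type, xlab = xlab, ylab = ylab, ...)
}

#' Root-mean-square difference between two DVH curves
#'
#' RMS of the volume-fraction differences over common dose levels, in
#' percentage points of volume fraction. When the curves are tabulated on
#' different level axes, `b` is linearly resampled onto the levels of `a`
#' with a warning.
#'
#' @param a,b `dvh_curve` objects.
#' @export
dvh_rmse <- function(a, b) {
  stopifnot(inherits(a, "dvh_curve"), inherits(b, "dvh_curve"))
  fb <- b$volume_fraction
  if (length(a$dose) != length(b$dose) ||
      max(abs(a$dose - b$dose)) > 1e-9 * max(a$dose)) {
    warning("DVH level axes differ; resampling the second curve")
    fb <- approx(b$dose, b$volume_fraction, xout = a$dose, rule = 2)$y
  }
  sqrt(mean((a$volume_fraction - fb)^2))
}

#' Global 3D gamma index analysis
#'
#' For every reference voxel, the gamma index is the minimum over candidate
#' displacements `r` (a lattice of `1/subsample_factor` voxel steps within
#' `search_radius_factor * dta`) of
#' `sqrt((dD / (dd% * Dmax_ref))^2 + (|r| / dta)^2)`, with the evaluated
#' volume interpolated trilinearly at the displaced position (global gamma:
#' the dose-difference criterion is a percentage of the reference maximum).
#' The pass rate counts voxels with gamma <= 1 among those at or above the
#' low-dose threshold; the 0-threshold rate over all voxels is also
#' reported.
#'
#' @param reference,evaluated `dose_volume`/`recon_volume` objects or numeric
#'   arrays on the same physical grid.
#' @param dd_percent dose-difference criterion (% of the reference maximum).
#' @param dta_mm distance-to-agreement criterion (mm).
#' @param low_dose_threshold exclusion threshold (% of the reference
#'   maximum); voxels below it are excluded from the headline pass rate.
#' @param search_radius_factor search radius in units of `dta_mm`.
#' @param subsample_factor subvoxel interpolation steps per voxel.
#' @param spacing voxel spacing (m), required when passing bare arrays.
#' @return A `gamma_result` with `gamma_map`, `pass_rate` (%),
#'   `pass_rate_all` (%), and the analysis settings.
#' @export
gamma_index <- function(reference, evaluated, dd_percent = 5, dta_mm = 5,
                        low_dose_threshold = 10, search_radius_factor = 3,
                        subsample_factor = 3, spacing = NULL) {
  ref <- as_values(reference); ev <- as_values(evaluated)
  if (!all(dim(ref) == dim(ev))) stop("volumes have different dimensions")
  gr <- as_grid(reference); ge <- as_grid(evaluated)
  if (!is.null(gr) && !is.null(ge) && !grids_match(gr, ge)) {
    stop("volumes lie on different physical grids")
  }
  if (is.null(spacing)) {
    if (is.null(gr)) stop("spacing required for bare arrays")
    spacing <- gr$spacing
  }
  stopifnot(dd_percent > 0, dta_mm > 0)
  dta <- dta_mm * 1e-3
  if (max(spacing) > dta) {
    stop("grid spacing exceeds the DTA criterion; resample the volumes first")
  }
  dmax <- max(ref)
  if (dmax <= 0) stop("reference volume is empty")
  disp <- gamma_displacements(spacing, dta, search_radius_factor,
                              subsample_factor)
  g <- cpp_gamma(as.numeric(ref), as.numeric(ev), dim(ref), spacing, disp,
                 dd_percent / 100 * dmax, dta)
  gmap <- array(g, dim(ref))
  sel <- ref >= low_dose_threshold / 100 * dmax
  structure(list(gamma_map = gmap,
                 pass_rate = 100 * mean(gmap[sel] <= 1),
                 pass_rate_all = 100 * mean(gmap <= 1),
                 dd_percent = dd_percent, dta_mm = dta_mm,
                 low_dose_threshold = low_dose_threshold,
                 normalization = dmax),
            class = "gamma_result")
}

# Candidate displacement lattice (m), sorted by norm, zero first.
gamma_displacements <- function(spacing, dta, search_radius_factor,
                                subsample_factor) {
  radius <- search_radius_factor * dta
  step <- spacing / subsample_factor
  k <- floor(radius / step)
  d <- expand.grid(x = (-k[1]:k[1]) * step[1],
                   y = (-k[2]:k[2]) * step[2],
                   z = (-k[3]:k[3]) * step[3])
  nrm <- sqrt(d$x^2 + d$y^2 + d$z^2)
  keep <- nrm <= radius
  d <- as.matrix(d[keep, , drop = FALSE])
  d[order(nrm[keep]), , drop = FALSE]
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(paste0("<gamma_result> %g%%/%g mm: pass rate %.2f%% ",
                     "(threshold %g%%), %.2f%% (all voxels)\n"),
              x$dd_percent, x$dta_mm, x$pass_rate, x$low_dose_threshold,
              x$pass_rate_all))
  invisible(x)
}

#' Structural similarity index
#'
#' Mean local SSIM with a Gaussian window and the standard stabilization
#' constants `C1 = (k1 L)^2`, `C2 = (k2 L)^2` from the dynamic range `L`.
#' 2D inputs are compared directly; 3D inputs are compared slice-wise along
#' the third axis and averaged (`mode = "volume"` treats the volume as a
#' stack but weights all windows equally, which for the separable Gaussian
#' window used here coincides with the slice-wise mean).
#'
#' @param a,b numeric arrays of identical shape, on a common dynamic range.
#' @param window_sigma Gaussian window standard deviation (pixels).
#' @param window_size window side length (odd; default 11).
#' @param k constants `c(k1, k2)`.
#' @param dynamic_range value range `L`; default `max(a, b) - min(a, b)`.
#' @return scalar in `[-1, 1]`.
#' @export
ssim_index <- function(a, b, window_sigma = 1.5, window_size = 11,
                       k = c(0.01, 0.03), dynamic_range = NULL) {
  if (!all(dim(a) == dim(b))) stop("inputs have different shapes")
  if (is.null(dynamic_range)) dynamic_range <- max(a, b) - min(a, b)
  if (dynamic_range <= 0) dynamic_range <- 1
  if (length(dim(a)) == 3) {
    return(mean(vapply(seq_len(dim(a)[3]), function(i) {
      ssim2d(a[, , i], b[, , i], window_sigma, window_size, k, dynamic_range)
    }, 0)))
  }
  ssim2d(a, b, window_sigma, window_size, k, dynamic_range)
}

ssim2d <- function(a, b, sigma, size, k, L) {
  C1 <- (k[1] * L)^2; C2 <- (k[2] * L)^2
  w <- gauss_kernel1(sigma, size)
  sm <- function(x) conv2_sep(x, w)
  mu_a <- sm(a); mu_b <- sm(b)
  va <- sm(a * a) - mu_a^2
  vb <- sm(b * b) - mu_b^2
  cab <- sm(a * b) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

gauss_kernel1 <- function(sigma, size) {
  n <- (size - 1) / 2
  k <- exp(-(-n:n)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable 2D convolution with symmetric (reflected) padding
conv2_sep <- function(x, k) {
  n <- (length(k) - 1) / 2
  pad_filter <- function(v) {
    p <- c(v[pmin(n:1, length(v))], v, v[pmax(length(v) - (1:n) + 1, 1)])
    stats::filter(p, k, sides = 2)[(n + 1):(n + length(v))]
  }
  x <- apply(x, 2, pad_filter)
  t(apply(x, 1, pad_filter))
}

#' Isodose contour in a cross-sectional plane
#'
#' Marching-squares contour(s) of a 2D image at `level_fraction` of its
#' maximum.
#'
#' @param plane_image 2D numeric matrix.
#' @param level_fraction contour level as a fraction of the image maximum,
#'   in (0, 1); the clinical benchmark level is 0.8.
#' @param x,y physical coordinates of the rows / columns (default: indices).
#' @return An `isodose_contour`: list with `level` (absolute), `level_fraction`
#'   and `contours`, a list of polylines with components `x`, `y`.
#' @export
isodose_contour <- function(plane_image, level_fraction, x = NULL, y = NULL) {
  stopifnot(is.matrix(plane_image), level_fraction > 0, level_fraction < 1)
  if (is.null(x)) x <- seq_len(nrow(plane_image))
  if (is.null(y)) y <- seq_len(ncol(plane_image))
  level <- level_fraction * max(plane_image)
  # contourLines warns on degenerate (constant) images; the empty-contour
  # warning below covers that case
  cl <- suppressWarnings(contourLines(x, y, plane_image, levels = level))
  if (length(cl) == 0) {
    warning("contour level above all image values; empty contour")
  }
  structure(list(level = level, level_fraction = level_fraction,
                 contours = lapply(cl, function(p) list(x = p$x, y = p$y))),
            class = "isodose_contour")
}

#' Region-mean normalized amplitude
#'
#' Mean of the volume's values over a region mask, the per-position summary
#' used to compare beams targeted at different locations.
#'
#' @param volume a `recon_volume`, `dose_volume` or numeric array.
#' @param mask logical array of the same shape; must select at least one
#'   voxel.
#' @export
region_mean_amplitude <- function(volume, mask) {
  v <- as_values(volume)
  if (!all(dim(v) == dim(mask))) stop("mask shape does not match volume")
  if (!any(mask)) stop("empty region mask")
  mean(v[mask])
}

#' Amplitude profile along a grid axis
#'
#' Samples the volume along a line parallel to one axis through a stated
#' point, by nearest-voxel lookup in the two transverse coordinates.
#'
#' @param volume a `recon_volume`, `dose_volume` or `sensitivity_map`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param through_point coordinates (m) of the line in the two transverse
#'   axes, in axis order with the profiled axis omitted.
#' @return data.frame with `coord_cm` (position along the axis, cm) and
#'   `amplitude`.
#' @export
line_profile <- function(volume, axis = c("z", "x", "y"),
                         through_point = c(0, 0)) {
  axis <- match.arg(axis)
  v <- as_values(volume); grid <- as_grid(volume)
  if (is.null(grid)) stop("volume carries no grid")
  ax <- grid_axes(grid)
  ia <- match(axis, c("x", "y", "z"))
  others <- setdiff(1:3, ia)
  idx <- integer(3)
  for (j in seq_along(others)) {
    centers <- ax[[others[j]]]
    if (through_point[j] < min(centers) - grid$spacing[others[j]] / 2 ||
        through_point[j] > max(centers) + grid$spacing[others[j]] / 2) {
      stop("profile line lies outside the volume")
    }
    idx[others[j]] <- which.min(abs(centers - through_point[j]))
  }
  sel <- list(idx[1], idx[2], idx[3])
  sel[[ia]] <- seq_len(dim(v)[ia])
  data.frame(coord_cm = ax[[ia]] * 100,
             amplitude = as.numeric(do.call(`[`, c(list(v), sel))))
}
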