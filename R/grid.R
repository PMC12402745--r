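#' Regular voxel grid in front of the array
#'
#' Defines the physical sampling of all volumetric quantities (sensitivity
#' maps, dose volumes, reconstructions). The array face lies in the plane
#' z = 0 with +z pointing into the medium; x is azimuth and y elevation.
#' The grid covers `[origin, origin + extent]` on each axis with voxel
#' centers at `origin + (i - 1/2) * spacing`.
#'
#' @param extent lengths (Lx, Ly, Lz) of the volume in meters.
#' @param spacing voxel size (dx, dy, dz) in meters; a scalar is recycled.
#' @param origin position (m) of the low corner of the volume. The default
#'   centers the volume laterally on the array axis with its front face at
#'   z = 0.
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(extent = c(0.15, 0.15, 0.25), spacing = 5e-3)
#' dim(g)
#' @export
volume_grid <- function(extent, spacing, origin = NULL) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(extent) == 3, length(spacing) == 3, all(spacing > 0),
            all(extent > 0))
  if (is.null(origin)) origin <- c(-extent[1] / 2, -extent[2] / 2, 0)
  stopifnot(length(origin) == 3)
  if (origin[3] < 0) {
    stop("volume must lie in front of the array (origin z >= 0)")
  }
  n <- as.integer(round(extent / spacing))
  if (any(n < 1)) stop("extent smaller than one voxel on some axis")
  structure(list(extent = as.numeric(extent), spacing = as.numeric(spacing),
                 origin = as.numeric(origin), n = n),
            class = "volume_grid")
}

#' @export
dim.volume_grid <- function(x) x$n

#' Voxel center coordinates along each axis
#' @param grid a [volume_grid()].
#' @return list with numeric vectors `x`, `y`, `z` (meters).
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  ax <- function(i) grid$origin[i] + (seq_len(grid$n[i]) - 0.5) * grid$spacing[i]
  list(x = ax(1), y = ax(2), z = ax(3))
}

#' All voxel centers as an n x 3 matrix
#'
#' Rows follow R array order: x varies fastest, then y, then z, matching
#' `array(values, dim(grid))`.
#' @inheritParams grid_axes
#' @export
voxel_centers <- function(grid) {
  a <- grid_axes(grid)
  cbind(rep(a$x, times = grid$n[2] * grid$n[3]),
        rep(rep(a$y, each = grid$n[1]), times = grid$n[3]),
        rep(a$z, each = grid$n[1] * grid$n[2]))
}

#' @rdname grid_axes
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %s mm, extent %s cm\n",
              x$n[1], x$n[2], x$n[3],
              paste(signif(x$spacing * 1e3, 3), collapse = " x "),
              paste(signif(x$extent * 1e2, 3), collapse = " x ")))
  invisible(x)
}

grids_match <- function(a, b, tol = 1e-9) {
  all(abs(a$extent - b$extent) < tol) && all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}
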